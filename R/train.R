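# SGD training on phantom pairs (or an image directory), checkpointing, and
# the YCbCr-aware inference path.

leaf_map <- function(p, f) {
  if (is.numeric(p)) return(f(p))
  if (is.list(p)) {
    for (i in seq_along(p)) if (!is.character(p[[i]])) p[[i]] <- leaf_map(p[[i]], f)
    return(p)
  }
  p
}

leaf_map3 <- function(p, a, b, f) {
  if (is.numeric(p)) return(f(p, a, b))
  if (is.list(p)) {
    for (i in seq_along(p))
      if (!is.character(p[[i]])) p[[i]] <- leaf_map3(p[[i]], a[[i]], b[[i]], f)
    return(p)
  }
  p
}

collect_grads <- function(params, pnodes, grads) {
  leaf_map3(params, pnodes, pnodes, function(p, n, ...) {
    g <- grads[[n]]
    if (is.null(g)) p * 0 else g
  })
}

# ---- data sources -----------------------------------------------------------

# Normalize a data argument into list(n, get(i)) yielding multimodal_pair.
as_pair_source <- function(data) {
  if (inherits(data, "multimodal_pair")) data <- list(data)
  if (is.function(data)) return(list(n = NA_integer_, get = data))
  if (is.character(data) && length(data) == 1 && dir.exists(data)) {
    m1 <- sort(list.files(data, pattern = "_m1\\.(png|tif|tiff)$", full.names = TRUE))
    if (length(m1) == 0) stop("no *_m1.* images found in ", data, call. = FALSE)
    stems <- sub("_m1\\.[^.]+$", "", m1)
    find1 <- function(stem, suffix) {
      hits <- Sys.glob(paste0(stem, suffix, ".*"))
      if (length(hits) == 0) NULL else hits[1]
    }
    return(list(n = length(stems), get = function(i) {
      j <- ((i - 1L) %% length(stems)) + 1L
      stem <- stems[j]
      p2 <- find1(stem, "_m2"); pl <- find1(stem, "_label")
      if (is.null(p2)) stop("missing modality-2 image for ", stem, call. = FALSE)
      lab <- if (is.null(pl)) NULL else (as_plane(read_image(pl)) > 0.5) * 1
      structure(list(img1 = as_plane(read_image(m1[j])),
                     img2 = read_image(p2), salient_label = lab,
                     meta = list(stem = stem)), class = "multimodal_pair")
    }))
  }
  if (is.list(data) && all(vapply(data, inherits, TRUE, "multimodal_pair")))
    return(list(n = length(data), get = function(i)
      data[[((i - 1L) %% length(data)) + 1L]]))
  stop("data must be multimodal pairs, a generator function, or a directory",
       call. = FALSE)
}

pair_luma <- function(pair) {
  if (is_gray(pair$img2)) as_plane(pair$img2) else rgb_to_ycbcr(pair$img2)$y
}

# ---- training ---------------------------------------------------------------

#' Train the fusion network with SGD
#'
#' Each step samples a batch of co-registered pairs, crops/augments them to
#' `cfg$patch`, runs the fusion forward graph, evaluates the configured loss
#' variant and applies one SGD-with-momentum update. The published protocol
#' (lr 1e-3, batch 8, 300 epochs, lambda 5) is the `"full"` profile default;
#' the `"desk"` profile scales everything down so a run takes seconds.
#'
#' @param cfg A [fusion_config()].
#' @param data Training pairs: a list of `multimodal_pair`, a generator
#'   `function(i)`, or a directory of `*_m1/_m2/_label` images (as written by
#'   [synthesize_phantom_set()]).
#' @param steps Total optimizer steps; default `cfg$epochs *
#'   cfg$steps_per_epoch`.
#' @param params Optional warm-start parameters.
#' @param log_csv Optional path; per-step losses are appended as CSV.
#' @param verbose Print a progress line every 20 steps.
#' @return A `train_state`: list with `params`, `cfg`, `step`, `opt`
#'   (momentum buffers), `seed` and `history` (per-step loss data.frame).
#' @export
train <- function(cfg, data, steps = NULL, params = NULL, log_csv = NULL,
                  verbose = FALSE) {
  src <- as_pair_source(data)
  if (is.null(steps)) steps <- cfg$epochs * cfg$steps_per_epoch
  if (is.null(params)) params <- init_params(cfg)
  vel <- leaf_map(params, function(x) x * 0)
  hist <- vector("list", steps)
  need_mask <- cfg$loss_variant %in% c("mask", "no_texture")

  with_local_seed(cfg$seed + 1L, {
    for (step in seq_len(steps)) {
      lr_t <- if (cfg$lr_schedule == "cosine")
        cfg$lr * 0.5 * (1 + cos(pi * (step - 1) / steps)) else cfg$lr
      tp <- ad_tape()
      pn <- nodeify(tp, params)
      loss_ids <- vector("list", cfg$batch_size)
      li_sum <- 0; lt_sum <- 0
      for (bi in seq_len(cfg$batch_size)) {
        i <- if (is.na(src$n)) step * cfg$batch_size + bi
             else sample.int(src$n, 1L)
        pair <- src$get(i)
        if (min(nrow(pair$img1), ncol(pair$img1)) > cfg$patch)
          pair <- crop_and_augment(pair, cfg$patch,
                                   seed = sample.int(.Machine$integer.max, 1L))
        i1 <- pair$img1
        i2 <- pair_luma(pair)
        masks <- NULL
        if (need_mask) {
          if (is.null(pair$salient_label))
            abort_config("loss variant '%s' requires salient labels",
                         cfg$loss_variant)
          masks <- build_masks(pair$salient_label,
                               contrast_mask(i1, cfg$contrast_window,
                                             cfg$contrast_threshold))
        }
        fused <- g_forward(tp, ad_const(tp, as3d(i1)), ad_const(tp, as3d(i2)),
                           pn, cfg)
        lo <- g_total_loss(tp, fused, i1, i2, masks, cfg)
        loss_ids[[bi]] <- lo$total
        li_sum <- li_sum + ad_value(tp, lo$l_int)
        lt_sum <- lt_sum + if (is.null(lo$l_text)) 0 else ad_value(tp, lo$l_text)
      }
      total <- loss_ids[[1]]
      if (cfg$batch_size > 1) {
        for (bi in 2:cfg$batch_size) total <- g_add(tp, total, loss_ids[[bi]])
        total <- g_scale(tp, total, 1 / cfg$batch_size)
      }
      grads <- ad_backward(tp, total)
      gs <- collect_grads(params, pn, grads)
      vel <- leaf_map3(vel, gs, gs, function(v, g, ...) cfg$momentum * v + g)
      params <- leaf_map3(params, vel, vel, function(p, v, ...) p - lr_t * v)
      hist[[step]] <- data.frame(step = step, l_total = ad_value(tp, total),
                                 l_int = li_sum / cfg$batch_size,
                                 l_text = lt_sum / cfg$batch_size, lr = lr_t)
      if (verbose && step %% 20L == 0L)
        message(sprintf("step %d/%d  loss %.4f", step, steps,
                        hist[[step]]$l_total))
    }
  })
  history <- do.call(rbind, hist)
  if (!is.null(log_csv)) utils::write.csv(history, log_csv, row.names = FALSE)
  structure(list(params = params, cfg = cfg, step = steps,
                 epoch = steps / cfg$steps_per_epoch, opt = list(velocity = vel),
                 seed = cfg$seed, history = history),
            class = "train_state")
}

# ---- checkpoints ------------------------------------------------------------

CKPT_VERSION <- "mmfuse-checkpoint-1"

#' Save / load a training checkpoint
#'
#' The checkpoint stores the versioned parameter set, configuration,
#' optimizer state and seed; a round trip restores bit-identical forward
#' outputs.
#'
#' @param state A `train_state` (or list with `params` and `cfg`).
#' @param path Checkpoint file path (RDS).
#' @return `save_checkpoint`: `path` invisibly; `load_checkpoint`: the
#'   restored `train_state`.
#' @export
save_checkpoint <- function(state, path) {
  saveRDS(list(version = CKPT_VERSION, state = state), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path, call. = FALSE)
  x <- tryCatch(readRDS(path), error = function(e)
    stop("corrupt checkpoint: ", path, call. = FALSE))
  if (!identical(x$version, CKPT_VERSION))
    stop("unsupported checkpoint version: ", x$version, call. = FALSE)
  x$state
}

# ---- inference --------------------------------------------------------------

pad_to_multiple <- function(img, f) {
  h <- nrow(img); w <- ncol(img)
  hp <- ceiling(h / f) * f; wp <- ceiling(w / f) * f
  if (hp == h && wp == w) return(list(img = img, h = h, w = w))
  out <- img[c(seq_len(h), rep(h, hp - h)), c(seq_len(w), rep(w, wp - w)),
             drop = FALSE]
  list(img = out, h = h, w = w)
}

#' Fuse a co-registered image pair with a trained model
#'
#' Grayscale pairs are fused directly. When the second image is RGB it is
#' converted to YCbCr, the network fuses its Y (luminance) plane with the
#' first image, and the fused luminance is recombined with the original
#' Cb/Cr planes (chroma passes through exactly) before conversion back to
#' RGB. Inputs whose sides are not divisible by the network stride are
#' edge-padded and the output cropped back.
#'
#' @param img1,img2 Matrices/arrays in `[0, 1]`, or image file paths.
#' @param state A `train_state` or checkpoint file path.
#' @param out Optional output image path (written with [write_image()]).
#' @return Fused image (matrix, or H x W x 3 array when `img2` is RGB).
#' @export
fuse_images <- function(img1, img2, state, out = NULL) {
  if (is.character(img1)) img1 <- read_image(img1)
  if (is.character(img2)) img2 <- read_image(img2)
  if (is.character(state)) state <- load_checkpoint(state)
  cfg <- state$cfg
  i1 <- as_plane(img1)
  rgb <- !is_gray(img2)
  if (rgb) {
    yc <- rgb_to_ycbcr(img2)
    i2 <- yc$y
  } else i2 <- as_plane(img2)
  if (!all(dim(i1) == dim(i2)))
    stop("fuse_images: input sizes differ", call. = FALSE)
  f <- 2L^(cfg$depth - 1L)
  p1 <- pad_to_multiple(i1, f); p2 <- pad_to_multiple(i2, f)
  fused <- forward_fuse(p1$img, p2$img, state$params, cfg)
  fused <- fused[seq_len(p1$h), seq_len(p1$w), drop = FALSE]
  # No gamut clipping here: recombining fused Y with the original Cb/Cr must
  # pass chroma through exactly; write_image() clips at quantization time.
  result <- if (rgb) ycbcr_to_rgb(fused, yc$cb, yc$cr) else fused
  if (!is.null(out)) write_image(out, result)
  result
}
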