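#' Write a set of synthetic phantom pairs to disk
#'
#' Generates `n` phantom pairs (seeds `seed`, `seed + 1`, ...) and writes
#' `phantom_###_m1.png`, `phantom_###_m2.png` and `phantom_###_label.png`
#' (labels as 0/255 single-channel PNG) into `dir` — the on-disk layout
#' consumed by [train()] and the CLI.
#'
#' @param dir Output directory (created if missing).
#' @param n Number of pairs.
#' @param seed Base seed.
#' @param height,width,... Passed to [phantom_config()].
#' @return Character vector of file stems, invisibly.
#' @export
synthesize_phantom_set <- function(dir, n = 4, seed = 1, height = 64,
                                   width = 64, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stems <- character(n)
  for (i in seq_len(n)) {
    pair <- generate_phantom_pair(phantom_config(height = height, width = width,
                                                 seed = seed + i - 1L, ...))
    stem <- file.path(dir, sprintf("phantom_%03d", i))
    write_image(paste0(stem, "_m1.png"), pair$img1)
    write_image(paste0(stem, "_m2.png"), pair$img2)
    write_image(paste0(stem, "_label.png"), pair$salient_label)
    stems[i] <- stem
  }
  invisible(stems)
}

phantom_pairs <- function(n, seed, height = 64, width = 64, ...) {
  lapply(seq_len(n), function(i)
    generate_phantom_pair(phantom_config(height = height, width = width,
                                         seed = seed + i - 1L, ...)))
}

eval_state_on_pairs <- function(state, pairs) {
  rows <- lapply(pairs, function(p) {
    fused <- fuse_images(p$img1, pair_luma(p), state)
    evaluate_all(fused, p$img1, pair_luma(p))
  })
  colMeans(do.call(rbind, rows))
}

#' Module and depth ablation harness
#'
#' Trains one network per requested module-toggle combination (subsets of
#' SFIM/PSIM/FIM; a disabled junction falls back to concatenation +
#' convolution) and per pyramid depth, all at the same desk-scale budget, and
#' evaluates each on the same held-out phantoms.
#'
#' @param toggle_sets List of character vectors, each a subset of
#'   `c("sfim", "psim", "fim")`; default all 8 combinations.
#' @param depths Integer vector of pyramid depths to additionally test with
#'   all modules on; default none.
#' @param cfg Base [fusion_config()] supplying everything except the toggles.
#' @param steps Training steps per configuration.
#' @param n_train,n_test Number of training and held-out phantom pairs.
#' @param seed Base seed for phantoms and initialization.
#' @return `data.frame` with one row per configuration: toggle/depth columns
#'   plus the seven mean metrics.
#' @export
ablation_run <- function(toggle_sets = NULL, depths = integer(0),
                         cfg = fusion_config(), steps = 20,
                         n_train = 4, n_test = 2, seed = 1) {
  all_mods <- c("sfim", "psim", "fim")
  if (is.null(toggle_sets)) {
    toggle_sets <- list()
    for (k in 0:3) toggle_sets <- c(toggle_sets, utils::combn(all_mods, k,
                                                simplify = FALSE))
  }
  stopifnot(all(unlist(toggle_sets) %in% all_mods))
  train_pairs <- phantom_pairs(n_train, seed + 100L)
  test_pairs <- phantom_pairs(n_test, seed + 900L)

  run_one <- function(cfg_i, label, depth) {
    st <- train(cfg_i, train_pairs, steps = steps)
    m <- eval_state_on_pairs(st, test_pairs)
    cbind(data.frame(config = label, depth = depth,
                     sfim = cfg_i$enable_sfim, psim = cfg_i$enable_psim,
                     fim = cfg_i$enable_fim,
                     final_loss = utils::tail(st$history$l_total, 1)),
          as.data.frame(as.list(m)))
  }

  rows <- list()
  for (ts in toggle_sets) {
    cfg_i <- cfg
    cfg_i$enable_sfim <- "sfim" %in% ts
    cfg_i$enable_psim <- "psim" %in% ts
    cfg_i$enable_fim <- "fim" %in% ts
    cfg_i$seed <- seed
    label <- if (length(ts) == 0) "baseline" else paste(sort(ts), collapse = "+")
    rows[[length(rows) + 1L]] <- run_one(cfg_i, label, cfg$depth)
  }
  for (d in depths) {
    cfg_d <- fusion_config(profile = cfg$profile, depth = d,
                           lambda = cfg$lambda, lr = cfg$lr,
                           momentum = cfg$momentum,
                           batch_size = cfg$batch_size, epochs = cfg$epochs,
                           patch = cfg$patch,
                           steps_per_epoch = cfg$steps_per_epoch, seed = seed,
                           loss_variant = cfg$loss_variant)
    rows[[length(rows) + 1L]] <- run_one(cfg_d, sprintf("depth-%d", d), d)
  }
  do.call(rbind, rows)
}
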