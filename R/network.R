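# Two-path multi-scale encoder, interaction junctions, decoder chain, and the
# end-to-end fusion forward graph.

conv_init <- function(k, cin, cout, gain = 2) {
  list(w = array(stats::rnorm(k * k * cin * cout, sd = sqrt(gain / (k * k * cin))),
                 c(k, k, cin, cout)),
       b = numeric(cout))
}

#' Initialize network parameters for a fusion configuration
#'
#' Parameter shapes are a pure function of the configuration: two separate
#' encoder paths (four 3x3 convolutions each by default, the first at stride
#' 1 and the rest at stride 2), one interaction junction per level (SFIM at
#' levels 1-2, PSIM at deeper levels, or concatenation + convolution when a
#' toggle is off), the decoder chain, and the four-layer reconstruction head.
#'
#' @param cfg A [fusion_config()].
#' @param seed Optional seed overriding `cfg$seed` for weight initialization.
#' @return Nested list of arrays (class `network_params`).
#' @export
init_params <- function(cfg, seed = NULL) {
  ch <- cfg$base_channels
  L <- cfg$depth
  with_local_seed(if (is.null(seed)) cfg$seed else seed, {
    enc_path <- function() {
      out <- list()
      for (l in seq_len(L)) {
        cin <- if (l == 1L) 1L else ch[l - 1L]
        out[[paste0("l", l)]] <- conv_init(3L, cin, ch[l])
      }
      out
    }
    junction <- list()
    for (l in seq_len(L)) {
      C <- ch[l]
      junction[[paste0("l", l)]] <-
        if (l <= 2L && cfg$enable_sfim) {
          list(type = "sfim",
               att = conv_init(3L, 2L, 2L, gain = 1),
               grp = list(w = array(stats::rnorm(18L * C, sd = sqrt(2 / 18)),
                                    c(3L, 3L, 2L, C)),
                          b = numeric(C)))
        } else if (l >= 3L && cfg$enable_psim) {
          list(type = "psim",
               v1 = conv_init(3L, C, C, gain = 1),
               k1 = conv_init(3L, C, C, gain = 1),
               v2 = conv_init(3L, C, C, gain = 1),
               k2 = conv_init(3L, C, C, gain = 1),
               q = conv_init(3L, 2L * C, C, gain = 1),
               out = conv_init(3L, 2L * C, C))
        } else {
          c(list(type = "concat"), conv_init(3L, 2L * C, C))
        }
    }
    dec <- list()
    for (l in L:2L) {
      dec[[paste0("d", l)]] <- list(c1 = conv_init(1L, ch[l], ch[l]),
                                    c3 = conv_init(3L, ch[l], ch[l - 1L]))
    }
    merge <- list()
    for (l in (L - 1L):1L) {
      merge[[paste0("m", l)]] <-
        if (l == 2L && cfg$enable_fim) list(type = "fim")
        else c(list(type = "concat"), conv_init(3L, 2L * ch[l], ch[l]))
    }
    d1 <- list(c1 = conv_init(3L, ch[1], ch[1]),
               c2 = conv_init(3L, ch[1], ch[1]),
               c3 = conv_init(3L, ch[1], ch[1]),
               c4 = conv_init(3L, ch[1], 1L, gain = 1))
    structure(list(enc1 = enc_path(), enc2 = enc_path(),
                   junction = junction, dec = dec, merge = merge, d1 = d1),
              class = "network_params")
  })
}

# ---- graph builders ---------------------------------------------------------

g_encode <- function(tp, ximg, encp, L) {
  levels <- vector("list", L)
  x <- ximg
  for (l in seq_len(L)) {
    s <- if (l == 1L) 1L else 2L
    x <- g_relu(tp, g_conv2d(tp, x, encp[[l]]$w, encp[[l]]$b, s, 1L))
    levels[[l]] <- x
  }
  levels
}

g_junction <- function(tp, f1, f2, jpl, cfg, level) {
  jp <- jpl[[level]]
  type <- jp$type
  if (type == "sfim") g_sfim(tp, f1, f2, jp, cfg$sfim_shared_gate)
  else if (type == "psim") g_psim(tp, f1, f2, jp, cfg$psim_downsample,
                                  cfg$scaled_attention)
  else g_conv2d(tp, g_concat_c(tp, f1, f2), jp$w, jp$b, 1L, 1L)
}

g_decode <- function(tp, fused, pn, cfg) {
  L <- cfg$depth
  x <- fused[[L]]
  for (l in L:2L) {
    dp <- pn$dec[[paste0("d", l)]]
    x <- g_relu(tp, g_conv2d(tp, x, dp$c1$w, dp$c1$b, 1L, 0L))
    x <- g_relu(tp, g_conv2d(tp, x, dp$c3$w, dp$c3$b, 1L, 1L))
    dl <- dim(as3d(nv(tp, fused[[l - 1L]])))
    x <- g_resize(tp, x, dl[1], dl[2])
    mp <- pn$merge[[paste0("m", l - 1L)]]
    x <- if (mp$type == "fim") g_fim(tp, x, fused[[l - 1L]])
         else g_conv2d(tp, g_concat_c(tp, x, fused[[l - 1L]]), mp$w, mp$b, 1L, 1L)
  }
  d1 <- pn$d1
  x <- g_relu(tp, g_conv2d(tp, x, d1$c1$w, d1$c1$b, 1L, 1L))
  x <- g_relu(tp, g_conv2d(tp, x, d1$c2$w, d1$c2$b, 1L, 1L))
  x <- g_relu(tp, g_conv2d(tp, x, d1$c3$w, d1$c3$b, 1L, 1L))
  x <- g_tanh(tp, g_conv2d(tp, x, d1$c4$w, d1$c4$b, 1L, 1L))
  g_shift(tp, g_scale(tp, x, 0.5), 0.5)     # tanh in [-1,1] -> [0,1]
}

g_forward <- function(tp, i1, i2, pn, cfg) {
  L <- cfg$depth
  p1 <- g_encode(tp, i1, pn$enc1, L)
  p2 <- g_encode(tp, i2, pn$enc2, L)
  fused <- vector("list", L)
  for (l in seq_len(L))
    fused[[l]] <- g_junction(tp, p1[[l]], p2[[l]], pn$junction, cfg, l)
  g_decode(tp, fused, pn, cfg)
}

check_divisible <- function(img, L) {
  d <- dim(as3d(img))
  f <- 2L^(L - 1L)
  if (d[1] %% f != 0L || d[2] %% f != 0L)
    stop(sprintf("input size %dx%d not divisible by %d", d[1], d[2], f),
         call. = FALSE)
}

# ---- public wrappers --------------------------------------------------------

#' Encode one modality into a multi-scale feature pyramid
#'
#' Runs one of the two separate encoding paths: `depth` 3x3 convolutions with
#' ReLU, the first at stride 1 and the rest at stride 2, producing feature
#' maps at scales 1, 1/2, ..., 1/2^(depth-1).
#'
#' @param image H x W matrix (H, W divisible by 2^(depth-1)).
#' @param params A `network_params` object (see [init_params()]).
#' @param side 1 or 2: which modality's encoder path to use.
#' @param cfg The [fusion_config()] the parameters were built for.
#' @return List of `depth` feature arrays (class `feature_pyramid`).
#' @export
encode <- function(image, params, side = 1, cfg) {
  check_divisible(image, cfg$depth)
  tp <- ad_tape()
  encp <- nodeify(tp, if (side == 1) params$enc1 else params$enc2)
  ids <- g_encode(tp, ad_const(tp, as3d(image)), encp, cfg$depth)
  structure(lapply(ids, function(i) ad_value(tp, i)), class = "feature_pyramid")
}

#' Reconstruct the fused image from a pyramid of fused feature maps
#'
#' Applies the decoder chain: each decoder is a 1x1 convolution, a 3x3
#' convolution and a bilinear x2 upsample, merged with the next-shallower
#' fused map (channel-gated interaction at the level-2 junction when enabled,
#' concatenation + convolution elsewhere). The final four-layer head uses
#' ReLU on the first three convolutions and Tanh on the last, affinely mapped
#' to `[0, 1]`.
#'
#' @param fused List of `depth` fused feature arrays (deepest last).
#' @param params A `network_params` object.
#' @param cfg The matching [fusion_config()].
#' @return H x W matrix with values in `[0, 1]`.
#' @export
decode <- function(fused, params, cfg) {
  if (length(fused) != cfg$depth)
    stop(sprintf("decode: expected %d pyramid levels, got %d", cfg$depth,
                 length(fused)), call. = FALSE)
  tp <- ad_tape()
  pn <- list(dec = nodeify(tp, params$dec), merge = nodeify(tp, params$merge),
             d1 = nodeify(tp, params$d1))
  ids <- lapply(fused, function(f) ad_const(tp, as3d(f)))
  as_plane(ad_value(tp, g_decode(tp, ids, pn, cfg)))
}

#' Full fusion forward pass on a pair of single-channel images
#'
#' Composition encode || encode -> per-level interaction (SFIM at levels 1-2,
#' PSIM at deeper levels; disabled junctions fall back to concatenation +
#' convolution) -> decode. RGB inputs are reduced to their luminance upstream
#' (see [fuse_images()]).
#'
#' @param img1,img2 Co-registered H x W matrices in `[0, 1]`.
#' @param params A `network_params` object.
#' @param cfg The matching [fusion_config()].
#' @return Fused H x W matrix in `[0, 1]`.
#' @export
forward_fuse <- function(img1, img2, params, cfg) {
  if (!all(dim(as_plane(img1)) == dim(as_plane(img2))))
    stop("forward_fuse: modality shapes differ", call. = FALSE)
  check_divisible(img1, cfg$depth)
  tp <- ad_tape()
  pn <- nodeify(tp, params)
  out <- g_forward(tp, ad_const(tp, as3d(as_plane(img1))),
                   ad_const(tp, as3d(as_plane(img2))), pn, cfg)
  as_plane(ad_value(tp, out))
}
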