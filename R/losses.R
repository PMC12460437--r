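# Mask construction and the training objective: saliency/contrast-mask
# intensity loss plus Sobel texture loss, and the ablation variants.

sobel_kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)       # d/dx (columns)
sobel_ky <- t(sobel_kx)                                          # d/dy (rows)

conv3_reflect <- function(img, kern) {
  n1 <- nrow(img); n2 <- ncol(img)
  xr <- img[reflect_idx(n1, 1L), reflect_idx(n2, 1L), drop = FALSE]
  out <- matrix(0, n1, n2)
  for (a in 1:3) for (b in 1:3) {
    if (kern[a, b] == 0) next
    out <- out + kern[a, b] * xr[a:(a + n1 - 1L), b:(b + n2 - 1L), drop = FALSE]
  }
  out
}

#' Sobel gradient magnitude
#'
#' Applies the standard 3x3 Sobel kernels with reflective borders and
#' combines the two responses as `|Gx| + |Gy|` (the usual fusion-loss
#' convention) or the Euclidean magnitude.
#'
#' @param img 2-D numeric matrix.
#' @param magnitude `"l1"` (default) or `"l2"`.
#' @return Matrix of gradient magnitudes, same shape as `img`.
#' @export
sobel_gradient <- function(img, magnitude = c("l1", "l2")) {
  magnitude <- match.arg(magnitude)
  img <- as_plane(img)
  gx <- conv3_reflect(img, sobel_kx)
  gy <- conv3_reflect(img, sobel_ky)
  if (magnitude == "l1") abs(gx) + abs(gy) else sqrt(gx^2 + gy^2)
}

#' High-contrast pixel mask
#'
#' Marks pixels whose squared deviation from the local box-filter mean (full
#' window, reflective borders) exceeds `threshold`.
#'
#' @param img 2-D matrix in `[0, 1]`.
#' @param window Odd window size >= 3.
#' @param threshold Squared-deviation threshold.
#' @return 0/1 matrix.
#' @export
contrast_mask <- function(img, window = 9, threshold = 0.02) {
  if (window %% 2 == 0 || window < 3)
    abort_config("contrast_mask: window must be odd and >= 3")
  img <- as_plane(img)
  mu <- box_mean(img, as.integer(window))
  ((img - mu)^2 > threshold) * 1
}

#' Build the mask set driving the intensity loss
#'
#' Adds the salient-object mask (from segmentation labels) and the
#' high-contrast mask of the infrared-like modality; wherever the sum is
#' positive the infrared mask `m_ir` is 1. The visible mask is its complement
#' `m_vi = 1 - m_ir`, so the two masks partition the image and the intensity
#' loss composites each pixel from exactly one source.
#'
#' @param salient 0/1 matrix of salient-object support.
#' @param contrast_ir 0/1 matrix from [contrast_mask()] of the infrared image.
#' @return List (class `mask_set`) with `salient`, `contrast`, `m_sum`,
#'   `m_ir`, `m_vi`.
#' @export
build_masks <- function(salient, contrast_ir) {
  salient <- as_plane(salient) * 1; contrast_ir <- as_plane(contrast_ir) * 1
  if (!all(dim(salient) == dim(contrast_ir)))
    stop("build_masks: shapes differ", call. = FALSE)
  m_sum <- salient + contrast_ir
  m_ir <- (m_sum > 0) * 1
  structure(list(salient = salient, contrast = contrast_ir, m_sum = m_sum,
                 m_ir = m_ir, m_vi = 1 - m_ir), class = "mask_set")
}

#' Masked intensity loss
#'
#' `(1/HW) * (||m_ir * (I_f - I_ir)||_1 + ||m_vi * (I_f - I_vi)||_1)`:
#' inside the infrared mask the fused image is pulled to the infrared
#' intensities, elsewhere to the visible ones, which suppresses overexposed
#' visible regions that fall inside `m_ir`.
#'
#' @param i_f,i_ir,i_vi Matrices of equal shape.
#' @param masks A `mask_set` from [build_masks()].
#' @return Nonnegative scalar.
#' @export
intensity_loss <- function(i_f, i_ir, i_vi, masks) {
  i_f <- as_plane(i_f); i_ir <- as_plane(i_ir); i_vi <- as_plane(i_vi)
  if (!all(dim(i_f) == dim(i_ir)) || !all(dim(i_f) == dim(i_vi)))
    stop("intensity_loss: shapes differ", call. = FALSE)
  hw <- length(i_f)
  (sum(abs(masks$m_ir * (i_f - i_ir))) + sum(abs(masks$m_vi * (i_f - i_vi)))) / hw
}

#' Sobel texture loss
#'
#' `(1/HW) * || |grad I_f| - max(|grad I_ir|, |grad I_vi|) ||_1` with the
#' Sobel operator and element-wise maximum: the fused image should carry the
#' stronger of the two source gradients everywhere.
#'
#' @inheritParams intensity_loss
#' @param magnitude Gradient magnitude convention, see [sobel_gradient()].
#' @return Nonnegative scalar.
#' @export
texture_loss <- function(i_f, i_ir, i_vi, magnitude = c("l1", "l2")) {
  magnitude <- match.arg(magnitude)
  i_f <- as_plane(i_f); i_ir <- as_plane(i_ir); i_vi <- as_plane(i_vi)
  if (!all(dim(i_f) == dim(i_ir)) || !all(dim(i_f) == dim(i_vi)))
    stop("texture_loss: shapes differ", call. = FALSE)
  g_f <- sobel_gradient(i_f, magnitude)
  g_max <- pmax(sobel_gradient(i_ir, magnitude), sobel_gradient(i_vi, magnitude))
  sum(abs(g_f - g_max)) / length(i_f)
}

#' Total training loss
#'
#' Default: `L_total = L_text + lambda * L_int` with the mask-based intensity
#' term. Ablation variants replace the intensity term with the plain
#' two-source L1 (`"pixel"`), the L1 to the element-wise source maximum
#' (`"max"`), or drop the texture term (`"no_texture"`).
#'
#' @inheritParams intensity_loss
#' @param lambda Intensity-loss weight (> 0), default 5.
#' @param variant One of `"mask"`, `"pixel"`, `"max"`, `"no_texture"`.
#' @param magnitude Sobel magnitude convention.
#' @return List (class `loss_values`) with `l_int`, `l_text`, `l_total`,
#'   `variant`.
#' @export
total_loss <- function(i_f, i_ir, i_vi, masks = NULL, lambda = 5,
                       variant = c("mask", "pixel", "max", "no_texture"),
                       magnitude = c("l1", "l2")) {
  variant <- match.arg(variant)
  if (lambda <= 0) abort_config("lambda must be > 0")
  i_f <- as_plane(i_f); i_ir <- as_plane(i_ir); i_vi <- as_plane(i_vi)
  hw <- length(i_f)
  l_int <- switch(variant,
    mask = ,
    no_texture = {
      if (is.null(masks)) abort_config("variant '%s' requires masks", variant)
      intensity_loss(i_f, i_ir, i_vi, masks)
    },
    pixel = (sum(abs(i_f - i_ir)) + sum(abs(i_f - i_vi))) / hw,
    max = sum(abs(i_f - pmax(i_ir, i_vi))) / hw)
  l_text <- texture_loss(i_f, i_ir, i_vi, magnitude)
  l_total <- if (variant == "no_texture") lambda * l_int
             else l_text + lambda * l_int
  structure(list(l_int = l_int, l_text = l_text, l_total = l_total,
                 variant = variant), class = "loss_values")
}

# ---- tape-side losses (training path) ---------------------------------------

g_sobel <- function(tp, x, magnitude = "l1") {
  xp <- g_pad_reflect(tp, x, 1L)
  kx <- ad_const(tp, array(sobel_kx, c(3L, 3L, 1L, 1L)))
  ky <- ad_const(tp, array(sobel_ky, c(3L, 3L, 1L, 1L)))
  zb <- ad_const(tp, 0)
  gx <- g_conv2d(tp, xp, kx, zb, 1L, 0L)
  gy <- g_conv2d(tp, xp, ky, zb, 1L, 0L)
  if (magnitude == "l1") g_add(tp, g_abs(tp, gx), g_abs(tp, gy))
  else stop("l2 sobel magnitude is not differentiable at 0; training uses l1")
}

g_l1_mean <- function(tp, a, b) g_mean(tp, g_abs(tp, g_sub(tp, a, b)))

# Total loss graph; i_f is a tape node, sources/masks are plain matrices.
g_total_loss <- function(tp, i_f, i_ir, i_vi, masks, cfg) {
  ir <- ad_const(tp, as3d(i_ir)); vi <- ad_const(tp, as3d(i_vi))
  variant <- cfg$loss_variant
  l_int <- switch(variant,
    mask = ,
    no_texture = {
      mir <- ad_const(tp, as3d(masks$m_ir)); mvi <- ad_const(tp, as3d(masks$m_vi))
      a <- g_mean(tp, g_abs(tp, g_mul(tp, mir, g_sub(tp, i_f, ir))))
      b <- g_mean(tp, g_abs(tp, g_mul(tp, mvi, g_sub(tp, i_f, vi))))
      g_add(tp, a, b)
    },
    pixel = g_add(tp, g_l1_mean(tp, i_f, ir), g_l1_mean(tp, i_f, vi)),
    max = g_l1_mean(tp, i_f, ad_const(tp, as3d(pmax(as_plane(i_ir),
                                                    as_plane(i_vi))))))
  if (variant == "no_texture") {
    list(total = g_scale(tp, l_int, cfg$lambda), l_int = l_int, l_text = NULL)
  } else {
    gmax <- pmax(sobel_gradient(as_plane(i_ir), "l1"),
                 sobel_gradient(as_plane(i_vi), "l1"))
    l_text <- g_mean(tp, g_abs(tp, g_sub(tp, g_sobel(tp, i_f),
                                         ad_const(tp, as3d(gmax)))))
    list(total = g_add(tp, l_text, g_scale(tp, l_int, cfg$lambda)),
         l_int = l_int, l_text = l_text)
  }
}
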