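# Reference-free and full-reference fusion-quality metrics:
# EN, AG, SF, SSIM, SCD, Qabf, VIF. Images are [0,1] matrices; EN quantizes
# to 256 levels and VIF rescales to the conventional 0-255 range internally.

#' Shannon entropy of the intensity histogram
#'
#' Intensities are quantized to 256 levels; result in bits, in `[0, 8]`.
#' @param img Matrix in `[0, 1]`.
#' @return Scalar entropy in bits.
#' @export
metric_en <- function(img) {
  img <- as_plane(img)
  if (length(img) == 0) stop("empty image", call. = FALSE)
  q <- floor(clip01(img) * 255 + 0.5)
  p <- tabulate(q + 1L, nbins = 256L) / length(q)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Average gradient
#'
#' Mean over interior pixels of `sqrt((dx^2 + dy^2) / 2)` with forward
#' differences.
#' @param img Matrix, at least 2 x 2.
#' @return Nonnegative scalar.
#' @export
metric_ag <- function(img) {
  img <- as_plane(img)
  h <- nrow(img); w <- ncol(img)
  if (h < 2 || w < 2) stop("image smaller than 2x2", call. = FALSE)
  dx <- img[seq_len(h - 1), -1, drop = FALSE] -
        img[seq_len(h - 1), seq_len(w - 1), drop = FALSE]
  dy <- img[-1, seq_len(w - 1), drop = FALSE] -
        img[seq_len(h - 1), seq_len(w - 1), drop = FALSE]
  mean(sqrt((dx^2 + dy^2) / 2))
}

#' Spatial frequency
#'
#' `sqrt(RF^2 + CF^2)` where RF and CF are the root-mean-square horizontal
#' and vertical first differences.
#' @param img Matrix, at least 2 x 2.
#' @return Nonnegative scalar.
#' @export
metric_sf <- function(img) {
  img <- as_plane(img)
  h <- nrow(img); w <- ncol(img)
  if (h < 2 || w < 2) stop("image smaller than 2x2", call. = FALSE)
  rf2 <- mean((img[, -1, drop = FALSE] - img[, -w, drop = FALSE])^2)
  cf2 <- mean((img[-1, , drop = FALSE] - img[-h, , drop = FALSE])^2)
  sqrt(rf2 + cf2)
}

gauss_kernel1d <- function(n, sigma) {
  k <- exp(-((seq_len(n) - (n + 1) / 2)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable filtering keeping only fully covered (valid) pixels.
filt_valid <- function(x, k) {
  n <- length(k)
  h <- nrow(x); w <- ncol(x)
  ho <- h - n + 1L; wo <- w - n + 1L
  if (ho < 1L || wo < 1L) stop("image too small for window", call. = FALSE)
  y <- matrix(0, ho, w)
  for (j in seq_len(n)) y <- y + k[j] * x[j:(j + ho - 1L), , drop = FALSE]
  z <- matrix(0, ho, wo)
  for (j in seq_len(n)) z <- z + k[j] * y[, j:(j + wo - 1L), drop = FALSE]
  z
}

ssim_pair <- function(a, b) {
  k <- gauss_kernel1d(11L, 1.5)
  c1 <- 0.01^2; c2 <- 0.03^2              # dynamic range 1
  mu1 <- filt_valid(a, k); mu2 <- filt_valid(b, k)
  s1 <- filt_valid(a * a, k) - mu1^2
  s2 <- filt_valid(b * b, k) - mu2^2
  s12 <- filt_valid(a * b, k) - mu1 * mu2
  mean(((2 * mu1 * mu2 + c1) * (2 * s12 + c2)) /
       ((mu1^2 + mu2^2 + c1) * (s1 + s2 + c2)))
}

#' Structural similarity
#'
#' Standard SSIM with an 11 x 11 Gaussian window (sigma 1.5), K1 = 0.01,
#' K2 = 0.03, dynamic range 1, averaged over the valid map. With three
#' arguments, returns the fusion convention: the mean of `ssim(fused, a)` and
#' `ssim(fused, b)`.
#'
#' @param a,b Matrices of equal shape.
#' @param b2 Optional second source (fusion usage: `metric_ssim(fused, src1,
#'   src2)`).
#' @return Scalar in `[-1, 1]`.
#' @export
metric_ssim <- function(a, b, b2 = NULL) {
  a <- as_plane(a); b <- as_plane(b)
  if (!all(dim(a) == dim(b))) stop("shape mismatch", call. = FALSE)
  if (is.null(b2)) return(ssim_pair(a, b))
  b2 <- as_plane(b2)
  if (!all(dim(a) == dim(b2))) stop("shape mismatch", call. = FALSE)
  (ssim_pair(a, b) + ssim_pair(a, b2)) / 2
}

cor0 <- function(x, y) {
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(0)       # zero-variance convention
  stats::cor(as.vector(x), as.vector(y))
}

#' Sum of correlations of differences
#'
#' `r(fused - b, a) + r(fused - a, b)` with Pearson correlation; a
#' zero-variance operand contributes 0.
#' @param fused,a,b Matrices of equal shape.
#' @return Scalar in `[-2, 2]`.
#' @export
metric_scd <- function(fused, a, b) {
  fused <- as_plane(fused); a <- as_plane(a); b <- as_plane(b)
  cor0(fused - b, a) + cor0(fused - a, b)
}

qabf_edges <- function(img) {
  gx <- conv3_reflect(img, sobel_kx)
  gy <- conv3_reflect(img, sobel_ky)
  g <- sqrt(gx^2 + gy^2)
  alpha <- atan(ifelse(gx == 0, ifelse(gy >= 0, Inf, -Inf), gy / gx))
  list(g = g, alpha = alpha)
}

qabf_preserve <- function(src, fus) {
  Gg <- 0.9994; kg <- -15; sg <- 0.5      # canonical strength model
  Ga <- 0.9879; ka <- -22; sa <- 0.8      # canonical orientation model
  G <- ifelse(src$g == fus$g, 1,
              pmin(src$g, fus$g) / pmax(src$g, fus$g, 1e-30))
  A <- 1 - abs(src$alpha - fus$alpha) / (pi / 2)
  qg <- Gg / (1 + exp(kg * (G - sg)))
  qa <- Ga / (1 + exp(ka * (A - sa)))
  # normalised so perfect preservation (G = 1, A = 1) scores exactly 1
  (qg / (Gg / (1 + exp(kg * (1 - sg))))) * (qa / (Ga / (1 + exp(ka * (1 - sa)))))
}

#' Edge-transfer quality (Q_abf)
#'
#' Gradient-based edge-preservation metric: Sobel edge strength and
#' orientation are computed for each source and the fused image; per-source
#' preservation follows the canonical sigmoidal strength/orientation models,
#' normalised so that perfect preservation scores 1, and the per-pixel values
#' are weighted by the source edge strengths. Result in `[0, 1]`; if all
#' images are flat the weights vanish and 0 is returned.
#'
#' @param fused,a,b Matrices of equal shape.
#' @return Scalar in `[0, 1]`.
#' @export
metric_qabf <- function(fused, a, b) {
  fused <- as_plane(fused); a <- as_plane(a); b <- as_plane(b)
  if (!all(dim(fused) == dim(a)) || !all(dim(fused) == dim(b)))
    stop("shape mismatch", call. = FALSE)
  ea <- qabf_edges(a); eb <- qabf_edges(b); ef <- qabf_edges(fused)
  qa <- qabf_preserve(ea, ef)
  qb <- qabf_preserve(eb, ef)
  wsum <- sum(ea$g) + sum(eb$g)
  if (wsum == 0) return(0)
  sum(qa * ea$g + qb * eb$g) / wsum
}

vifp_single <- function(ref, dist) {
  sigma_nsq <- 2
  num <- 0; den <- 0
  for (scale in 1:4) {
    N <- 2^(4 - scale + 1) + 1
    k <- gauss_kernel1d(N, N / 5)
    if (scale > 1) {
      ref <- filt_valid(ref, k)
      dist <- filt_valid(dist, k)
      ref <- ref[seq(1, nrow(ref), 2), seq(1, ncol(ref), 2), drop = FALSE]
      dist <- dist[seq(1, nrow(dist), 2), seq(1, ncol(dist), 2), drop = FALSE]
    }
    mu1 <- filt_valid(ref, k); mu2 <- filt_valid(dist, k)
    s1 <- pmax(filt_valid(ref * ref, k) - mu1^2, 0)
    s2 <- pmax(filt_valid(dist * dist, k) - mu2^2, 0)
    s12 <- filt_valid(ref * dist, k) - mu1 * mu2
    g <- s12 / (s1 + 1e-10)
    sv <- s2 - g * s12
    g[s1 < 1e-10] <- 0; sv[s1 < 1e-10] <- s2[s1 < 1e-10]; s1[s1 < 1e-10] <- 0
    g[s2 < 1e-10] <- 0; sv[s2 < 1e-10] <- 0
    sv[g < 0] <- s2[g < 0]; g[g < 0] <- 0
    sv[sv <= 1e-10] <- 1e-10
    num <- num + sum(log10(1 + g^2 * s1 / (sv + sigma_nsq)))
    den <- den + sum(log10(1 + s1 / sigma_nsq))
  }
  if (den == 0) return(1)                 # flat reference carries no information
  num / den
}

#' Visual information fidelity (pixel domain)
#'
#' Multi-scale Gaussian-scale-mixture formulation with four scales,
#' Gaussian windows of size 17/9/5/3 (sigma = size/5) and noise variance 2 on
#' the conventional 0-255 intensity range ([0,1] inputs are rescaled
#' internally). Computed fused-vs-each-source with the source as reference
#' and averaged over the two sources.
#'
#' @param fused,a,b Matrices of equal shape (at least 41 px per side for the
#'   four-scale pyramid).
#' @return Nonnegative scalar; 1 when the fused image equals both sources.
#' @export
metric_vif <- function(fused, a, b) {
  fused <- as_plane(fused) * 255; a <- as_plane(a) * 255; b <- as_plane(b) * 255
  (vifp_single(a, fused) + vifp_single(b, fused)) / 2
}

#' Evaluate all seven fusion metrics for one fused result
#'
#' @param fused Fused image, matrix in `[0, 1]`.
#' @param src1,src2 The two source images (RGB sources are reduced to their
#'   BT.601 luminance).
#' @return One-row `data.frame` (class `metric_report`) with columns `vif`,
#'   `ag`, `scd`, `qabf`, `sf`, `en`, `ssim`.
#' @export
evaluate_all <- function(fused, src1, src2) {
  to_luma <- function(x) if (is_gray(x)) as_plane(x) else rgb_to_ycbcr(x)$y
  f <- to_luma(fused); s1 <- to_luma(src1); s2 <- to_luma(src2)
  out <- data.frame(vif = metric_vif(f, s1, s2),
                    ag = metric_ag(f),
                    scd = metric_scd(f, s1, s2),
                    qabf = metric_qabf(f, s1, s2),
                    sf = metric_sf(f),
                    en = metric_en(f),
                    ssim = metric_ssim(f, s1, s2))
  class(out) <- c("metric_report", class(out))
  out
}

#' Evaluate matched directories of fused results against their sources
#'
#' Files are matched by name across the three directories; per-pair rows are
#' followed by an aggregate mean row.
#'
#' @param dir_fused,dir_src1,dir_src2 Directories of images with matching
#'   filenames.
#' @param csv Optional output CSV path.
#' @return `data.frame` with one row per pair plus a final `"mean"` row.
#' @export
evaluate_dir <- function(dir_fused, dir_src1, dir_src2, csv = NULL) {
  fs <- sort(basename(list.files(dir_fused)))
  s1 <- sort(basename(list.files(dir_src1)))
  s2 <- sort(basename(list.files(dir_src2)))
  if (!identical(fs, s1) || !identical(fs, s2)) {
    mm <- unique(c(setdiff(fs, s1), setdiff(s1, fs), setdiff(fs, s2),
                   setdiff(s2, fs)))
    stop("unmatched files across directories: ", paste(mm, collapse = ", "),
         call. = FALSE)
  }
  if (length(fs) == 0) stop("no images found", call. = FALSE)
  rows <- lapply(fs, function(f) {
    evaluate_all(read_image(file.path(dir_fused, f)),
                 read_image(file.path(dir_src1, f)),
                 read_image(file.path(dir_src2, f)))
  })
  tab <- do.call(rbind, rows)
  tab <- rbind(tab, colMeans(tab))
  tab <- cbind(data.frame(image = c(fs, "mean")), tab)
  if (!is.null(csv)) utils::write.csv(tab, csv, row.names = FALSE)
  tab
}
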