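#' Configuration for the synthetic multimodal phantom generator
#'
#' Describes one synthetic scene: co-registered modality-1 (infrared/MRI-like)
#' and modality-2 (visible/CT-like) images sharing geometry, with a
#' ground-truth salient-object mask. The generator is a pure function of this
#' configuration: the same seed yields a bit-identical phantom.
#'
#' @param height,width Image size in pixels, at least 32.
#' @param n_hot_objects Number of bright low-texture salient blobs in
#'   modality 1 (ellipses; their union is the salient label).
#' @param overexposure_fraction Fraction of modality-2 area saturated at 1.0,
#'   in `[0, 0.5]`, emulating headlight/overexposure failure regions.
#' @param texture_scale Correlation length (pixels) of the band-limited
#'   texture carried by modality 2.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param seed Integer RNG seed.
#' @return An object of class `phantom_config`.
#' @export
#' @examples
#' cfg <- phantom_config(height = 48, width = 48, seed = 7)
#' pair <- generate_phantom_pair(cfg)
#' range(pair$img1)
phantom_config <- function(height = 64, width = 64, n_hot_objects = 3,
                           overexposure_fraction = 0.1, texture_scale = 3,
                           noise_sd = 0.02, seed = 1) {
  if (height < 32 || width < 32)
    abort_config("phantom height/width must be >= 32 (got %d x %d)", height, width)
  if (overexposure_fraction < 0 || overexposure_fraction > 0.5)
    abort_config("overexposure_fraction must lie in [0, 0.5]")
  if (n_hot_objects < 0) abort_config("n_hot_objects must be >= 0")
  if (noise_sd < 0) abort_config("noise_sd must be >= 0")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_hot_objects = as.integer(n_hot_objects),
                 overexposure_fraction = overexposure_fraction,
                 texture_scale = texture_scale, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Read a phantom configuration from a YAML file
#'
#' @param path YAML file whose keys match the [phantom_config()] arguments.
#' @return A `phantom_config`.
#' @export
phantom_config_from_yaml <- function(path) {
  do.call(phantom_config, yaml::read_yaml(path))
}

ellipse_mask <- function(h, w, cy, cx, ry, rx, theta) {
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  u <- cos(theta) * xx + sin(theta) * yy
  v <- -sin(theta) * xx + cos(theta) * yy
  (u / rx)^2 + (v / ry)^2 <= 1
}

#' Generate one synthetic multimodal image pair
#'
#' Modality 1 holds the salience: `n_hot_objects` bright, low-texture
#' elliptical blobs on a dark, smoothly varying background (by construction
#' the mean intensity inside the salient label exceeds the mean outside).
#' Modality 2 is an RGB image sharing the scene geometry but carrying
#' high-frequency texture; the salient objects appear slightly darkened there
#' ("submerged"), and a contiguous `overexposure_fraction` of its area is
#' saturated at exactly 1.0 on all channels.
#'
#' @param cfg A [phantom_config()].
#' @return A `multimodal_pair`: list with `img1` (H x W matrix in `[0,1]`),
#'   `img2` (H x W x 3 array in `[0,1]`), `salient_label` (H x W 0/1 matrix)
#'   and `meta`.
#' @export
generate_phantom_pair <- function(cfg) {
  if (!inherits(cfg, "phantom_config")) cfg <- do.call(phantom_config, cfg)
  h <- cfg$height; w <- cfg$width
  with_local_seed(cfg$seed, {
    label <- matrix(0, h, w)
    if (cfg$n_hot_objects > 0) {
      for (i in seq_len(cfg$n_hot_objects)) {
        cy <- runif(1, 0.15 * h, 0.85 * h)
        cx <- runif(1, 0.15 * w, 0.85 * w)
        ry <- max(2, runif(1, 0.05, 0.14) * min(h, w))
        rx <- max(2, runif(1, 0.05, 0.14) * min(h, w))
        th <- runif(1, 0, pi)
        label[ellipse_mask(h, w, cy, cx, ry, rx, th)] <- 1
      }
    }

    # modality 1: dark smooth background + hot blobs + noise
    bg <- gauss_smooth(matrix(rnorm(h * w), h, w), min(h, w) / 8)
    bg <- 0.06 + 0.10 * (bg - min(bg)) / max(1e-12, diff(range(bg)))
    blob <- gauss_smooth(label, 1.2)       # soft shoulders, still bright inside
    img1 <- bg + 0.55 * label + 0.25 * blob
    img1 <- img1 + cfg$noise_sd * matrix(rnorm(h * w), h, w)
    img1 <- clip01(img1)

    # modality 2: shared geometry, high-frequency texture, overexposure
    tex <- gauss_smooth(matrix(rnorm(h * w), h, w), cfg$texture_scale / 3)
    tex <- tex / max(1e-12, stats::sd(tex))
    scene <- gauss_smooth(matrix(rnorm(h * w), h, w), min(h, w) / 6)
    scene <- (scene - min(scene)) / max(1e-12, diff(range(scene)))
    luma <- 0.35 + 0.25 * scene + 0.12 * tex - 0.20 * blob
    luma <- luma + cfg$noise_sd * matrix(rnorm(h * w), h, w)
    luma <- clip01(luma, 0, 0.97)          # headroom so saturation is exclusive

    img2 <- array(0, c(h, w, 3))
    img2[, , 1] <- clip01(luma * 1.04, 0, 0.97)
    img2[, , 2] <- luma
    img2[, , 3] <- clip01(luma * 0.94, 0, 0.97)

    if (cfg$overexposure_fraction > 0) {
      ov <- gauss_smooth(matrix(rnorm(h * w), h, w), min(h, w) / 6)
      thr <- stats::quantile(ov, 1 - cfg$overexposure_fraction, names = FALSE)
      ovm <- ov >= thr
      for (k in 1:3) {
        pl <- img2[, , k]; pl[ovm] <- 1; img2[, , k] <- pl
      }
    }

    structure(list(img1 = img1, img2 = img2, salient_label = label,
                   meta = list(seed = cfg$seed, config = unclass(cfg))),
              class = "multimodal_pair")
  })
}

rot90k <- function(m, k) {
  k <- k %% 4L
  if (k == 0L) return(m)
  for (i in seq_len(k)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  m
}

apply_geom <- function(m, top, left, patch, fliph, flipv, rotk) {
  m <- m[top:(top + patch - 1L), left:(left + patch - 1L), drop = FALSE]
  if (fliph) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  if (flipv) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  rot90k(m, rotk)
}

#' Crop a random square patch with flip/rotation augmentation
#'
#' The same crop window, flips and 90-degree rotation are applied to both
#' modalities and the salient label, preserving pixel-wise co-registration.
#'
#' @param pair A `multimodal_pair`.
#' @param patch Patch side length (<= min(height, width)).
#' @param seed RNG seed controlling window and augmentation draws.
#' @param augment If `FALSE`, no flips/rotations and, when `patch` equals the
#'   full size, the pair is returned unchanged.
#' @return A `multimodal_pair` of size `patch x patch`.
#' @export
crop_and_augment <- function(pair, patch, seed = 1, augment = TRUE) {
  h <- nrow(pair$img1); w <- ncol(pair$img1)
  if (patch > min(h, w))
    abort_config("patch (%d) exceeds image size (%d x %d)", patch, h, w)
  with_local_seed(seed, {
    top <- if (h == patch) 1L else sample.int(h - patch + 1L, 1L)
    left <- if (w == patch) 1L else sample.int(w - patch + 1L, 1L)
    fliph <- augment && runif(1) < 0.5
    flipv <- augment && runif(1) < 0.5
    rotk <- if (augment) sample.int(4L, 1L) - 1L else 0L
    tr <- function(m) apply_geom(m, top, left, patch, fliph, flipv, rotk)
    img2 <- pair$img2
    img2 <- if (is_gray(img2)) tr(as_plane(img2)) else {
      out <- array(0, c(patch, patch, dim(img2)[3]))
      for (k in seq_len(dim(img2)[3])) out[, , k] <- tr(img2[, , k])
      out
    }
    structure(list(img1 = tr(pair$img1), img2 = img2,
                   salient_label = if (is.null(pair$salient_label)) NULL
                                   else tr(pair$salient_label),
                   meta = c(pair$meta, list(patch = patch, crop_seed = seed))),
              class = "multimodal_pair")
  })
}
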