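#' Fusion network and training configuration
#'
#' Collects the architecture widths, module toggles, loss settings and
#' optimizer schedule. Two profiles are provided: `"full"` mirrors the
#' published training protocol (256 px patches, widths 32/64/128/256, SGD for
#' 300 epochs at lr 1e-3, batch 8), while `"desk"` is the default test-scale
#' profile (64 px phantoms, widths divided by 4, a handful of epochs) whose
#' runs complete in seconds on one CPU.
#'
#' @param profile `"desk"` or `"full"`; sets defaults for the arguments left
#'   `NULL`.
#' @param depth Number of encoder levels (3, 4 or 5); scales 1, 1/2, ...,
#'   1/2^(depth-1). The default 4-level pyramid (1, 1/2, 1/4, 1/8) balances
#'   fusion quality against edge erosion from deeper downsampling.
#' @param base_channels Integer vector of per-level channel widths
#'   (length `depth`).
#' @param lambda Weight of the intensity loss in the total loss
#'   `L_total = L_text + lambda * L_int`; default 5.
#' @param lr,momentum,batch_size,epochs SGD hyper-parameters.
#' @param patch Training patch side length (pixels).
#' @param steps_per_epoch Optimizer steps per epoch.
#' @param seed Integer seed governing initialization and data order.
#' @param enable_sfim,enable_psim,enable_fim Module toggles; a disabled
#'   junction falls back to channel concatenation + 3x3 convolution.
#' @param loss_variant `"mask"` (default, saliency/contrast-mask intensity
#'   loss), `"pixel"` (plain two-source L1), `"max"` (L1 to the element-wise
#'   source maximum) or `"no_texture"` (drops the texture term).
#' @param psim_downsample Spatial reduction inside the deep cross-attention.
#' @param scaled_attention Apply 1/sqrt(C) attention temperature (off by
#'   default).
#' @param sfim_shared_gate Share one spatial-attention map between modalities.
#' @param contrast_window,contrast_threshold Contrast-mask parameters (odd
#'   window in pixels; squared-deviation threshold on [0,1] intensities).
#' @param sobel_magnitude `"l1"` (|Gx|+|Gy|, default) or `"l2"` gradient
#'   magnitude in the texture loss.
#' @param lr_schedule `"constant"` (default) or `"cosine"`.
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(profile = c("desk", "full"), depth = 4,
                          base_channels = NULL, lambda = 5,
                          lr = 1e-3, momentum = 0.9,
                          batch_size = NULL, epochs = NULL, patch = NULL,
                          steps_per_epoch = NULL, seed = 1,
                          enable_sfim = TRUE, enable_psim = TRUE,
                          enable_fim = TRUE,
                          loss_variant = c("mask", "pixel", "max", "no_texture"),
                          psim_downsample = 2, scaled_attention = FALSE,
                          sfim_shared_gate = FALSE,
                          contrast_window = 9, contrast_threshold = 0.02,
                          sobel_magnitude = c("l1", "l2"),
                          lr_schedule = c("constant", "cosine")) {
  profile <- match.arg(profile)
  loss_variant <- match.arg(loss_variant)
  sobel_magnitude <- match.arg(sobel_magnitude)
  lr_schedule <- match.arg(lr_schedule)
  if (!depth %in% 3:5) abort_config("depth must be 3, 4 or 5")
  full_widths <- c(32L, 64L, 128L, 256L, 512L)[seq_len(depth)]
  if (is.null(base_channels))
    base_channels <- if (profile == "full") full_widths else full_widths %/% 4L
  base_channels <- as.integer(base_channels)
  if (length(base_channels) != depth || any(base_channels < 1))
    abort_config("base_channels must be %d positive integers", depth)
  if (lambda <= 0) abort_config("lambda must be > 0")
  if (contrast_window %% 2 == 0 || contrast_window < 3)
    abort_config("contrast_window must be odd and >= 3")
  if (is.null(batch_size)) batch_size <- if (profile == "full") 8L else 4L
  if (is.null(epochs)) epochs <- if (profile == "full") 300L else 5L
  if (is.null(patch)) patch <- if (profile == "full") 256L else 32L
  if (is.null(steps_per_epoch)) steps_per_epoch <- if (profile == "full") 135L else 10L
  structure(list(profile = profile, depth = as.integer(depth),
                 base_channels = base_channels, lambda = lambda,
                 lr = lr, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patch = as.integer(patch),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 seed = as.integer(seed),
                 enable_sfim = isTRUE(enable_sfim),
                 enable_psim = isTRUE(enable_psim),
                 enable_fim = isTRUE(enable_fim),
                 loss_variant = loss_variant,
                 psim_downsample = as.integer(psim_downsample),
                 scaled_attention = isTRUE(scaled_attention),
                 sfim_shared_gate = isTRUE(sfim_shared_gate),
                 contrast_window = as.integer(contrast_window),
                 contrast_threshold = contrast_threshold,
                 sobel_magnitude = sobel_magnitude,
                 lr_schedule = lr_schedule),
            class = "fusion_config")
}

#' @export
print.fusion_config <- function(x, ...) {
  cat("fusion_config (", x$profile, " profile)\n", sep = "")
  cat("  depth: ", x$depth, "; widths: ", paste(x$base_channels, collapse = "/"),
      "\n", sep = "")
  cat("  modules: SFIM=", x$enable_sfim, " PSIM=", x$enable_psim,
      " FIM=", x$enable_fim, "\n", sep = "")
  cat("  loss: ", x$loss_variant, " (lambda=", x$lambda, ", sobel=",
      x$sobel_magnitude, ")\n", sep = "")
  cat("  SGD: lr=", x$lr, " momentum=", x$momentum, " batch=", x$batch_size,
      " epochs=", x$epochs, " patch=", x$patch, "\n", sep = "")
  invisible(x)
}
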