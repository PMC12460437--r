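#' Read an image file into a [0,1] float array
#'
#' Supports 8- and 16-bit PNG and TIFF. Grayscale files come back as an
#' H x W matrix, colour files as an H x W x 3 array; an alpha channel, if
#' present, is dropped.
#'
#' @param path File path (`.png`, `.tif`, `.tiff`).
#' @return Numeric array with values in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 2L) img <- img[, , 1L]          # gray + alpha
    else if (dim(img)[3] == 4L) img <- img[, , 1:3]    # rgb + alpha
    else if (dim(img)[3] == 1L) img <- img[, , 1L]
  }
  img
}

#' Write a [0,1] float array to an image file
#'
#' PNG output is 8-bit; TIFF output may be 8- or 16-bit. Values are clipped to
#' `[0, 1]` before quantization, so `read_image(write_image(...))` round-trips
#' within one quantization step.
#'
#' @param path Output path (`.png`, `.tif`, `.tiff`).
#' @param img Matrix or H x W x 3 array in `[0, 1]`.
#' @param bits Bit depth, 8 or 16 (16 is available for TIFF only).
#' @return `path`, invisibly.
#' @export
write_image <- function(path, img, bits = 8) {
  img <- clip01(img)
  ext <- tolower(tools::file_ext(path))
  if (!bits %in% c(8, 16)) abort_config("bits must be 8 or 16")
  switch(ext,
    png = {
      if (bits != 8) abort_config("PNG output is 8-bit; use TIFF for 16-bit")
      png::writePNG(img, path)
    },
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = bits),
    stop("unsupported image format: .", ext, call. = FALSE))
  invisible(path)
}

#' RGB to YCbCr (full-range BT.601) and back
#'
#' The luma/chroma transform used throughout the fusion pipeline: the network
#' fuses the Y (luminance) plane only, and the Cb/Cr planes of the visible
#' image are carried through unchanged. Full-range BT.601 weights are used
#' (Kr = 0.299, Kg = 0.587, Kb = 0.114), with chroma centred at 0.5, so the
#' two functions are exact inverses on float input.
#'
#' @param img H x W x 3 array in `[0, 1]`.
#' @return `rgb_to_ycbcr`: list with matrices `y`, `cb`, `cr`.
#' @export
rgb_to_ycbcr <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("rgb_to_ycbcr expects an H x W x 3 array", call. = FALSE)
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  y <- 0.299 * r + 0.587 * g + 0.114 * b
  cb <- (b - y) / 1.772 + 0.5
  cr <- (r - y) / 1.402 + 0.5
  list(y = y, cb = cb, cr = cr)
}

#' @rdname rgb_to_ycbcr
#' @param y,cb,cr Matrices as produced by `rgb_to_ycbcr`.
#' @return `ycbcr_to_rgb`: H x W x 3 RGB array.
#' @export
ycbcr_to_rgb <- function(y, cb, cr) {
  if (!all(dim(y) == dim(cb)) || !all(dim(y) == dim(cr)))
    stop("y, cb, cr must share dimensions", call. = FALSE)
  r <- y + 1.402 * (cr - 0.5)
  b <- y + 1.772 * (cb - 0.5)
  g <- (y - 0.299 * r - 0.114 * b) / 0.587
  out <- array(0, c(dim(y), 3L))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out
}
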