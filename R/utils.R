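# Shared internal helpers.

clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# Run `expr` under a private RNG stream so callers' .Random.seed is untouched
# and the same seed always yields the same draw.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Separable Gaussian smoothing with reflective borders on a 2-D matrix.
gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  n1 <- nrow(x); n2 <- ncol(x)
  r1 <- min(r, n1 - 1L); r2 <- min(r, n2 - 1L)
  k1 <- if (r1 < r) { kk <- k[(r - r1 + 1L):(r + r1 + 1L)]; kk / sum(kk) } else k
  k2 <- if (r2 < r) { kk <- k[(r - r2 + 1L):(r + r2 + 1L)]; kk / sum(kk) } else k
  xr <- x[reflect_idx(n1, r1), , drop = FALSE]
  y <- matrix(0, n1, n2)
  for (j in seq_along(k1)) y <- y + k1[j] * xr[j:(j + n1 - 1L), , drop = FALSE]
  yr <- y[, reflect_idx(n2, r2), drop = FALSE]
  z <- matrix(0, n1, n2)
  for (j in seq_along(k2)) z <- z + k2[j] * yr[, j:(j + n2 - 1L), drop = FALSE]
  z
}

# Box-filter local mean with reflective borders (odd window).
box_mean <- function(x, window) {
  r <- (window - 1L) %/% 2L
  n1 <- nrow(x); n2 <- ncol(x)
  xr <- x[reflect_idx(n1, r), , drop = FALSE]
  y <- matrix(0, n1, n2)
  for (j in seq_len(window)) y <- y + xr[j:(j + n1 - 1L), , drop = FALSE]
  yr <- y[, reflect_idx(n2, r), drop = FALSE]
  z <- matrix(0, n1, n2)
  for (j in seq_len(window)) z <- z + yr[, j:(j + n2 - 1L), drop = FALSE]
  z / (window * window)
}

is_gray <- function(img) is.null(dim(img)) || length(dim(img)) == 2L ||
  (length(dim(img)) == 3L && dim(img)[3] == 1L)

as_plane <- function(img) {
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

abort_config <- function(...) stop(sprintf(...), call. = FALSE)
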