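# Independent brute-force oracles: literal per-element loop evaluations of the
# interaction blocks, losses and resampling, kept deliberately naive and
# separate from the package's vectorized implementations.

rand_feat <- function(h, w, c) array(stats::rnorm(h * w * c), c(h, w, c))

# Naive 2-D cross-correlation, zero padding, loops over every output pixel.
# w: (k, k, cin, cout) with w[a, b, ci, co] multiplying the input pixel
# (i*s - s + a - p, j*s - s + b - p).
conv2d_naive <- function(x, w, b, stride = 1, pad = 1) {
  d <- dim(x)
  k <- dim(w)[1]; cin <- dim(w)[3]; cout <- dim(w)[4]
  hp <- d[1] + 2 * pad; wp <- d[2] + 2 * pad
  xp <- array(0, c(hp, wp, cin))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  ho <- (hp - k) %/% stride + 1; wo <- (wp - k) %/% stride + 1
  y <- array(0, c(ho, wo, cout))
  for (o in seq_len(cout)) for (i in seq_len(ho)) for (j in seq_len(wo)) {
    acc <- b[o]
    for (ci in seq_len(cin)) for (a in seq_len(k)) for (bb in seq_len(k)) {
      acc <- acc + w[a, bb, ci, o] *
        xp[(i - 1) * stride + a, (j - 1) * stride + bb, ci]
    }
    y[i, j, o] <- acc
  }
  y
}

sfim_enhance_oracle <- function(f1, f2, params, shared_gate = FALSE) {
  d <- dim(f1)
  cat12 <- array(c(f1, f2), c(d[1], d[2], 2 * d[3]))
  fmax <- apply(cat12, c(1, 2), max)
  favg <- apply(cat12, c(1, 2), mean)
  pooled <- array(c(fmax, favg), c(d[1], d[2], 2))
  att <- 1 / (1 + exp(-conv2d_naive(pooled, params$att$w, params$att$b)))
  a1 <- if (shared_gate) (att[, , 1] + att[, , 2]) / 2 else att[, , 1]
  a2 <- if (shared_gate) a1 else att[, , 2]
  f1h <- f1; f2h <- f2
  for (c in seq_len(d[3])) {
    f1h[, , c] <- f1[, , c] + f1[, , c] * a1
    f2h[, , c] <- f2[, , c] + f2[, , c] * a2
  }
  list(f1_hat = f1h, f2_hat = f2h, att = att)
}

grouped_fuse_oracle <- function(f1h, f2h, params) {
  d <- dim(f1h)
  out <- array(0, c(d[1], d[2], d[3]))
  for (a in seq_len(d[3])) {
    pair <- array(c(f1h[, , a], f2h[, , a]), c(d[1], d[2], 2))
    wk <- array(params$grp$w[, , , a], c(3, 3, 2, 1))
    out[, , a] <- conv2d_naive(pair, wk, params$grp$b[a])[, , 1]
  }
  out
}

# Half-pixel-centre bilinear resampling, one output pixel at a time.
resize_naive <- function(x, ho, wo) {
  d <- dim(x)
  y <- array(0, c(ho, wo, d[3]))
  for (c in seq_len(d[3])) for (i in seq_len(ho)) for (j in seq_len(wo)) {
    sy <- (i - 0.5) * d[1] / ho - 0.5
    sx <- (j - 0.5) * d[2] / wo - 0.5
    i0 <- floor(sy); j0 <- floor(sx)
    fy <- sy - i0; fx <- sx - j0
    cl <- function(v, n) min(max(v, 0), n - 1) + 1
    y[i, j, c] <-
      (1 - fy) * (1 - fx) * x[cl(i0, d[1]), cl(j0, d[2]), c] +
      (1 - fy) * fx       * x[cl(i0, d[1]), cl(j0 + 1, d[2]), c] +
      fy       * (1 - fx) * x[cl(i0 + 1, d[1]), cl(j0, d[2]), c] +
      fy       * fx       * x[cl(i0 + 1, d[1]), cl(j0 + 1, d[2]), c]
  }
  y
}

# Flatten (H, W, C) to (H*W, C) with position index running down columns.
to_tokens <- function(x) matrix(x, prod(dim(x)[1:2]), dim(x)[3])

psim_oracle <- function(f1, f2, params, downsample = 2) {
  d <- dim(f1)
  hd <- d[1] %/% downsample; wd <- d[2] %/% downsample
  f1d <- resize_naive(f1, hd, wd)
  f2d <- resize_naive(f2, hd, wd)
  v1 <- to_tokens(conv2d_naive(f1d, params$v1$w, params$v1$b))
  k1 <- to_tokens(conv2d_naive(f1d, params$k1$w, params$k1$b))
  v2 <- to_tokens(conv2d_naive(f2d, params$v2$w, params$v2$b))
  k2 <- to_tokens(conv2d_naive(f2d, params$k2$w, params$k2$b))
  cat12 <- array(c(f1d, f2d), c(hd, wd, 2 * d[3]))
  q <- to_tokens(conv2d_naive(cat12, params$q$w, params$q$b))
  n <- nrow(q)
  ctx <- function(kx, vx) {
    out <- matrix(0, n, d[3])
    for (i in seq_len(n)) {
      logits <- numeric(n)
      for (j in seq_len(n)) logits[j] <- sum(q[i, ] * kx[j, ])
      e <- exp(logits - max(logits))
      a <- e / sum(e)
      for (cc in seq_len(d[3])) out[i, cc] <- sum(a * vx[, cc])
    }
    array(out, c(hd, wd, d[3]))
  }
  r1 <- f1 + resize_naive(ctx(k1, v1), d[1], d[2])
  r2 <- f2 + resize_naive(ctx(k2, v2), d[1], d[2])
  conv2d_naive(array(c(r1, r2), c(d[1], d[2], 2 * d[3])),
               params$out$w, params$out$b)
}

fim_oracle <- function(f_deep, f_shallow) {
  d <- dim(f_deep)
  out <- array(0, d)
  for (c in seq_len(d[3])) {
    gate <- 1 / (1 + exp(-mean(f_deep[, , c])))
    out[, , c] <- f_deep[, , c] + f_shallow[, , c] * gate
  }
  out
}

# Literal per-pixel loss evaluations.
intensity_loss_oracle <- function(i_f, i_ir, i_vi, m_ir, m_vi) {
  acc <- 0
  for (i in seq_len(nrow(i_f))) for (j in seq_len(ncol(i_f))) {
    acc <- acc + m_ir[i, j] * abs(i_f[i, j] - i_ir[i, j]) +
      m_vi[i, j] * abs(i_f[i, j] - i_vi[i, j])
  }
  acc / length(i_f)
}

sobel_naive <- function(img) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  ky <- t(kx)
  h <- nrow(img); w <- ncol(img)
  refl <- function(v, n) { v[v < 1] <- 2 - v[v < 1]; v[v > n] <- 2 * n - v[v > n]; v }
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    gx <- 0; gy <- 0
    for (a in -1:1) for (b in -1:1) {
      px <- img[refl(i + a, h), refl(j + b, w)]
      gx <- gx + kx[a + 2, b + 2] * px
      gy <- gy + ky[a + 2, b + 2] * px
    }
    out[i, j] <- abs(gx) + abs(gy)
  }
  out
}

texture_loss_oracle <- function(i_f, i_ir, i_vi) {
  gf <- sobel_naive(i_f)
  gm <- pmax(sobel_naive(i_ir), sobel_naive(i_vi))
  mean(abs(gf - gm))
}

rand_psim_params <- function(c) {
  pconv <- function(cin, cout) list(w = array(stats::rnorm(9 * cin * cout, sd = 0.3),
                                              c(3, 3, cin, cout)),
                                    b = stats::rnorm(cout, sd = 0.1))
  list(v1 = pconv(c, c), k1 = pconv(c, c), v2 = pconv(c, c), k2 = pconv(c, c),
       q = pconv(2 * c, c), out = pconv(2 * c, c))
}

rand_sfim_params <- function(c) {
  list(att = list(w = array(stats::rnorm(9 * 2 * 2, sd = 0.3), c(3, 3, 2, 2)),
                  b = stats::rnorm(2, sd = 0.1)),
       grp = list(w = array(stats::rnorm(18 * c, sd = 0.3), c(3, 3, 2, c)),
                  b = stats::rnorm(c, sd = 0.1)))
}
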