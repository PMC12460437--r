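# Minimal reverse-mode automatic differentiation over plain R arrays.
#
# The fusion network is small (a few dozen convolutions on <= 64 px patches),
# so a dynamic tape of array-valued nodes with closures for the backward pass
# is fast enough on one CPU: every convolution is an im2col gather followed by
# one BLAS matrix product. Feature maps are stored as (H, W, C) arrays,
# column-major, origin top-left.

.mm_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  v <- .mm_cache[[key]]
  if (is.null(v)) {
    v <- build()
    .mm_cache[[key]] <- v
  }
  v
}

# ---- tape -------------------------------------------------------------------

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$vals <- vector("list", 256L)
  tp$parents <- vector("list", 256L)
  tp$backfns <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ad_node <- function(tp, val, parents = integer(0), backfn = NULL) {
  # Force val and parents before claiming an id: either promise may itself
  # append nodes to the tape (inline op composition under lazy evaluation).
  force(val)
  parents <- as.integer(parents)
  n <- tp$n + 1L
  if (n > length(tp$vals)) {
    length(tp$vals) <- 2L * n
    length(tp$parents) <- 2L * n
    length(tp$backfns) <- 2L * n
  }
  tp$vals[[n]] <- val
  tp$parents[[n]] <- parents
  if (!is.null(backfn)) tp$backfns[[n]] <- backfn
  tp$n <- n
  n
}

ad_const <- function(tp, val) ad_node(tp, val)

# Read a node value. The node-id argument must be forced BEFORE tp$vals is
# fetched: op arguments are often inline op calls that append to the tape, and
# R's lazy evaluation would otherwise index a stale copy of the list.
nv <- function(tp, id) {
  force(id)
  tp$vals[[id]]
}

ad_value <- nv

# Backward sweep from a scalar node; returns a list of gradients indexed by
# node id (NULL where no gradient flows).
ad_backward <- function(tp, id) {
  grads <- vector("list", tp$n)
  grads[[id]] <- 1
  for (k in seq(id, 1L)) {
    g <- grads[[k]]
    if (is.null(g)) next
    bf <- tp$backfns[[k]]
    if (is.null(bf)) next
    pg <- bf(g)
    ps <- tp$parents[[k]]
    for (j in seq_along(ps)) {
      gj <- pg[[j]]
      if (is.null(gj)) next
      p <- ps[j]
      grads[[p]] <- if (is.null(grads[[p]])) gj else grads[[p]] + gj
    }
  }
  grads
}

# ---- elementwise ops --------------------------------------------------------

g_add <- function(tp, a, b) {
  ad_node(tp, nv(tp, a) + nv(tp, b), c(a, b), function(g) list(g, g))
}

g_sub <- function(tp, a, b) {
  ad_node(tp, nv(tp, a) - nv(tp, b), c(a, b), function(g) list(g, -g))
}

g_mul <- function(tp, a, b) {
  av <- nv(tp, a); bv <- nv(tp, b)
  ad_node(tp, av * bv, c(a, b), function(g) list(g * bv, g * av))
}

g_scale <- function(tp, a, s) {
  ad_node(tp, nv(tp, a) * s, a, function(g) list(g * s))
}

g_shift <- function(tp, a, s) {
  ad_node(tp, nv(tp, a) + s, a, function(g) list(g))
}

g_relu <- function(tp, a) {
  av <- nv(tp, a)
  keep <- av > 0
  y <- av * keep
  ad_node(tp, y, a, function(g) list(g * keep))
}

g_sigmoid <- function(tp, a) {
  y <- 1 / (1 + exp(-nv(tp, a)))
  ad_node(tp, y, a, function(g) list(g * y * (1 - y)))
}

g_tanh <- function(tp, a) {
  y <- tanh(nv(tp, a))
  ad_node(tp, y, a, function(g) list(g * (1 - y * y)))
}

g_abs <- function(tp, a) {
  av <- nv(tp, a)
  s <- sign(av)
  ad_node(tp, abs(av), a, function(g) list(g * s))
}

g_sum <- function(tp, a) {
  av <- nv(tp, a)
  d <- dim(av)
  ad_node(tp, sum(av), a, function(g) list(array(g, if (is.null(d)) length(av) else d)))
}

g_mean <- function(tp, a) {
  av <- nv(tp, a)
  n <- length(av)
  d <- dim(av)
  ad_node(tp, sum(av) / n, a, function(g) list(array(g / n, if (is.null(d)) n else d)))
}

# ---- shape / channel ops ----------------------------------------------------

as3d <- function(x) {
  if (is.null(dim(x))) dim(x) <- c(length(x), 1L, 1L)
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}

g_reshape <- function(tp, a, dims) {
  av <- nv(tp, a)
  d0 <- dim(av)
  y <- av
  dim(y) <- dims
  ad_node(tp, y, a, function(g) { dim(g) <- d0; list(g) })
}

g_concat_c <- function(tp, a, b) {
  av <- as3d(nv(tp, a)); bv <- as3d(nv(tp, b))
  da <- dim(av); db <- dim(bv)
  y <- array(c(av, bv), c(da[1], da[2], da[3] + db[3]))
  ad_node(tp, y, c(a, b), function(g) {
    list(array(g[, , seq_len(da[3]), drop = FALSE], da),
         array(g[, , da[3] + seq_len(db[3]), drop = FALSE], db))
  })
}

# Interleave channels of two equal-shape maps: out channels
# (a1, b1, a2, b2, ...) — the grouped-convolution input layout.
g_interleave_c <- function(tp, a, b) {
  av <- as3d(nv(tp, a)); bv <- as3d(nv(tp, b))
  d <- dim(av)
  C <- d[3]
  y <- array(0, c(d[1], d[2], 2L * C))
  y[, , seq(1L, 2L * C, by = 2L)] <- av
  y[, , seq(2L, 2L * C, by = 2L)] <- bv
  ad_node(tp, y, c(a, b), function(g) {
    list(array(g[, , seq(1L, 2L * C, by = 2L), drop = FALSE], d),
         array(g[, , seq(2L, 2L * C, by = 2L), drop = FALSE], d))
  })
}

# Channel-wise max over all channels -> (H, W, 1)
g_max_c <- function(tp, a) {
  av <- as3d(nv(tp, a))
  d <- dim(av)
  m <- matrix(av, d[1] * d[2], d[3])
  am <- max.col(m, ties.method = "first")
  sel <- cbind(seq_len(nrow(m)), am)
  y <- array(m[sel], c(d[1], d[2], 1L))
  ad_node(tp, y, a, function(g) {
    dm <- matrix(0, d[1] * d[2], d[3])
    dm[sel] <- as.vector(g)
    list(array(dm, d))
  })
}

# Channel-wise mean over all channels -> (H, W, 1)
g_mean_c <- function(tp, a) {
  av <- as3d(nv(tp, a))
  d <- dim(av)
  y <- array(rowMeans(matrix(av, d[1] * d[2], d[3])), c(d[1], d[2], 1L))
  ad_node(tp, y, a, function(g) {
    list(array(rep(as.vector(g) / d[3], d[3]), d))
  })
}

# (H, W, C) * (H, W) spatial map broadcast over channels
g_mul_hw <- function(tp, a, m) {
  av <- as3d(nv(tp, a))
  mv <- nv(tp, m)
  d <- dim(av)
  mvec <- as.vector(mv)
  y <- av * as.vector(mvec)          # recycles over channels
  ad_node(tp, y, c(a, m), function(g) {
    da <- g * mvec
    dmm <- rowSums(matrix(g * av, d[1] * d[2], d[3]))
    dm <- array(dmm, dim(mv))
    list(da, dm)
  })
}

# (H, W, C) * gate vector of length C broadcast spatially
g_mul_c <- function(tp, a, gate) {
  av <- as3d(nv(tp, a))
  gv <- nv(tp, gate)
  d <- dim(av)
  y <- av * rep(gv, each = d[1] * d[2])
  ad_node(tp, y, c(a, gate), function(g) {
    da <- g * rep(gv, each = d[1] * d[2])
    dg <- colSums(matrix(g * av, d[1] * d[2], d[3]))
    list(da, dg)
  })
}

# Global average pooling: (H, W, C) -> length-C vector
g_gap <- function(tp, a) {
  av <- as3d(nv(tp, a))
  d <- dim(av)
  hw <- d[1] * d[2]
  y <- colMeans(matrix(av, hw, d[3]))
  ad_node(tp, y, a, function(g) {
    list(array(rep(g / hw, each = hw), d))
  })
}

# ---- matrix / attention ops -------------------------------------------------

g_matmul <- function(tp, a, b) {
  av <- nv(tp, a); bv <- nv(tp, b)
  ad_node(tp, av %*% bv, c(a, b), function(g) {
    list(tcrossprod(g, bv), crossprod(av, g))
  })
}

# A %*% t(B)
g_matmul_tB <- function(tp, a, b) {
  av <- nv(tp, a); bv <- nv(tp, b)
  ad_node(tp, tcrossprod(av, bv), c(a, b), function(g) {
    list(g %*% bv, crossprod(g, av))
  })
}

g_softmax_rows <- function(tp, a) {
  av <- nv(tp, a)
  mx <- apply(av, 1L, max)
  e <- exp(av - mx)
  y <- e / rowSums(e)
  ad_node(tp, y, a, function(g) {
    list((g - rowSums(g * y)) * y)
  })
}

# ---- convolution ------------------------------------------------------------

im2col_index <- function(H, W, C, k, s, p) {
  Hp <- H + 2L * p; Wp <- W + 2L * p
  Hout <- (Hp - k) %/% s + 1L
  Wout <- (Wp - k) %/% s + 1L
  kh <- rep(0:(k - 1L), times = k)
  kw <- rep(0:(k - 1L), each = k)
  kern <- rep(kh + kw * Hp, times = C) + rep(0:(C - 1L), each = k * k) * (Hp * Wp)
  pos <- rep((0:(Hout - 1L)) * s, times = Wout) +
    rep((0:(Wout - 1L)) * s * Hp, each = Hout)
  ix <- outer(kern, pos, "+") + 1L
  storage.mode(ix) <- "integer"
  list(ix = ix, Hout = Hout, Wout = Wout, Hp = Hp, Wp = Wp)
}

im2col_cached <- function(H, W, C, k, s, p) {
  cache_get(paste("i2c", H, W, C, k, s, p, sep = "_"),
            function() im2col_index(H, W, C, k, s, p))
}

pad_zero_arr <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  y <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3]))
  y[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
  y
}

scatter_cols <- function(dP, ix, nout) {
  acc <- rowsum(as.vector(dP), group = as.vector(ix))
  out <- numeric(nout)
  out[as.integer(rownames(acc))] <- acc
  out
}

# 2-D convolution (cross-correlation) with zero padding.
# x: (H, W, Cin); w: (k, k, Cin, Cout); b: length Cout.
g_conv2d <- function(tp, x, w, b, stride = 1L, pad = 1L) {
  xv <- as3d(nv(tp, x))
  wv <- nv(tp, w); bv <- nv(tp, b)
  d <- dim(xv); dw <- dim(wv)
  k <- dw[1]; Cin <- dw[3]; Cout <- dw[4]
  stopifnot(d[3] == Cin)
  ii <- im2col_cached(d[1], d[2], Cin, k, as.integer(stride), as.integer(pad))
  Xp <- pad_zero_arr(xv, as.integer(pad))
  # index with the flattened vector: a matrix index whose column count equals
  # the array rank would be read as per-row coordinates
  P <- matrix(Xp[as.vector(ii$ix)], nrow = k * k * Cin)
  Wm <- matrix(wv, ncol = Cout)
  Yt <- crossprod(P, Wm)
  Yt <- Yt + rep(bv, each = nrow(Yt))
  out <- array(Yt, c(ii$Hout, ii$Wout, Cout))
  ad_node(tp, out, c(x, w, b), function(g) {
    dYt <- matrix(g, ncol = Cout)
    dW <- P %*% dYt
    db <- colSums(dYt)
    dP <- tcrossprod(Wm, dYt)
    dXp <- array(scatter_cols(dP, ii$ix, ii$Hp * ii$Wp * Cin),
                 c(ii$Hp, ii$Wp, Cin))
    p <- as.integer(pad)
    dx <- if (p == 0L) dXp else
      array(dXp[p + seq_len(d[1]), p + seq_len(d[2]), , drop = FALSE], d)
    list(dx, array(dW, dw), db)
  })
}

# Grouped 3x3 convolution: input (H, W, 2C) in interleaved layout
# (group g occupies channels 2g-1, 2g); each group maps 2 -> 1 channels.
# w: (3, 3, 2, C); b: length C.
g_grouped_conv <- function(tp, x, w, b) {
  xv <- as3d(nv(tp, x))
  wv <- nv(tp, w); bv <- nv(tp, b)
  d <- dim(xv)
  C <- d[3] %/% 2L
  ii <- im2col_cached(d[1], d[2], d[3], 3L, 1L, 1L)
  Xp <- pad_zero_arr(xv, 1L)
  N <- ii$Hout * ii$Wout
  P <- array(Xp[as.vector(ii$ix)], c(18L, C, N))
  wvec <- as.vector(wv)                       # length 18C, recycles over N
  Y <- colSums(P * wvec, dims = 1L)           # (C, N)
  Y <- Y + bv
  out <- array(t(Y), c(ii$Hout, ii$Wout, C))
  ad_node(tp, out, c(x, w, b), function(g) {
    dYm <- t(matrix(g, N, C))                 # (C, N)
    dYe <- array(rep(as.vector(dYm), each = 18L), c(18L, C, N))
    dW <- rowSums(P * dYe, dims = 2L)         # (18, C)
    db <- rowSums(dYm)
    dP <- dYe * wvec
    dXp <- array(scatter_cols(dP, ii$ix, ii$Hp * ii$Wp * d[3]),
                 c(ii$Hp, ii$Wp, d[3]))
    dx <- array(dXp[1L + seq_len(d[1]), 1L + seq_len(d[2]), , drop = FALSE], d)
    list(dx, array(dW, dim(wv)), db)
  })
}

# ---- resampling -------------------------------------------------------------

# 1-D linear interpolation matrix (half-pixel-centre convention, i.e. corner
# alignment disabled); downsampling by 2 reduces to 2-pixel averaging.
lin_resize_mat <- function(n_in, n_out) {
  cache_get(paste("lrm", n_in, n_out, sep = "_"), function() {
    M <- matrix(0, n_out, n_in)
    src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    i0 <- floor(src)
    f <- src - i0
    i0c <- pmin(pmax(i0, 0), n_in - 1) + 1L
    i1c <- pmin(pmax(i0 + 1, 0), n_in - 1) + 1L
    for (r in seq_len(n_out)) {
      M[r, i0c[r]] <- M[r, i0c[r]] + (1 - f[r])
      M[r, i1c[r]] <- M[r, i1c[r]] + f[r]
    }
    M
  })
}

resize_bilinear_arr <- function(xv, Hout, Wout) {
  xv <- as3d(xv)
  d <- dim(xv)
  Rm <- lin_resize_mat(d[1], Hout)
  Cm <- lin_resize_mat(d[2], Wout)
  Y1 <- Rm %*% matrix(xv, d[1])                    # (Hout, W*C)
  Y1p <- aperm(array(Y1, c(Hout, d[2], d[3])), c(2, 1, 3))
  Y2 <- Cm %*% matrix(Y1p, d[2])                   # (Wout, Hout*C)
  aperm(array(Y2, c(Wout, Hout, d[3])), c(2, 1, 3))
}

g_resize <- function(tp, x, Hout, Wout) {
  xv <- as3d(nv(tp, x))
  d <- dim(xv)
  out <- resize_bilinear_arr(xv, Hout, Wout)
  Rm <- lin_resize_mat(d[1], Hout)
  Cm <- lin_resize_mat(d[2], Wout)
  ad_node(tp, out, x, function(g) {
    g <- as3d(g)
    G2 <- crossprod(Cm, matrix(aperm(g, c(2, 1, 3)), Wout))   # (W, Hout*C)
    G1 <- matrix(aperm(array(G2, c(d[2], Hout, d[3])), c(2, 1, 3)), Hout)
    dx <- array(crossprod(Rm, G1), d)
    list(dx)
  })
}

# ---- reflect padding (mirror without edge duplication) ----------------------

reflect_idx <- function(n, p) {
  if (p == 0L) return(seq_len(n))
  stopifnot(n >= p + 1L)
  c((p + 1L):2L, seq_len(n), (n - 1L):(n - p))
}

g_pad_reflect <- function(tp, x, p) {
  xv <- as3d(nv(tp, x))
  d <- dim(xv)
  ih <- reflect_idx(d[1], p); iw <- reflect_idx(d[2], p)
  out <- xv[ih, iw, , drop = FALSE]
  key <- paste("refl", d[1], d[2], d[3], p, sep = "_")
  idx <- cache_get(key, function() {
    base <- outer(ih, (iw - 1L) * d[1], "+")
    as.vector(outer(as.vector(base), (seq_len(d[3]) - 1L) * d[1] * d[2], "+"))
  })
  ad_node(tp, out, x, function(g) {
    acc <- rowsum(as.vector(g), group = idx)
    dx <- numeric(prod(d))
    dx[as.integer(rownames(acc))] <- acc
    list(array(dx, d))
  })
}
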