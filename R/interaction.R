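# The three fusion blocks. Each has an internal graph builder (g_*) used by
# the training tape and a public array-in/array-out wrapper.

# Recursively replace numeric leaves of a parameter list with tape nodes,
# leaving character fields (e.g. $type) untouched.
nodeify <- function(tp, x) {
  if (is.numeric(x)) ad_node(tp, x)
  else if (is.list(x)) lapply(x, function(e) nodeify(tp, e))
  else x
}

g_slice_c <- function(tp, x, ch) {
  xv <- as3d(nv(tp, x))
  d <- dim(xv)
  y <- array(xv[, , ch], c(d[1], d[2], 1L))
  ad_node(tp, y, x, function(g) {
    dx <- array(0, d)
    dx[, , ch] <- g
    list(dx)
  })
}

# ---- SFIM -------------------------------------------------------------------

# Shared spatial attention: channel-wise max and mean of the concatenated
# stack -> 3x3 conv (2 -> 2 channels) -> sigmoid. Channel x of the map gates
# modality x (shared_gate = TRUE averages the two channels into one map used
# by both modalities).
g_sfim_enhance <- function(tp, f1, f2, jp, shared_gate = FALSE) {
  cat12 <- g_concat_c(tp, f1, f2)
  fmax <- g_max_c(tp, cat12)
  favg <- g_mean_c(tp, cat12)
  pooled <- g_concat_c(tp, fmax, favg)
  att <- g_sigmoid(tp, g_conv2d(tp, pooled, jp$att$w, jp$att$b, 1L, 1L))
  if (shared_gate) {
    a1 <- g_mean_c(tp, att)
    a2 <- a1
  } else {
    a1 <- g_slice_c(tp, att, 1L)
    a2 <- g_slice_c(tp, att, 2L)
  }
  f1h <- g_add(tp, f1, g_mul_hw(tp, f1, a1))
  f2h <- g_add(tp, f2, g_mul_hw(tp, f2, a2))
  list(f1h = f1h, f2h = f2h, att = att, fmax = fmax, favg = favg)
}

g_sfim_fuse <- function(tp, f1h, f2h, jp) {
  g_grouped_conv(tp, g_interleave_c(tp, f1h, f2h), jp$grp$w, jp$grp$b)
}

g_sfim <- function(tp, f1, f2, jp, shared_gate = FALSE) {
  enh <- g_sfim_enhance(tp, f1, f2, jp, shared_gate)
  g_sfim_fuse(tp, enh$f1h, enh$f2h, jp)
}

#' Superficial feature interaction: spatial-attention enhancement
#'
#' Concatenates the two modality features, pools them channel-wise (max and
#' mean), derives a two-channel sigmoid spatial-attention map via a 3x3
#' convolution, and residually re-weights each modality by its own attention
#' channel: `F_hat_x = F_x + F_x * att_x`.
#'
#' @param f1,f2 Feature maps, H x W x C arrays of equal shape.
#' @param params List with `att = list(w, b)`: `w` a (3, 3, 2, 2) kernel
#'   array, `b` length 2.
#' @param shared_gate Use one shared attention map (channel mean) for both
#'   modalities instead of one channel each.
#' @return List with `f1_hat`, `f2_hat`, and the intermediate `att`
#'   (H x W x 2, values in (0,1)), `f_max`, `f_avg` maps.
#' @export
sfim_enhance <- function(f1, f2, params, shared_gate = FALSE) {
  f1 <- as3d(f1); f2 <- as3d(f2)
  if (!all(dim(f1) == dim(f2)))
    stop("sfim_enhance: feature shapes differ", call. = FALSE)
  tp <- ad_tape()
  jp <- list(att = nodeify(tp, params$att))
  enh <- g_sfim_enhance(tp, ad_const(tp, f1), ad_const(tp, f2), jp, shared_gate)
  list(f1_hat = ad_value(tp, enh$f1h), f2_hat = ad_value(tp, enh$f2h),
       att = ad_value(tp, enh$att),
       f_max = as_plane(ad_value(tp, enh$fmax)),
       f_avg = as_plane(ad_value(tp, enh$favg)))
}

#' Superficial feature interaction: per-channel grouped fusion
#'
#' Pairs channel a of each enhanced modality, concatenates the pair and
#' reduces it to one output channel with one group of a 3x3 grouped
#' convolution (C groups, 2 -> 1 channels per group), avoiding cross-channel
#' interference.
#'
#' @param f1_hat,f2_hat Enhanced feature maps, H x W x C.
#' @param params List with `grp = list(w, b)`: `w` a (3, 3, 2, C) array
#'   (kernel for group a is `w[ , , , a]`, its two input slices being
#'   modality 1 then modality 2), `b` length C.
#' @return Fused H x W x C array.
#' @export
sfim_grouped_fuse <- function(f1_hat, f2_hat, params) {
  f1_hat <- as3d(f1_hat); f2_hat <- as3d(f2_hat)
  if (dim(f1_hat)[3] != dim(f2_hat)[3])
    stop("sfim_grouped_fuse: channel counts differ", call. = FALSE)
  tp <- ad_tape()
  jp <- list(grp = nodeify(tp, params$grp))
  ad_value(tp, g_sfim_fuse(tp, ad_const(tp, f1_hat), ad_const(tp, f2_hat), jp))
}

# ---- PSIM -------------------------------------------------------------------

g_psim <- function(tp, f1, f2, jp, downsample = 2L, scaled = FALSE) {
  d <- dim(as3d(nv(tp, f1)))
  H <- d[1]; W <- d[2]; C <- d[3]
  Hd <- H %/% downsample; Wd <- W %/% downsample
  if (Hd < 1L || Wd < 1L)
    abort_config("psim: spatial size %dx%d too small for downsample %d", H, W, downsample)
  f1d <- if (downsample > 1L) g_resize(tp, f1, Hd, Wd) else f1
  f2d <- if (downsample > 1L) g_resize(tp, f2, Hd, Wd) else f2
  N <- Hd * Wd
  proj <- function(x, pw) g_reshape(tp, g_conv2d(tp, x, pw$w, pw$b, 1L, 1L), c(N, C))
  v1 <- proj(f1d, jp$v1); k1 <- proj(f1d, jp$k1)
  v2 <- proj(f2d, jp$v2); k2 <- proj(f2d, jp$k2)
  q <- proj(g_concat_c(tp, f1d, f2d), jp$q)
  att_ctx <- function(kx, vx) {
    logits <- g_matmul_tB(tp, q, kx)
    if (scaled) logits <- g_scale(tp, logits, 1 / sqrt(C))
    a <- g_softmax_rows(tp, logits)
    g_reshape(tp, g_matmul(tp, a, vx), c(Hd, Wd, C))
  }
  r1 <- g_add(tp, f1, g_resize(tp, att_ctx(k1, v1), H, W))
  r2 <- g_add(tp, f2, g_resize(tp, att_ctx(k2, v2), H, W))
  g_conv2d(tp, g_concat_c(tp, r1, r2), jp$out$w, jp$out$b, 1L, 1L)
}

#' Profound semantic interaction: shared-query cross-attention fusion
#'
#' Both deep feature maps are spatially downsampled, projected by 3x3
#' convolutions into per-modality keys/values and a single query computed from
#' their channel concatenation (so the query carries complementary attributes
#' of both modalities). Row-wise softmax attention `A_x = softmax(Q K_x^T)`
#' yields per-modality global contexts `A_x V_x`, which are reshaped,
#' bilinearly upsampled back to the input size, residually added to the
#' original features, concatenated, and reduced by a 3x3 convolution.
#'
#' @param f1,f2 Deep feature maps, H x W x C arrays of equal shape.
#' @param params List of projection convolutions `v1, k1, v2, k2` (each
#'   `list(w, b)` with (3,3,C,C) kernels), `q` ((3,3,2C,C)) and the output
#'   reduction `out` ((3,3,2C,C)).
#' @param downsample Integer spatial reduction applied before attention.
#' @param scaled Apply 1/sqrt(C) attention temperature (off by default: the
#'   attention is used exactly as defined, without scaling).
#' @return Fused H x W x C array.
#' @export
psim <- function(f1, f2, params, downsample = 2, scaled = FALSE) {
  f1 <- as3d(f1); f2 <- as3d(f2)
  if (!all(dim(f1) == dim(f2)))
    stop("psim: feature shapes differ", call. = FALSE)
  tp <- ad_tape()
  jp <- nodeify(tp, params)
  ad_value(tp, g_psim(tp, ad_const(tp, f1), ad_const(tp, f2), jp,
                      as.integer(downsample), scaled))
}

# ---- FIM --------------------------------------------------------------------

g_fim <- function(tp, f_deep, f_shallow) {
  gate <- g_sigmoid(tp, g_gap(tp, f_deep))
  g_add(tp, f_deep, g_mul_c(tp, f_shallow, gate))
}

#' Feature interaction between decoder depths: channel-gated residual
#'
#' Bridges deep semantic and shallow detail features in the decoder:
#' `F' = F_deep + F_shallow * sigmoid(GAP(F_deep))`, where global average
#' pooling yields one sigmoid gate per channel, broadcast spatially. The gate
#' is parameter-free.
#'
#' @param f_deep Decoder output at the shallow level's resolution (H x W x C).
#' @param f_shallow Shallow fused features of the same shape.
#' @param params Unused; accepted for interface uniformity.
#' @return H x W x C array.
#' @export
fim <- function(f_deep, f_shallow, params = NULL) {
  f_deep <- as3d(f_deep); f_shallow <- as3d(f_shallow)
  if (dim(f_deep)[3] != dim(f_shallow)[3])
    stop("fim: channel counts differ", call. = FALSE)
  if (!all(dim(f_deep)[1:2] == dim(f_shallow)[1:2]))
    stop("fim: spatial sizes differ", call. = FALSE)
  tp <- ad_tape()
  ad_value(tp, g_fim(tp, ad_const(tp, f_deep), ad_const(tp, f_shallow)))
}
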