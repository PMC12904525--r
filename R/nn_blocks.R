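# Composite network blocks: wavelet-transform convolution (WTConv),
# frequency-spatial feature fusion (FS-FF) with difference-aware attention,
# and the multi-scale asymmetric feature fusion module (MS-AFFM) used by the
# quality critic. Each block has explicit forward/backward passes.

# ---- WTConv: per-subband depthwise convolution ---------------------------

#' Create a WTConv block
#'
#' One orthonormal Haar decomposition, an independent depthwise `k x k`
#' convolution per subband (LL, LH, HL, HH), and the inverse transform.
#' With identity-initialized subband convolutions the block is an exact
#' identity map; `identity_init = FALSE` adds small random perturbations
#' around the identity kernels.
#'
#' @param C channel count of the input features
#' @param k depthwise kernel size (default 3)
#' @param identity_init start exactly at the identity mapping
#' @return parameter list for [wtconv_fwd()]
#' @export
wtconv_new <- function(C, k = 3, identity_init = TRUE) {
  mk <- if (identity_init) function() dw_identity(k, C) else
    function() dw_random(k, C)
  list(LL = mk(), LH = mk(), HL = mk(), HH = mk())
}

reflect_pad1 <- function(x, pr, pc) {
  x <- as_cube(x)
  d <- dim(x)
  if (pr > 0) x <- x[c(seq_len(d[1]), d[1]), , , drop = FALSE]
  if (pc > 0) x <- x[, c(seq_len(d[2]), d[2]), , drop = FALSE]
  x
}

#' Apply / backpropagate a WTConv block
#'
#' @param p parameters from [wtconv_new()]
#' @param x `H x W x C` feature array; odd dimensions are edge-padded to
#'   even size and the output cropped back
#' @return `wtconv_fwd`: list with `y` and the cache; `wtconv_bwd`: list
#'   with `dx` and `grads`
#' @export
wtconv_fwd <- function(p, x) {
  x <- as_cube(x)
  d0 <- dim(x)
  pr <- d0[1] %% 2
  pc <- d0[2] %% 2
  xp <- if (pr || pc) reflect_pad1(x, pr, pc) else x
  sb <- dwt2_haar_nc(xp)
  caches <- list()
  ysb <- list()
  for (b in c("LL", "LH", "HL", "HH")) {
    caches[[b]] <- dwconv_fwd(p[[b]], sb[[b]])
    ysb[[b]] <- caches[[b]]$y
  }
  y <- idwt2_haar_nc(ysb)
  y <- y[seq_len(d0[1]), seq_len(d0[2]), , drop = FALSE]
  list(y = y, caches = caches, d0 = d0, pr = pr, pc = pc)
}

#' @rdname wtconv_fwd
#' @param cache forward cache
#' @param dy upstream gradient
#' @export
wtconv_bwd <- function(p, cache, dy) {
  dy <- as_cube(dy)
  d0 <- cache$d0
  if (cache$pr || cache$pc) {
    # adjoint of cropping is zero-padding to the padded size
    dyp <- array(0, dim = c(d0[1] + cache$pr, d0[2] + cache$pc, d0[3]))
    dyp[seq_len(d0[1]), seq_len(d0[2]), ] <- dy
    dy <- dyp
  }
  dsb <- dwt2_haar_nc(dy)  # adjoint of orthonormal IDWT
  grads <- list()
  dxs <- list()
  for (b in c("LL", "LH", "HL", "HH")) {
    r <- dwconv_bwd(p[[b]], cache$caches[[b]], dsb[[b]])
    grads[[b]] <- r$grads
    dxs[[b]] <- r$dx
  }
  dxp <- idwt2_haar_nc(dxs)  # adjoint of orthonormal DWT
  if (cache$pr || cache$pc) {
    dx <- dxp[seq_len(d0[1]), seq_len(d0[2]), , drop = FALSE]
    # fold the edge-replicated row/col gradients back
    if (cache$pr) dx[d0[1], , ] <- dx[d0[1], , ] + dxp[d0[1] + 1, seq_len(d0[2]), ]
    if (cache$pc) dx[, d0[2], ] <- dx[, d0[2], ] + dxp[seq_len(d0[1]), d0[2] + 1, ]
    dxp <- dx
  }
  list(dx = dxp, grads = grads)
}

# ---- FS-FF: difference-aware frequency-spatial fusion --------------------

#' Create an FS-FF fusion block
#'
#' Fuses spatial features `Fs` and frequency features `Ff` (same shape) as
#' `F_out = Conv3x3( DA(|Fs - Ff|) ) + Fs`, where the difference-aware
#' attention DA is a 1x1-conv sigmoid gate applied multiplicatively to the
#' absolute difference. The closing 3x3 convolution is zero-initialized, so
#' the block is exactly the identity on `Fs` at initialization.
#'
#' @param C channel count
#' @return parameter list for [fsff_fwd()]
#' @export
fsff_new <- function(C) {
  list(gate = he_conv(1, C, C), out = he_conv(3, C, C, zero = TRUE))
}

#' Apply / backpropagate FS-FF fusion
#'
#' @param p parameters from [fsff_new()]
#' @param fs spatial-branch features
#' @param ff frequency-branch features (same shape)
#' @export
fsff_fwd <- function(p, fs, ff) {
  fs <- as_cube(fs); ff <- as_cube(ff)
  if (!all(dim(fs) == dim(ff))) stop("FS-FF inputs must have equal shapes")
  diff <- fs - ff
  adiff <- abs(diff)
  cg <- conv_fwd(p$gate, adiff, stride = 1, pad = 0)
  sg <- sigmoid_fwd(cg$y)
  attended <- adiff * sg$y
  co <- conv_fwd(p$out, attended)
  list(y = co$y + fs, diff = diff, adiff = adiff, cg = cg, sg = sg,
       attended = attended, co = co)
}

#' @rdname fsff_fwd
#' @param cache forward cache
#' @param dy upstream gradient
#' @export
fsff_bwd <- function(p, cache, dy) {
  dy <- as_cube(dy)
  bo <- conv_bwd(p$out, cache$co, dy)
  datt <- bo$dx
  dadiff <- datt * cache$sg$y
  dgate <- datt * cache$adiff
  dg <- sigmoid_bwd(cache$sg, dgate)
  bg <- conv_bwd(p$gate, cache$cg, dg)
  dadiff <- dadiff + bg$dx
  ddiff <- dadiff * sign(cache$diff)
  list(dfs = dy + ddiff, dff = -ddiff,
       grads = list(gate = bg$grads, out = bo$grads))
}

# ---- MS-AFFM: multi-scale asymmetric feature fusion ----------------------

#' Create an MS-AFFM block
#'
#' Per-scale channel gates `alpha_s = sigmoid(W2 relu(W1 GAP(F_s)))` applied
#' to features resized (nearest-neighbor) to the finest scale, summed across
#' scales, with residual addition of the finest-scale input.
#'
#' @param C channel count (equal across scales)
#' @param n_scales number of input scales (coarser scales are upsampled)
#' @return parameter list for [msaffm_fwd()]
#' @export
msaffm_new <- function(C, n_scales = 2) {
  mid <- max(1L, C %/% 2)
  lapply(seq_len(n_scales), function(s) {
    list(d1 = he_dense(C, mid), d2 = he_dense(mid, C))
  })
}

#' Apply / backpropagate MS-AFFM
#'
#' @param p parameters from [msaffm_new()]
#' @param feats list of feature arrays, finest first, each half the
#'   resolution of the previous
#' @export
msaffm_fwd <- function(p, feats) {
  S <- length(feats)
  fine <- dim(as_cube(feats[[1]]))
  caches <- vector("list", S)
  fused <- as_cube(feats[[1]]) * 0
  for (s in seq_len(S)) {
    f <- as_cube(feats[[s]])
    ups <- list()
    fu <- f
    while (dim(fu)[1] < fine[1]) {
      u <- upsample2_fwd(fu)
      ups[[length(ups) + 1]] <- u
      fu <- u$y
    }
    g <- gap_fwd(f)
    z1 <- dense_fwd(p[[s]]$d1, g$y)
    r1 <- relu_fwd(z1$y)
    z2 <- dense_fwd(p[[s]]$d2, r1$y)
    sg <- sigmoid_fwd(z2$y)
    gated <- fu
    for (ch in seq_len(dim(fu)[3])) gated[, , ch] <- fu[, , ch] * sg$y[ch]
    fused <- fused + gated
    caches[[s]] <- list(f = f, ups = ups, fu = fu, g = g, z1 = z1, r1 = r1,
                        z2 = z2, sg = sg)
  }
  fused <- fused + as_cube(feats[[1]])  # residual enhancement
  list(y = fused, caches = caches, S = S)
}

#' @rdname msaffm_fwd
#' @param cache forward cache
#' @param dy upstream gradient
#' @export
msaffm_bwd <- function(p, cache, dy) {
  dy <- as_cube(dy)
  S <- cache$S
  dfeats <- vector("list", S)
  grads <- vector("list", S)
  for (s in seq_len(S)) {
    cc <- cache$caches[[s]]
    C <- dim(cc$fu)[3]
    dfu <- dy
    dgate <- numeric(C)
    for (ch in seq_len(C)) {
      dfu[, , ch] <- dy[, , ch] * cc$sg$y[ch]
      dgate[ch] <- sum(dy[, , ch] * cc$fu[, , ch])
    }
    dz2 <- sigmoid_bwd(cc$sg, dgate)
    b2 <- dense_bwd(p[[s]]$d2, cc$z2, dz2)
    dr1 <- relu_bwd(cc$r1, b2$dx)
    b1 <- dense_bwd(p[[s]]$d1, cc$z1, dr1)
    dgap <- gap_bwd(cc$g, b1$dx)
    for (u in rev(cc$ups)) dfu <- upsample2_bwd(u, dfu)
    dfeats[[s]] <- dfu + dgap
    grads[[s]] <- list(d1 = b1$grads, d2 = b2$grads)
  }
  dfeats[[1]] <- dfeats[[1]] + dy  # residual path
  list(dfeats = dfeats, grads = grads)
}
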