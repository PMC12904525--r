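# Orthonormal 2-D Haar transform and derived feature pyramids. The transform
# is its own building block for the wavelet-convolution (WTConv) blocks and
# the difference-perception critic; orthonormality gives exact Parseval
# energy conservation and perfect reconstruction.

#' Single-level orthonormal 2-D Haar transform
#'
#' Decomposes an even-sized matrix into four half-resolution subbands
#' `LL` (approximation), `LH` (horizontal detail), `HL` (vertical detail),
#' `HH` (diagonal detail). With the orthonormal scaling each 2x2 block maps
#' through an orthogonal matrix, so `sum(x^2)` equals the summed subband
#' energy and [idwt2_haar()] reconstructs exactly. A constant input `c`
#' yields `LL = 2c` and zero detail bands.
#'
#' @param x numeric matrix with even dimensions
#' @return list with matrices `LL`, `LH`, `HL`, `HH`
#' @export
dwt2_haar <- function(x) {
  n <- dim(x)
  if (any(n %% 2 != 0)) stop("dwt2_haar requires even dimensions")
  r1 <- seq(1, n[1], 2); r2 <- r1 + 1
  c1 <- seq(1, n[2], 2); c2 <- c1 + 1
  a <- x[r1, c1, drop = FALSE]; b <- x[r1, c2, drop = FALSE]
  d <- x[r2, c1, drop = FALSE]; e <- x[r2, c2, drop = FALSE]
  list(LL = (a + b + d + e) / 2,
       LH = (a - b + d - e) / 2,
       HL = (a + b - d - e) / 2,
       HH = (a - b - d + e) / 2)
}

#' Inverse of [dwt2_haar()]
#'
#' @param sb list with subbands `LL`, `LH`, `HL`, `HH`
#' @return reconstructed matrix
#' @export
idwt2_haar <- function(sb) {
  n <- dim(sb$LL)
  out <- matrix(0, 2 * n[1], 2 * n[2])
  r1 <- seq(1, 2 * n[1], 2); r2 <- r1 + 1
  c1 <- seq(1, 2 * n[2], 2); c2 <- c1 + 1
  out[r1, c1] <- (sb$LL + sb$LH + sb$HL + sb$HH) / 2
  out[r1, c2] <- (sb$LL - sb$LH + sb$HL - sb$HH) / 2
  out[r2, c1] <- (sb$LL + sb$LH - sb$HL - sb$HH) / 2
  out[r2, c2] <- (sb$LL - sb$LH - sb$HL + sb$HH) / 2
  out
}

# Multi-channel wrappers operating on H x W x C arrays.
dwt2_haar_nc <- function(x) {
  C <- dim(x)[3]
  sb <- lapply(seq_len(C), function(c) dwt2_haar(x[, , c]))
  bands <- c("LL", "LH", "HL", "HH")
  out <- lapply(bands, function(b) {
    arr <- array(0, dim = c(dim(sb[[1]]$LL), C))
    for (c in seq_len(C)) arr[, , c] <- sb[[c]][[b]]
    arr
  })
  names(out) <- bands
  out
}

idwt2_haar_nc <- function(sb) {
  C <- dim(sb$LL)[3]
  out <- array(0, dim = c(2 * dim(sb$LL)[1], 2 * dim(sb$LL)[2], C))
  for (c in seq_len(C)) {
    out[, , c] <- idwt2_haar(lapply(sb, function(b) b[, , c]))
  }
  out
}

#' Deterministic multi-scale structural features of an amplitude image
#'
#' Builds the three-scale feature set exported by the reconstruction stage
#' to the staining encoder: scale 1 is the image plus its Haar detail-energy
#' map; scales 2 and 3 are successive Haar approximations with their own
#' detail-energy channels. Every scale has 2 channels at 1x, 1/2x, 1/4x of
#' the input resolution, matching the staining encoder's pyramid.
#'
#' @param x numeric matrix in `[0, 1]` with dimensions divisible by 4
#' @return list of 3 arrays `H_i x W_i x 2`
#' @export
structural_features <- function(x) {
  stopifnot(all(dim(x) %% 4 == 0))
  feats <- vector("list", 3)
  cur <- x
  for (i in 1:3) {
    sb <- dwt2_haar(cur)
    energy <- sqrt(sb$LH^2 + sb$HL^2 + sb$HH^2)
    up_energy <- bicubic_resample(energy, size = dim(cur))
    f <- array(0, dim = c(dim(cur), 2))
    f[, , 1] <- cur
    f[, , 2] <- up_energy
    feats[[i]] <- f
    cur <- sb$LL / 2  # keep the approximation on the input scale
  }
  feats
}
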