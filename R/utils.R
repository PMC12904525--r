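# Shared numerical helpers: unitary FFTs, DC-centered spectra, resampling,
# seeded RNG scoping.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Mix two seed components into a valid 32-bit integer seed.
mix_seed <- function(a, b = 0) {
  as.integer((abs(a) %% 65011) * 33013 + abs(b) %% 32999)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed`, so library-level global RNG state is
#' never disturbed by seeded generation routines.
#'
#' @param seed integer seed
#' @param code expression to evaluate
#' @return value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Unitary 2-D FFT / inverse FFT
#'
#' Orthonormal scaling (`1/sqrt(n)` both ways) so Parseval's identity holds
#' exactly: `sum(|x|^2) == sum(|fft2u(x)|^2)`.
#'
#' @param x complex or real matrix
#' @return complex matrix
#' @export
fft2u <- function(x) stats::fft(x) / sqrt(length(x))

#' @rdname fft2u
#' @export
ifft2u <- function(x) stats::fft(x, inverse = TRUE) / sqrt(length(x))

#' Center / de-center the DC component of a spectrum
#'
#' `fftshift` moves DC to the grid center (index `floor(n/2)+1`);
#' `ifftshift` is its inverse (identical for even sizes).
#'
#' @param x matrix
#' @return matrix of the same shape
#' @export
fftshift <- function(x) {
  n <- dim(x)
  p <- floor(n / 2)
  x[c(seq_len(n[1] - p[1]) + p[1], seq_len(p[1])),
    c(seq_len(n[2] - p[2]) + p[2], seq_len(p[2])), drop = FALSE]
}

#' @rdname fftshift
#' @export
ifftshift <- function(x) {
  n <- dim(x)
  p <- ceiling(n / 2)
  x[c(seq_len(n[1] - p[1]) + p[1], seq_len(p[1])),
    c(seq_len(n[2] - p[2]) + p[2], seq_len(p[2])), drop = FALSE]
}

# DC-centered frequency axis for n samples of pitch `px` (units 1/[px]).
freq_axis <- function(n, px = 1) (seq_len(n) - (floor(n / 2) + 1)) / (n * px)

# Indices of the centered m x m patch inside an M x M DC-centered spectrum,
# displaced by (dr, dc) bins.
patch_index <- function(M, m, dr = 0, dc = 0) {
  cM <- floor(M / 2) + 1
  cm <- floor(m / 2) + 1
  rows <- (cM + dr) + (seq_len(m) - cm)
  cols <- (cM + dc) + (seq_len(m) - cm)
  if (any(rows < 1 | rows > M | cols < 1 | cols > M)) {
    stop("spectral patch falls outside the high-resolution frequency grid")
  }
  list(rows = rows, cols = cols)
}

#' Min-max normalization to [0, 1]
#'
#' Deterministic per-field normalization used for the Stage I to Stage II
#' interface image. A constant input maps to all zeros.
#'
#' @param x numeric matrix or array
#' @return rescaled object of the same shape
#' @export
norm01 <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi - lo <= .Machine$double.eps * max(1, abs(hi))) {
    return(x * 0)
  }
  (x - lo) / (hi - lo)
}

# Cubic convolution (Catmull-Rom, a = -0.5) interpolation weights.
cubic_kernel <- function(t, a = -0.5) {
  at <- abs(t)
  w <- numeric(length(t))
  i1 <- at <= 1
  w[i1] <- (a + 2) * at[i1]^3 - (a + 3) * at[i1]^2 + 1
  i2 <- at > 1 & at < 2
  w[i2] <- a * (at[i2]^3 - 5 * at[i2]^2 + 8 * at[i2] - 4)
  w
}

# 1-D resampling matrix (n_out x n_in), cubic convolution, clamped edges.
resample_matrix <- function(n_in, n_out) {
  W <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    x <- (i - 0.5) * scale - 0.5  # 0-based source coordinate
    j0 <- floor(x)
    js <- j0 + (-1:2)
    w <- cubic_kernel(x - js)
    js <- pmin(pmax(js, 0), n_in - 1)
    for (k in seq_along(js)) W[i, js[k] + 1] <- W[i, js[k] + 1] + w[k]
  }
  W / rowSums(W)
}

#' Bicubic resampling of an image
#'
#' Separable cubic-convolution (Catmull-Rom) interpolation; the standard
#' baseline upsampler that super-resolution gains are measured against.
#'
#' @param x numeric matrix
#' @param factor integer or fractional scale factor (>1 upsamples)
#' @param size optional explicit output size `c(rows, cols)` overriding factor
#' @return resampled matrix
#' @export
bicubic_resample <- function(x, factor = NULL, size = NULL) {
  if (is.null(size)) {
    stopifnot(!is.null(factor), factor > 0)
    size <- round(dim(x) * factor)
  }
  Wr <- resample_matrix(nrow(x), size[1])
  Wc <- resample_matrix(ncol(x), size[2])
  Wr %*% x %*% t(Wc)
}

# Separable Gaussian blur with edge replication; sigma in pixels, sigma = 0
# returns the input unchanged.
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad_blur_1d <- function(m) {
    n <- nrow(m)
    idx <- pmin(pmax(seq(1 - r, n + r), 1), n)
    mp <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (i in seq_len(n)) {
      out[i, ] <- crossprod(k, mp[i:(i + 2 * r), , drop = FALSE])
    }
    out
  }
  t(pad_blur_1d(t(pad_blur_1d(x))))
}

#' Least-squares intensity alignment
#'
#' Returns `a*x + b` minimizing `||a*x + b - ref||^2`. Ptychographic
#' reconstructions are only defined up to a global gain/offset (the
#' intensity scale is unobservable), so estimates are aligned to the
#' reference before fidelity metrics.
#'
#' @param x numeric matrix to rescale
#' @param ref reference matrix of the same shape
#' @return rescaled matrix
#' @export
match_scale <- function(x, ref) {
  vx <- as.vector(x); vr <- as.vector(ref)
  a <- stats::cov(vx, vr) / max(stats::var(vx), .Machine$double.eps)
  b <- mean(vr) - a * mean(vx)
  a * x + b
}
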