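# Image-fidelity metrics (MAE, PSNR, SSIM) and line-profile extraction.

#' Image fidelity metrics
#'
#' MAE is the mean absolute difference; PSNR is
#' `10 log10(data_range^2 / MSE)`, capped at 99 dB for identical images;
#' SSIM uses the standard 11x11 Gaussian window (sigma 1.5) with
#' `K1 = 0.01`, `K2 = 0.03`, computed over windows fully inside the image
#' (no boundary padding) and averaged.
#'
#' @param x,y equal-shape numeric matrices
#' @param data_range value range of the data (default 1.0)
#' @return named vector `c(mae, psnr, ssim)`
#' @export
image_metrics <- function(x, y, data_range = 1.0) {
  if (!all(dim(x) == dim(y))) stop("shape mismatch between images")
  mae <- mean(abs(x - y))
  mse <- mean((x - y)^2)
  psnr <- if (mse == 0) 99 else min(99, 10 * log10(data_range^2 / mse))
  c(mae = mae, psnr = psnr, ssim = ssim_index(x, y, data_range))
}

# Gaussian-windowed SSIM (Wang et al. constants), valid-window mean.
ssim_index <- function(x, y, data_range = 1.0, win = 11, sigma = 1.5,
                       K1 = 0.01, K2 = 0.03) {
  if (min(dim(x)) < win) win <- min(dim(x)) - (1 - min(dim(x)) %% 2)
  r <- (win - 1) / 2
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  g <- g / sum(g)
  filt <- function(m) {
    # separable valid-mode Gaussian filtering
    n1 <- nrow(m); n2 <- ncol(m)
    out1 <- matrix(0, n1 - 2 * r, n2)
    for (i in seq_len(n1 - 2 * r)) {
      out1[i, ] <- crossprod(g, m[i:(i + 2 * r), , drop = FALSE])
    }
    out2 <- matrix(0, n1 - 2 * r, n2 - 2 * r)
    for (j in seq_len(n2 - 2 * r)) {
      out2[, j] <- out1[, j:(j + 2 * r), drop = FALSE] %*% g
    }
    out2
  }
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  mx <- filt(x); my <- filt(y)
  mxx <- filt(x * x); myy <- filt(y * y); mxy <- filt(x * y)
  vx <- mxx - mx^2; vy <- myy - my^2; cxy <- mxy - mx * my
  ssim_map <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  mean(ssim_map)
}

#' Extract an intensity line profile
#'
#' Returns raw intensities along a row or column segment, plus local-maxima
#' peak positions at a configurable prominence.
#'
#' @param image numeric matrix
#' @param axis `"row"` (profile along a row) or `"col"`
#' @param index row/column index (in bounds)
#' @param span optional `c(from, to)` range along the profile
#' @param prominence minimum peak prominence (default 10% of profile range)
#' @return list with `profile`, `positions` (indices along the axis), and
#'   `peaks` (positions of detected maxima)
#' @export
line_profile <- function(image, axis = c("row", "col"), index,
                         span = NULL, prominence = NULL) {
  axis <- match.arg(axis)
  nmax <- if (axis == "row") nrow(image) else ncol(image)
  if (index < 1 || index > nmax) stop("profile index out of bounds")
  v <- if (axis == "row") image[index, ] else image[, index]
  pos <- seq_along(v)
  if (!is.null(span)) {
    if (span[1] < 1 || span[2] > length(v)) stop("span out of bounds")
    pos <- span[1]:span[2]
    v <- v[pos]
  }
  if (is.null(prominence)) prominence <- 0.1 * diff(range(v))
  peaks <- find_peaks(v, prominence)
  list(profile = v, positions = pos, peaks = pos[peaks])
}

# Local maxima with a simple prominence criterion: the drop from the peak
# to the highest minimum separating it from strictly higher terrain on
# either side must be at least `prom`. Plateaus count as single peaks
# (reported at their center); flat profiles yield no peaks.
find_peaks <- function(v, prom) {
  if (length(v) < 3 || diff(range(v)) == 0) return(integer(0))
  r <- rle(v)
  vals <- r$values
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  m <- length(vals)
  if (m < 3) return(integer(0))
  cand <- which(diff(sign(diff(vals))) < 0) + 1
  out <- integer(0)
  for (i in cand) {
    left <- vals[seq_len(i - 1)]
    right <- vals[seq(i + 1, m)]
    lh <- which(left > vals[i])
    rh <- which(right > vals[i])
    lmin <- if (length(lh) == 0) min(left) else
      min(left[seq(max(lh), length(left))])
    rmin <- if (length(rh) == 0) min(right) else
      min(right[seq_len(min(rh))])
    if ((vals[i] - max(lmin, rmin)) >= prom) {
      out <- c(out, floor((starts[i] + ends[i]) / 2))
    }
  }
  out
}
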