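# Wiener-regularized inverse filtering: the inverse-physics half of the
# bidirectional consistency objective.

#' Wiener deconvolution of an intensity image
#'
#' Computes `U_deconv = IFFT( conj(H) * FFT(I) / (|H|^2 + alpha) )` with a
#' DC-centered transfer function `H` and stabilizer `alpha >= 0`. With
#' `H == 1` and `alpha == 0` this is the identity; as `alpha` grows the
#' output is uniformly damped toward zero.
#'
#' @param intensity real matrix (e.g. the LED-averaged intensity)
#' @param H complex transfer function, DC-centered, same size
#' @param alpha Wiener stabilizer (>= 0); `alpha = 0` is only allowed when
#'   `H` has no zeros on the grid
#' @return complex matrix `U_deconv` (take `Mod()` for the amplitude
#'   estimate)
#' @export
wiener_deconvolve <- function(intensity, H, alpha = 1e-3) {
  stopifnot(all(dim(intensity) == dim(H)), alpha >= 0)
  if (alpha == 0 && any(Mod(H) < .Machine$double.eps)) {
    stop("alpha = 0 requires a strictly nonzero transfer function")
  }
  Fi <- fftshift(fft2u(intensity + 0i))
  ifft2u(ifftshift(Conj(H) * Fi / (Mod(H)^2 + alpha)))
}

# Reliable deconvolution band: the LED-averaged intensity is only a
# trustworthy amplitude proxy where the OTF retains a substantial fraction
# of its peak response (phase-object artifacts and noise amplification
# dominate the attenuated bands). Soft threshold at half response.
deconv_band <- function(H, threshold = 0.5, width = 0.1) {
  smoothstep((Mod(H) - threshold) / width)
}

# Apply a real, even, DC-centered frequency mask to a real image
# (self-adjoint linear filter).
band_filter <- function(x, mask) {
  Re(ifft2u(ifftshift(mask * fftshift(fft2u(x + 0i)))))
}

# Ideal (sinc) Fourier upsampling of an LR intensity image to the M x M HR
# grid: embeds the LR spectrum at the center of the HR spectrum.
fourier_upsample <- function(x, M) {
  m <- nrow(x)
  if (m == M) return(x)
  Fx <- fftshift(fft2u(x + 0i))
  FH <- matrix(0 + 0i, M, M)
  idx <- patch_index(M, m)
  FH[idx$rows, idx$cols] <- Fx * (M / m)
  Re(ifft2u(ifftshift(FH)))
}
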