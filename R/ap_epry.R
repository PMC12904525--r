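# Classical alternating-projections FPM reconstruction with embedded pupil
# recovery (AP+EPRY): the iterative baseline that the learned reconstruction
# is validated against.

#' Configuration for AP+EPRY
#'
#' @param n_iterations number of full sweeps over the LED set (>= 1)
#' @param step_object object-spectrum update step (default 1.0)
#' @param step_pupil pupil update step (default 0.1); ignored when
#'   `update_pupil = FALSE`
#' @param initialization `"upsampled-mean"` (bicubic-upsampled square root of
#'   the mean intensity, zero phase) or `"flat"`
#' @param update_pupil enable the embedded pupil recovery update
#' @return object of class `ap_config`
#' @export
ap_config <- function(n_iterations = 20, step_object = 1.0, step_pupil = 0.1,
                      initialization = c("upsampled-mean", "flat"),
                      update_pupil = TRUE) {
  stopifnot(n_iterations >= 1, step_object > 0, step_pupil > 0)
  structure(list(n_iterations = as.integer(n_iterations),
                 step_object = step_object, step_pupil = step_pupil,
                 initialization = match.arg(initialization),
                 update_pupil = update_pupil),
            class = "ap_config")
}

# LED processing order: spiral outward from the center of k-space.
spiral_order <- function(illum) {
  order(illum$sin_x^2 + illum$sin_y^2,
        atan2(illum$sin_y, illum$sin_x))
}

#' Alternating-projections reconstruction with embedded pupil recovery
#'
#' Classical sequential Gerchberg-Saxton-style FPM: each LED's low-resolution
#' field has its modulus replaced by the measured `sqrt(I_n)`, and the
#' correction is written back into the shifted patch of the high-resolution
#' spectrum; the pupil receives the standard EPRY gradient update from the
#' same correction. The recovered field is defined up to a global phase and
#' intensity gain.
#'
#' @param stack an `fpm_stack`
#' @param system an [optical_system()] consistent with the stack
#' @param config an [ap_config()]
#' @param init_pupil optional [make_pupil()] used as the starting (or fixed)
#'   pupil; default aberration-free
#' @return list with `field` (a [complex_field()]), `pupil` (complex matrix
#'   on the LR grid), and `residuals` (per-iteration data-consistency RMSE)
#' @export
ap_epry_reconstruct <- function(stack, system = stack$system,
                                config = ap_config(), init_pupil = NULL) {
  M <- system$hr_size
  m <- system$lr_size
  scale <- m / M
  illum <- stack$illum
  bins <- k_to_bins(illum, system)
  if (max(abs(c(bins$dr, bins$dc))) + ceiling(m / 2) > floor(M / 2)) {
    stop("LED wave vectors map outside the HR frequency grid")
  }

  sqrtI <- lapply(stack$images, function(im) sqrt(pmax(im, 0)))
  u0 <- switch(config$initialization,
    "upsampled-mean" = {
      iavg <- Reduce(`+`, stack$images) / length(stack$images)
      bicubic_resample(sqrt(pmax(iavg, 0)), size = c(M, M))
    },
    "flat" = matrix(mean(sqrt(pmax(stack$images[[1]], 0))), M, M))
  O <- fftshift(fft2u(u0 + 0i))

  base_pupil <- init_pupil %||% make_pupil(system)
  P <- base_pupil$p
  support <- base_pupil$support
  ord <- spiral_order(illum)
  residuals <- numeric(config$n_iterations)

  for (it in seq_len(config$n_iterations)) {
    res <- 0
    for (n in ord) {
      idx <- patch_index(M, m, -bins$dr[n], -bins$dc[n])
      Opatch <- O[idx$rows, idx$cols]
      Phi <- P * Opatch
      psi <- ifft2u(ifftshift(Phi)) * scale
      amp <- Mod(psi)
      res <- res + mean((sqrtI[[n]] - amp)^2)
      psi_new <- sqrtI[[n]] * psi / pmax(amp, 1e-12)
      Phi_new <- fftshift(fft2u(psi_new)) / scale
      dPhi <- Phi_new - Phi
      O[idx$rows, idx$cols] <- Opatch +
        config$step_object * Conj(P) / max(Mod(P)^2) * dPhi
      if (config$update_pupil) {
        P <- P + config$step_pupil * Conj(Opatch) / max(Mod(Opatch)^2) * dPhi
        P[!support] <- 0
      }
    }
    residuals[it] <- res / illum$n
    if (!is.finite(residuals[it])) {
      stop(sprintf("AP+EPRY diverged (non-finite residual) at iteration %d",
                   it))
    }
  }

  u <- ifft2u(ifftshift(O))
  list(field = complex_field(Mod(u), Arg(u), system$hr_pixel),
       pupil = P, residuals = residuals)
}
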