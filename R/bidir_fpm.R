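# Stage I: self-supervised reconstruction of amplitude, phase, Zernike pupil
# and illumination gain from a multi-LED FPM stack, by direct gradient-based
# optimization of a bidirectional physics-consistency objective:
#   forward path  — the differentiable band-limited coherent model (shared
#                   with the simulator) projects the current estimate to
#                   per-LED intensities;
#   inverse path  — Wiener PSF deconvolution of the LED-averaged intensity
#                   anchors the amplitude from the measurement side.
# The object field, 15 Zernike coefficients and the gain are the trainable
# parameters (the physics-based-network formulation in which the specimen's
# field itself is optimized under the physical forward model); gradients are
# derived analytically with Wirtinger calculus and applied with Adam.

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
softplus_inv <- function(y) ifelse(y > 30, y, log(expm1(pmax(y, 1e-8))))
sigmoid <- function(x) 1 / (1 + exp(-x))

flip_spectrum <- function(x) {
  n <- dim(x)
  x[c(1, n[1]:2), c(1, n[2]:2), drop = FALSE]
}

#' Loss weights for the reconstruction objective
#'
#' The total objective is
#' `L = L_phys + lambda_d L_deconv + lambda_tv (TV(A)+TV(phi)) + lambda_p R(P)`
#' with `R(P) = eta1 sum(a_i^2) + eta2 ||P(f) - conj(P(-f))||^2`. All squared
#' norms are per-pixel means so the weights are resolution-independent.
#'
#' @param lambda_d weight of the Wiener-deconvolution consistency term
#' @param lambda_tv weight of the total-variation terms
#' @param lambda_p weight of the pupil regularizer
#' @param eta1,eta2 pupil penalty components (coefficient energy, Hermitian
#'   asymmetry)
#' @param alpha_wiener Wiener stabilizer used in the inverse path
#' @return object of class `bidir_loss_weights`
#' @export
bidir_loss_weights <- function(lambda_d = 0.1, lambda_tv = 1e-4,
                             lambda_p = 1e-3, eta1 = 0.01, eta2 = 0.01,
                             alpha_wiener = 1e-3) {
  w <- list(lambda_d = lambda_d, lambda_tv = lambda_tv, lambda_p = lambda_p,
            eta1 = eta1, eta2 = eta2, alpha_wiener = alpha_wiener)
  if (any(unlist(w) < 0)) stop("loss weights must be >= 0")
  structure(w, class = "bidir_loss_weights")
}

#' Training configuration for the reconstruction stage
#'
#' @param epochs number of optimization epochs (200 at full scale; reduced
#'   presets are appropriate for small grids)
#' @param freeze_epochs epochs during which the optical parameters (Zernike
#'   coefficients and gain) receive zero gradient, stabilizing early field
#'   estimation; must be < `epochs`
#' @param lr_field Adam learning rate for the field parameters (amplitude
#'   pre-activation and phase)
#' @param lr_optics Adam learning rate for Zernike coefficients and log-gain
#' @param n_modes number of Zernike modes (default 15; piston frozen)
#' @param seed seed controlling any stochastic choices (the optimization
#'   itself is deterministic)
#' @return object of class `bidir_train_config`
#' @export
bidir_train_config <- function(epochs = 200, freeze_epochs = 10,
                             lr_field = 0.05, lr_optics = 0.05,
                             n_modes = 15, seed = 1) {
  if (freeze_epochs >= epochs) stop("freeze_epochs must be < epochs")
  structure(list(epochs = as.integer(epochs),
                 freeze_epochs = as.integer(freeze_epochs),
                 lr_field = lr_field, lr_optics = lr_optics,
                 n_modes = as.integer(n_modes), seed = as.integer(seed)),
            class = "bidir_train_config")
}

# Assemble a prediction object from raw parameters.
bidir_prediction <- function(thA, phi, coeffs, ths, system) {
  A <- matrix(softplus(thA), nrow(thA))
  wrapped <- ((phi + pi) %% (2 * pi)) - pi
  wrapped[wrapped == -pi] <- pi
  structure(list(amplitude = A, phase = wrapped,
                 zernike_coeffs = coeffs, gain = exp(ths),
                 system = system,
                 params = list(thA = thA, phi = phi, a = coeffs, ths = ths)),
            class = "bidir_prediction")
}

#' @export
print.bidir_prediction <- function(x, ...) {
  cat(sprintf(
    "<bidir_prediction> %dx%d, gain=%.4g, |a|_max=%.3g (defocus a4=%.3g)\n",
    nrow(x$amplitude), ncol(x$amplitude), x$gain,
    max(abs(x$zernike_coeffs)), x$zernike_coeffs[4]))
  invisible(x)
}

#' Initial prediction from a stack
#'
#' Deterministic initialization of the reconstruction: amplitude is the
#' bicubic-upsampled square root of the LED-averaged intensity, phase is
#' zero, Zernike coefficients are zero, gain is one. Output grids are
#' `upsample` times the LR input size, amplitude is strictly nonnegative by
#' construction (softplus parameterization), and repeated calls are
#' identical.
#'
#' @param stack an `fpm_stack`
#' @param system an [optical_system()]; defaults to the stack's own
#' @param n_modes number of Zernike modes
#' @return a `bidir_prediction`
#' @export
bidir_fpm_predict <- function(stack, system = stack$system, n_modes = 15) {
  if (stack$illum$n != length(stack$images)) {
    stop("stack image count does not match its illumination set")
  }
  M <- system$hr_size
  iavg <- Reduce(`+`, stack$images) / length(stack$images)
  A0 <- bicubic_resample(sqrt(pmax(iavg, 0)), size = c(M, M))
  A0 <- pmax(A0, 1e-3)
  bidir_prediction(matrix(softplus_inv(A0), M), matrix(0, M, M),
                 numeric(n_modes), 0, system)
}

#' Forward-project a prediction to simulated measurements
#'
#' Runs the same band-limited coherent forward model as [simulate_stack()]
#' (single shared code path) on a prediction's amplitude, phase, pupil and
#' gain.
#'
#' @param pred a `bidir_prediction`
#' @param illum an `illumination_set`
#' @param system an [optical_system()]
#' @return an `fpm_stack` of simulated intensities
#' @export
forward_project <- function(pred, illum, system = pred$system) {
  field <- complex_field(pred$amplitude, pred$phase, system$hr_pixel)
  pupil <- make_pupil(system, pred$zernike_coeffs)
  simulate_stack(field, system, illum, pupil, gain = pred$gain)
}

# Raised-cosine per-LED frequency weights for synthetic-aperture fusion.
sa_weights <- function(system, illum) {
  m <- system$lr_size
  cutoff_bins <- system$cutoff / system$df
  ax <- seq_len(m) - (floor(m / 2) + 1)
  r <- sqrt(outer(ax^2, ax^2, `+`))
  rho <- r / cutoff_bins
  w <- ifelse(rho <= 1, 0.5 * (1 + cos(pi * pmin(rho, 1))), 0)
  structure(list(mask = w, support = rho <= 1, system = system,
                 illum = illum), class = "sa_weights")
}

#' Synthetic-aperture fusion of a prediction's spectrum
#'
#' Fuses the per-LED pupil-filtered sub-spectra into one enlarged synthetic
#' aperture: each LED contributes its band-pass patch at the position its
#' wave vector shifts it to, weighted by an LED-dependent raised-cosine mask
#' `W_n(f)` renormalized so that covered frequencies sum to one, and the
#' result is averaged over LEDs. The fused spectrum's support is contained
#' in the union of the shifted pupil supports; its inverse transform is the
#' synthetic-aperture field estimate.
#'
#' @param pred a `bidir_prediction`
#' @param illum an `illumination_set`
#' @param system an [optical_system()]
#' @param weights optional [sa_weights()]-style object; a user-supplied mask
#'   that is nonzero outside every shifted pupil support triggers a warning
#' @return a [complex_field()] with the fused spectrum in
#'   `attr(, "spectrum")`
#' @export
synthetic_aperture_fuse <- function(pred, illum, system = pred$system,
                                    weights = NULL) {
  if (is.null(weights)) weights <- sa_weights(system, illum)
  M <- system$hr_size
  m <- system$lr_size
  u <- pred$amplitude * exp(1i * pred$phase)
  O <- fftshift(fft2u(u))
  pupil <- make_pupil(system, pred$zernike_coeffs)
  bins <- k_to_bins(illum, system)
  w <- weights$mask
  if (any(w[!pupil$support] > 0)) {
    warning("weight mask is nonzero outside the pupil support; ",
            "those frequencies are not covered")
  }
  wtot <- matrix(0, M, M)
  for (n in seq_len(illum$n)) {
    idx <- patch_index(M, m, -bins$dr[n], -bins$dc[n])
    wtot[idx$rows, idx$cols] <- wtot[idx$rows, idx$cols] + w
  }
  Usyn <- matrix(0 + 0i, M, M)
  for (n in seq_len(illum$n)) {
    idx <- patch_index(M, m, -bins$dr[n], -bins$dc[n])
    wn <- w / pmax(wtot[idx$rows, idx$cols], .Machine$double.eps)
    wn[w == 0] <- 0
    Usyn[idx$rows, idx$cols] <- Usyn[idx$rows, idx$cols] +
      wn * pupil$p * O[idx$rows, idx$cols]
  }
  Usyn <- Usyn / illum$n
  uout <- ifft2u(ifftshift(Usyn))
  out <- complex_field(Mod(uout), Arg(uout), system$hr_pixel)
  attr(out, "spectrum") <- Usyn
  out
}

# Anisotropic L1 total variation (per-pixel mean) and its subgradient.
tv_term <- function(X) {
  n <- dim(X)
  dxc <- X[, -1, drop = FALSE] - X[, -n[2], drop = FALSE]
  dyr <- X[-1, , drop = FALSE] - X[-n[1], , drop = FALSE]
  val <- (sum(abs(dxc)) + sum(abs(dyr))) / length(X)
  g <- matrix(0, n[1], n[2])
  sx <- sign(dxc); sy <- sign(dyr)
  g[, -1] <- g[, -1, drop = FALSE] + sx
  g[, -n[2]] <- g[, -n[2], drop = FALSE] - sx
  g[-1, ] <- g[-1, , drop = FALSE] + sy
  g[-n[1], ] <- g[-n[1], , drop = FALSE] - sy
  list(value = val, grad = g / length(X))
}

# Incoherent OTF on the HR grid for the current Zernike coefficients.
hr_otf <- function(system, coeffs, mode = "incoherent") {
  intensity_otf(make_pupil(system, coeffs, grid = "hr"), mode = mode)
}

#' Loss breakdown for a prediction against a measured stack
#'
#' Computes every term of the reconstruction objective and its weighted
#' contribution: forward physics consistency `L_phys` (mean squared error
#' per image, averaged over LEDs), inverse Wiener-deconvolution consistency
#' `L_deconv` (amplitude compared to the deconvolved LED average, both
#' min-max normalized), total variation of amplitude and phase, and the
#' pupil regularizer. The report's `total` is exactly the sum of the
#' `weighted` column. The two auxiliary reconstructions (pupil-aware forward
#' images and the squared-modulus deconvolution) are attached for
#' diagnostics.
#'
#' @param stack measured `fpm_stack`
#' @param pred a `bidir_prediction`
#' @param weights a [bidir_loss_weights()]
#' @param otf_mode `"incoherent"` (default) or `"coherent"` transfer
#'   function for the deconvolution path
#' @return object of class `loss_report`
#' @export
bidir_compute_losses <- function(stack, pred, weights = bidir_loss_weights(),
                               otf_mode = "incoherent") {
  system <- pred$system
  sim <- forward_project(pred, stack$illum, system)
  n_led <- length(stack$images)
  lphys <- mean(vapply(seq_len(n_led), function(n) {
    mean((stack$images[[n]] - sim$images[[n]])^2)
  }, numeric(1)))

  iavg <- Reduce(`+`, stack$images) / n_led
  iavg_hr <- fourier_upsample(iavg, system$hr_size)
  H <- hr_otf(system, pred$zernike_coeffs, otf_mode)
  Ud <- wiener_deconvolve(iavg_hr, H, weights$alpha_wiener)
  # the deconvolved intensity average estimates |o|^2: its square root is
  # the amplitude-scale target. Consistency is enforced inside the band
  # the Wiener inverse reliably restores (so recovered super-resolved
  # content is not penalized), after least-squares gain/offset alignment
  # of the target to the amplitude (intensity scale is unobservable).
  wb <- deconv_band(H)
  Dn <- sqrt(pmax(Re(Ud), 0))
  BA <- band_filter(pred$amplitude, wb)
  BD <- band_filter(Dn, wb)
  ldeconv <- mean((BA - match_scale(BD, BA))^2)

  tvA <- tv_term(pred$amplitude)$value
  tvP <- tv_term(pred$phase)$value

  P <- make_pupil(system, pred$zernike_coeffs)$p
  D <- P - Conj(flip_spectrum(P))
  rpupil <- weights$eta1 * sum(pred$zernike_coeffs^2) +
    weights$eta2 * mean(Mod(D)^2)

  terms <- c(L_phys = lphys, L_deconv = ldeconv, TV = tvA + tvP,
             R_pupil = rpupil)
  wvec <- c(L_phys = 1, L_deconv = weights$lambda_d,
            TV = weights$lambda_tv, R_pupil = weights$lambda_p)
  weighted <- terms * wvec
  if (any(!is.finite(terms))) {
    stop("non-finite loss term: ",
         paste(names(terms)[!is.finite(terms)], collapse = ", "))
  }
  structure(list(terms = terms, weights = wvec, weighted = weighted,
                 total = sum(weighted),
                 aux = list(I_rec_A = sim$images, I_rec_B = Mod(Ud)^2)),
            class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  df <- data.frame(term = names(x$terms), value = unname(x$terms),
                   weight = unname(x$weights), weighted = unname(x$weighted))
  print(df, row.names = FALSE)
  cat(sprintf("total: %.6g\n", x$total))
  invisible(x)
}

#' Train the reconstruction on a single stack
#'
#' Per-specimen self-supervised optimization: Adam gradient descent on the
#' field parameters (softplus-amplitude and phase), the 15 Zernike
#' coefficients (piston frozen) and the log-gain, under the bidirectional
#' physics objective. During the first `freeze_epochs` the optical
#' parameters receive zero gradient. Returns the best-total-loss prediction
#' and the per-epoch loss history.
#'
#' @param stack an `fpm_stack`
#' @param config a [bidir_train_config()]
#' @param weights a [bidir_loss_weights()]
#' @param system an [optical_system()]; defaults to the stack's own
#' @param init optional starting `bidir_prediction`
#' @param extra_grad_A optional constant gradient matrix added to the
#'   amplitude gradient each epoch (joint training injects the staining
#'   loss gradient through this hook)
#' @return list with `prediction`, `history` (data frame of per-epoch loss
#'   terms), and `best_epoch`
#' @export
bidir_fpm_train <- function(stack, config = bidir_train_config(),
                          weights = bidir_loss_weights(),
                          system = stack$system, init = NULL,
                          extra_grad_A = NULL) {
  M <- system$hr_size
  m <- system$lr_size
  scale <- m / M
  n_led <- length(stack$images)
  bins <- k_to_bins(stack$illum, system)
  basis <- zernike_basis(config$n_modes, m, system$cutoff / system$df)
  ax <- seq_len(m) - (floor(m / 2) + 1)
  support <- sqrt(outer(ax^2, ax^2, `+`)) <= system$cutoff / system$df

  pred0 <- init %||% bidir_fpm_predict(stack, system, config$n_modes)
  thA <- pred0$params$thA
  phi <- pred0$params$phi
  a <- pred0$params$a
  ths <- pred0$params$ths

  # Precompute the inverse-path target (depends on the pupil; the
  # deconvolution is refreshed whenever the coefficients update, and treated
  # as constant within each gradient evaluation).
  iavg <- Reduce(`+`, stack$images) / n_led
  iavg_hr <- fourier_upsample(iavg, M)
  deconv_target <- function(coeffs) {
    H <- hr_otf(system, coeffs)
    wb <- deconv_band(H)
    Ud <- wiener_deconvolve(iavg_hr, H, weights$alpha_wiener)
    Dn <- sqrt(pmax(Re(Ud), 0))  # amplitude-scale target
    list(DnB = band_filter(Dn, wb), wb = wb)
  }
  dt <- deconv_target(a)

  adam <- function() list(m = 0, v = 0)
  st <- list(thA = adam(), phi = adam(), a = adam(), ths = adam())
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- function(p, g, s, lr, t) {
    s$m <- b1 * s$m + (1 - b1) * g
    s$v <- b2 * s$v + (1 - b2) * g^2
    mhat <- s$m / (1 - b1^t)
    vhat <- s$v / (1 - b2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), s = s)
  }

  hist_rows <- vector("list", config$epochs)
  best <- list(total = Inf, params = NULL, epoch = 0L)

  for (ep in seq_len(config$epochs)) {
    A <- matrix(softplus(thA), M)
    u <- A * exp(1i * phi)
    s_gain <- exp(ths)
    phase_z <- matrix(0, m, m)
    for (i in seq_along(a)) if (a[i] != 0) phase_z <- phase_z + a[i] * basis[, , i]
    P <- ifelse(support, 1, 0) * exp(1i * phase_z)
    P[!support] <- 0

    fw <- fpm_forward_core(u, system, bins, P, s_gain, want_fields = TRUE)

    dO <- matrix(0 + 0i, M, M)
    dP <- matrix(0 + 0i, m, m)
    ds_raw <- 0
    lphys <- 0
    for (n in seq_len(n_led)) {
      e <- fw$images[[n]] - stack$images[[n]]
      lphys <- lphys + mean(e^2)
      dI <- (2 / (n_led * m^2)) * e
      g <- fw$fields[[n]]
      ds_raw <- ds_raw + sum(dI * Mod(g)^2)
      Bg <- dI * s_gain * Conj(g)
      dS <- scale * fftshift(ifft2u(Bg))
      idx <- patch_index(M, m, -bins$dr[n], -bins$dc[n])
      dO[idx$rows, idx$cols] <- dO[idx$rows, idx$cols] + dS * P
      dP <- dP + dS * O_patch_of(fw$O, idx)
    }
    lphys <- lphys / n_led
    du <- fft2u(ifftshift(dO))
    dA <- 2 * Re(du * exp(1i * phi))
    dphi <- -2 * Im(du * u)

    # inverse-path consistency on the amplitude, inside the reliable
    # deconvolution band, with the target gain/offset-aligned to the
    # current amplitude (alignment constants carry no gradient)
    BA <- band_filter(A, dt$wb)
    resid <- BA - match_scale(dt$DnB, BA)
    ldeconv <- mean(resid^2)
    # band filter is self-adjoint (real even mask)
    dA <- dA + weights$lambda_d * 2 * band_filter(resid, dt$wb) /
      length(A)

    tvA <- tv_term(A)
    tvP <- tv_term(phi)
    dA <- dA + weights$lambda_tv * tvA$grad
    dphi <- dphi + weights$lambda_tv * tvP$grad
    if (!is.null(extra_grad_A)) dA <- dA + extra_grad_A

    # pupil regularizer
    Pf <- flip_spectrum(P)
    D <- P - Conj(Pf)
    rsym <- mean(Mod(D)^2)
    rpupil <- weights$eta1 * sum(a^2) + weights$eta2 * rsym
    da <- numeric(length(a))
    for (i in seq_along(a)) {
      Zi <- basis[, , i]
      da[i] <- 2 * Re(sum(dP * 1i * Zi * P))
      dDi <- 1i * Zi * P - Conj(1i * flip_spectrum(Zi) * Pf)
      da[i] <- da[i] + weights$lambda_p *
        (weights$eta1 * 2 * a[i] +
         weights$eta2 * (2 / m^2) * Re(sum(Conj(D) * dDi)))
    }
    da[1] <- 0  # piston is unobservable in intensity
    ds <- Re(ds_raw) * s_gain

    total <- lphys + weights$lambda_d * ldeconv +
      weights$lambda_tv * (tvA$value + tvP$value) +
      weights$lambda_p * rpupil
    if (!is.finite(total)) {
      stop(sprintf(paste0(
        "non-finite objective at epoch %d ",
        "(L_phys=%.3g, L_deconv=%.3g, TV=%.3g, R=%.3g)"),
        ep, lphys, ldeconv, tvA$value + tvP$value, rpupil))
    }
    hist_rows[[ep]] <- data.frame(epoch = ep, L_phys = lphys,
                                  L_deconv = ldeconv,
                                  TV = tvA$value + tvP$value,
                                  R_pupil = rpupil, total = total,
                                  a4 = a[4], gain = s_gain)
    if (total < best$total) {
      best <- list(total = total, params = list(thA = thA, phi = phi, a = a,
                                                ths = ths), epoch = ep)
    }

    dthA <- dA * sigmoid(thA)
    if (ep <= config$freeze_epochs) {
      da[] <- 0
      ds <- 0
    }
    r <- step(thA, dthA, st$thA, config$lr_field, ep); thA <- r$p; st$thA <- r$s
    r <- step(phi, dphi, st$phi, config$lr_field, ep); phi <- r$p; st$phi <- r$s
    r <- step(a, da, st$a, config$lr_optics, ep); a_new <- r$p; st$a <- r$s
    r <- step(ths, ds, st$ths, config$lr_optics, ep); ths <- r$p; st$ths <- r$s
    if (any(a_new != a)) {
      a <- a_new
      dt <- deconv_target(a)
    }
  }

  bp <- best$params %||% list(thA = thA, phi = phi, a = a, ths = ths)
  pred <- bidir_prediction(bp$thA, bp$phi, bp$a, bp$ths, system)
  list(prediction = pred, history = do.call(rbind, hist_rows),
       best_epoch = best$epoch)
}

O_patch_of <- function(O, idx) O[idx$rows, idx$cols]

#' Stage I to Stage II interface
#'
#' Produces the interface image `I_int = minmax(A)` in `[0, 1]` (a constant
#' amplitude maps to all zeros) and the deterministic multi-scale structural
#' features consumed by the staining encoder. Phase, pupil and gain are
#' deliberately not exported: the staining stage sees only the normalized
#' amplitude and features derived from it.
#'
#' @param pred a `bidir_prediction` (or a bare amplitude matrix)
#' @return list with `interface` (matrix in `[0,1]`) and `features`
#'   (3-scale list, see [structural_features()])
#' @export
export_interface <- function(pred) {
  A <- if (inherits(pred, "bidir_prediction")) pred$amplitude else pred
  iint <- norm01(A)
  list(interface = iint, features = structural_features(iint))
}

#' Deconvolution-only reconstruction (no learned prior)
#'
#' The inverse-physics path alone: Wiener deconvolution of the ideally
#' upsampled LED-averaged intensity under the aberration-free incoherent
#' OTF, with the square-rooted result as the amplitude estimate. Serves as
#' the "PSF-only" ablation in noise sweeps.
#'
#' @param stack an `fpm_stack`
#' @param system an [optical_system()]
#' @param alpha Wiener stabilizer
#' @return a [complex_field()] (zero phase)
#' @export
wiener_only_reconstruct <- function(stack, system = stack$system,
                                    alpha = 1e-3) {
  iavg <- Reduce(`+`, stack$images) / length(stack$images)
  iavg_hr <- fourier_upsample(iavg, system$hr_size)
  H <- hr_otf(system, numeric(15))
  Ud <- wiener_deconvolve(iavg_hr, H, alpha)
  complex_field(sqrt(pmax(Re(Ud), 0)), pixel_size = system$hr_pixel)
}
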