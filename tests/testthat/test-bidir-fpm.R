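# Physics-guided reconstruction: forward projection, synthetic aperture,
# Wiener path, loss arithmetic, gradients, and interface export.

test_that("prediction initialization meets its output contracts", {
  d <- desk_stack(hr = 48, leds = 3)
  pred <- bidir_fpm_predict(d$stack)
  expect_equal(dim(pred$amplitude), c(48, 48))
  expect_equal(dim(pred$phase), c(48, 48))
  expect_true(all(pred$amplitude >= 0))
  expect_true(all(pred$phase > -pi & pred$phase <= pi))
  pred2 <- bidir_fpm_predict(d$stack)
  expect_identical(pred$amplitude, pred2$amplitude)
  bad <- d$stack
  bad$images <- bad$images[-1]
  expect_error(bidir_fpm_predict(bad), "match")
})

test_that("forward projection is self-consistent and matches the simulator", {
  # feeding ground truth into the forward model reproduces measurements
  for (seed in 1:5) {
    d <- desk_stack(hr = 32, leds = 3, seed = seed,
                    coeffs = c(0, 0, 0, 0.2, rep(0, 11)), gain = 1.2)
    truth <- bidir_prediction_from_truth(d$phantom, d$system,
                                       c(0, 0, 0, 0.2, rep(0, 11)), 1.2)
    rep <- bidir_compute_losses(d$stack, truth)
    expect_lt(rep$terms[["L_phys"]], 1e-10)
  }
  # cross-implementation agreement on random instances
  for (seed in 6:10) {
    d <- desk_stack(hr = 32, leds = 3, seed = seed)
    pred <- bidir_fpm_predict(d$stack)
    sim <- forward_project(pred, d$illum, d$system)
    field <- complex_field(pred$amplitude, pred$phase, d$system$hr_pixel)
    ref <- simulate_stack(field, d$system, d$illum,
                          make_pupil(d$system, pred$zernike_coeffs),
                          gain = pred$gain)
    for (n in seq_along(sim$images)) {
      expect_lt(max(abs(sim$images[[n]] - ref$images[[n]])), 1e-6)
    }
  }
})

test_that("forward projection is linear in the gain", {
  d <- desk_stack(hr = 32, leds = 3, seed = 2)
  pred <- bidir_fpm_predict(d$stack)
  p2 <- pred
  p2$gain <- 2 * pred$gain
  s1 <- forward_project(pred, d$illum, d$system)
  s2 <- forward_project(p2, d$illum, d$system)
  expect_equal(s2$images[[1]], 2 * s1$images[[1]])
})

test_that("synthetic-aperture fusion preserves covered spectra", {
  # identity configuration: one on-axis LED, all-pass weights
  system <- desk_system(64)
  central <- structure(list(kx = 0, ky = 0, sin_x = 0, sin_y = 0,
                            row = 1, col = 1, n = 1),
                       class = "illumination_set")
  M <- 64
  spec <- matrix(0 + 0i, M, M)
  ctr <- M / 2 + 1
  set.seed(3)
  spec[(ctr - 2):(ctr + 2), (ctr - 2):(ctr + 2)] <-
    matrix(complex(real = rnorm(25), imaginary = rnorm(25)), 5)
  u <- ifft2u(ifftshift(spec))
  pred <- bidir_prediction_from_field(Mod(u), Arg(u), system)
  fused <- synthetic_aperture_fuse(pred, central, system)
  expect_lt(max(Mod(fused$amplitude * exp(1i * fused$phase) - u)), 1e-9)

  # multi-LED: spectrum outside every shifted pupil is exactly zero, and
  # the covered band is preserved up to the LED-count scalar
  illum <- desk_illum(system, 3)
  ph <- make_phantom("texture", 64, seed = 5)
  predt <- bidir_prediction_from_field(ph$amplitude, ph$phase, system)
  f2 <- synthetic_aperture_fuse(predt, illum, system)
  spec2 <- attr(f2, "spectrum")
  bins <- ptychostain:::k_to_bins(illum, system)
  cutoff_bins <- system$cutoff / system$df
  ax <- seq_len(M) - ctr
  covered <- matrix(FALSE, M, M)
  for (n in seq_len(illum$n)) {
    r <- sqrt(outer((ax + bins$dr[n])^2, (ax + bins$dc[n])^2, `+`))
    covered <- covered | (r <= cutoff_bins)
  }
  expect_true(all(Mod(spec2)[!covered] == 0))
  O <- fftshift(fft2u(ph$amplitude * exp(1i * ph$phase)))
  interior <- matrix(FALSE, M, M)
  r0 <- sqrt(outer(ax^2, ax^2, `+`))
  interior <- r0 <= 0.8 * cutoff_bins  # fully covered central band
  rel <- Mod(spec2 * illum$n - O)[interior] / pmax(Mod(O)[interior], 1e-9)
  expect_lt(max(rel[Mod(O)[interior] > 1e-3]), 1e-3)
})

test_that("Wiener deconvolution has the stated limits and restores blur", {
  img <- make_phantom("bars", 64, seed = 2, phase_scale = 0)$amplitude
  H1 <- matrix(1 + 0i, 64, 64)
  expect_equal(Re(wiener_deconvolve(img, H1, 0)), img, tolerance = 1e-12)
  expect_error(wiener_deconvolve(img, H1 * 0, 0), "nonzero")
  # damping limit: large alpha sends the output to zero, monotonically
  norms <- sapply(c(1, 1e2, 1e6), function(a) {
    sqrt(sum(Mod(wiener_deconvolve(img, H1, a))^2))
  })
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[3], 1e-5 * sqrt(sum(img^2)))
  # restoration gain on a Gaussian-blurred phantom with matched OTF
  sig <- 2
  ax <- ptychostain:::freq_axis(64)
  H <- exp(-2 * pi^2 * sig^2 * outer(ax^2, ax^2, `+`))
  Hc <- matrix(complex(real = H), 64)
  blurred <- Re(ifft2u(ifftshift(Hc * fftshift(fft2u(img + 0i)))))
  rec <- Re(wiener_deconvolve(blurred, Hc, 1e-3))
  expect_gt(cor(as.vector(rec), as.vector(img)),
            cor(as.vector(blurred), as.vector(img)))
})

test_that("loss arithmetic follows the stated conventions exactly", {
  # 2-LED toy with uniform per-pixel error 0.1 on 2x2 images
  imgs <- list(matrix(0.5, 2, 2), matrix(0.3, 2, 2))
  sims <- list(matrix(0.6, 2, 2), matrix(0.4, 2, 2))
  lphys <- mean(sapply(1:2, function(n) mean((imgs[[n]] - sims[[n]])^2)))
  expect_equal(lphys, 0.01)

  # constant fields have zero total variation
  expect_equal(ptychostain:::tv_term(matrix(0.7, 8, 8))$value, 0)

  # zero coefficients and an even real pupil have zero pupil penalty
  d <- desk_stack(hr = 32, leds = 3, seed = 1)
  pred <- bidir_fpm_predict(d$stack)
  rep <- bidir_compute_losses(d$stack, pred)
  expect_equal(rep$terms[["R_pupil"]], 0)
  # report total is exactly the weighted component sum
  expect_identical(rep$total, sum(rep$weighted))
  expect_true(all(rep$terms >= 0))
  expect_equal(dim(rep$aux$I_rec_B), c(32, 32))
})

test_that("analytic gradients match finite differences", {
  d <- desk_stack(hr = 32, leds = 3, seed = 5,
                  coeffs = c(0, 0, 0, 0.3, rep(0, 11)), gain = 1.3)
  st <- d$stack
  system <- d$system
  loss_at <- function(coeffs) {
    pred <- bidir_fpm_predict(st, system)
    pred$zernike_coeffs <- coeffs
    sim <- forward_project(pred, d$illum, system)
    sum(sapply(sim$images, sum))
  }
  # central finite difference of total intensity w.r.t. defocus
  h <- 1e-5
  a <- numeric(15)
  a[4] <- 0.2
  ap <- a; ap[4] <- a[4] + h
  am <- a; am[4] <- a[4] - h
  fd <- (loss_at(ap) - loss_at(am)) / (2 * h)
  # analytic counterpart assembled from the training-loop gradient pieces
  pred <- bidir_fpm_predict(st, system)
  pred$zernike_coeffs <- a
  M <- system$hr_size; m <- system$lr_size
  bins <- ptychostain:::k_to_bins(d$illum, system)
  basis <- zernike_basis(15, m, system$cutoff / system$df)
  P <- make_pupil(system, a)$p
  u <- pred$amplitude * exp(1i * pred$phase)
  fw <- ptychostain:::fpm_forward_core(u, system, bins, P, pred$gain,
                                       want_fields = TRUE)
  dP <- matrix(0 + 0i, m, m)
  for (n in seq_along(fw$images)) {
    Bg <- pred$gain * Conj(fw$fields[[n]])  # dL/dI = 1 everywhere
    dS <- (m / M) * fftshift(ifft2u(Bg))
    idx <- ptychostain:::patch_index(M, m, -bins$dr[n], -bins$dc[n])
    dP <- dP + dS * fw$O[idx$rows, idx$cols]
  }
  ana <- 2 * Re(sum(dP * 1i * basis[, , 4] * P))
  expect_equal(ana, fd, tolerance = 1e-4 * max(1, abs(fd)))
})

test_that("training recovers injected defocus and improves on bicubic", {
  d <- desk_stack(hr = 96, leds = 7, seed = 11,
                  coeffs = c(0, 0, 0, 0.5, rep(0, 11)))
  fit <- bidir_fpm_train(d$stack, bidir_train_config(epochs = 300,
                                                 freeze_epochs = 10))
  expect_lt(abs(fit$prediction$zernike_coeffs[4] - 0.5), 0.1)
  truth <- d$phantom$amplitude
  psnr_bidir <- psnr_vs(fit$prediction$amplitude, truth)
  iavg <- Reduce(`+`, d$stack$images) / length(d$stack$images)
  psnr_bic <- psnr_vs(bicubic_resample(sqrt(iavg), size = c(96, 96)),
                      truth)
  expect_gte(psnr_bidir, psnr_bic + 3)
  # optimization progressed past the freeze phase
  h <- fit$history
  expect_lte(tail(h$total, 1), h$total[10])
})

test_that("every learnable quantity receives gradient from the physics loss", {
  d <- desk_stack(hr = 32, leds = 3, seed = 3, gain = 1.4,
                  coeffs = c(0, 0.1, 0, 0.3, rep(0, 11)))
  fit <- bidir_fpm_train(d$stack, bidir_train_config(epochs = 3,
                                                 freeze_epochs = 1))
  p0 <- bidir_fpm_predict(d$stack)
  # after a few steps, the amplitude, phase, coefficients and gain all moved
  expect_gt(max(abs(fit$prediction$amplitude - p0$amplitude)), 0)
  expect_gt(max(abs(fit$prediction$phase - p0$phase)), 0)
  expect_gt(max(abs(fit$prediction$zernike_coeffs[-1])), 0)
  expect_equal(fit$prediction$zernike_coeffs[1], 0)  # piston frozen
  expect_true(fit$prediction$gain != 1)
})

test_that("interface export normalizes and is idempotent", {
  d <- desk_stack(hr = 48, leds = 3, seed = 6)
  pred <- bidir_fpm_predict(d$stack)
  out <- export_interface(pred)
  expect_gte(min(out$interface), 0)
  expect_lte(max(out$interface), 1)
  expect_length(out$features, 3)
  expect_equal(dim(out$features[[2]])[1:2], c(24, 24))
  # constant amplitude maps to all zeros
  flat <- export_interface(matrix(2, 16, 16))
  expect_true(all(flat$interface == 0))
  # idempotence of the normalization
  expect_equal(norm01(norm01(pred$amplitude)), norm01(pred$amplitude),
               tolerance = 1e-12)
})
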