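# Shared fixtures: small optical systems and phantom batteries used across
# the suite. All generation is seeded and happens at test time.

desk_system <- function(hr = 96, upsample = 4) {
  optical_system(wavelength = 505e-9, na = 0.13, magnification = 4,
                 camera_pixel_size = 6.5e-6, hr_size = hr,
                 upsample = upsample)
}

desk_illum <- function(system, rows = 7, cols = rows) {
  led_wavevectors(led_array(rows, cols, pitch = 8e-3, distance = 98e-3),
                  system)
}

# A noiseless simulated stack of a smooth texture phantom.
desk_stack <- function(hr = 96, leds = 7, seed = 11, coeffs = numeric(15),
                       gain = 1, phase_scale = pi) {
  system <- desk_system(hr)
  illum <- desk_illum(system, leds)
  ph <- make_phantom("texture", size = hr, seed = seed,
                     phase_scale = phase_scale)
  pupil <- make_pupil(system, coeffs)
  list(stack = simulate_stack(ph, system, illum, pupil, gain = gain),
       system = system, illum = illum, phantom = ph)
}

# A small paired bundle with nuclei scaled to fit the reduced field.
tiny_bundle <- function(seed, size = 32, n_cells = 2) {
  generate_bundle(tissue_phantom_spec(size = size, n_cells = n_cells,
                                      radius_range = c(3, 5),
                                      envelope = 1, seed = seed))
}

# Wrap an arbitrary (amplitude, phase) field as a prediction object.
bidir_prediction_from_field <- function(amp, phase, system,
                                      coeffs = numeric(15), gain = 1) {
  ptychostain:::bidir_prediction(
    matrix(ptychostain:::softplus_inv(pmax(amp, 1e-9)), nrow(amp)),
    phase, coeffs, log(gain), system)
}

bidir_prediction_from_truth <- function(ph, system, coeffs = numeric(15),
                                      gain = 1) {
  bidir_prediction_from_field(ph$amplitude, ph$phase, system, coeffs, gain)
}

psnr_vs <- function(est, ref) {
  a <- match_scale(est, ref)
  10 * log10(1 / mean((a - ref)^2))
}

# Independent naive metric implementations (direct formulas, loops) used as
# references for the vectorized package versions.
naive_mae <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) s <- s + abs(x[i] - y[i])
  s / length(x)
}

naive_psnr <- function(x, y, range = 1) {
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - y[i])^2
  mse <- s / length(x)
  if (mse == 0) 99 else min(99, 10 * log10(range^2 / mse))
}

naive_ssim <- function(x, y, range = 1, win = 11, sigma = 1.5) {
  r <- (win - 1) / 2
  g1 <- exp(-((-r:r)^2) / (2 * sigma^2))
  g1 <- g1 / sum(g1)
  w <- outer(g1, g1)
  C1 <- (0.01 * range)^2
  C2 <- (0.03 * range)^2
  vals <- c()
  for (i in seq(r + 1, nrow(x) - r)) {
    for (j in seq(r + 1, ncol(x) - r)) {
      wx <- x[(i - r):(i + r), (j - r):(j + r)]
      wy <- y[(i - r):(i + r), (j - r):(j + r)]
      mx <- sum(w * wx); my <- sum(w * wy)
      vx <- sum(w * wx^2) - mx^2
      vy <- sum(w * wy^2) - my^2
      cxy <- sum(w * wx * wy) - mx * my
      vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                  ((mx^2 + my^2 + C1) * (vx + vy + C2)))
    }
  }
  mean(vals)
}
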