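# Forward simulator: phantoms, stack synthesis, noise protocol.

test_that("flat object through an all-pass system gives unit intensity", {
  system <- desk_system(96)
  illum <- desk_illum(system, 3)
  field <- complex_field(matrix(1, 96, 96), pixel_size = system$hr_pixel)
  st <- simulate_stack(field, system, illum)
  central <- which(illum$row == 2 & illum$col == 2)
  expect_equal(max(abs(st$images[[central]] - 1)), 0, tolerance = 1e-10)
})

test_that("intensity is exactly linear in the gain", {
  d <- desk_stack(hr = 48, leds = 3)
  st2 <- simulate_stack(d$phantom, d$system, d$illum, gain = 2)
  for (n in seq_along(st2$images)) {
    expect_equal(st2$images[[n]], 2 * d$stack$images[[n]])
  }
  expect_error(simulate_stack(d$phantom, d$system, d$illum, gain = 0),
               "invalid")
})

test_that("band-limited objects pass the central LED unchanged", {
  system <- desk_system(64)
  illum <- desk_illum(system, 1)
  # object strictly band-limited inside the objective passband
  M <- 64
  spec <- matrix(0 + 0i, M, M)
  ctr <- M / 2 + 1
  set.seed(4)
  for (dr in -3:3) for (dc in -3:3) {
    v <- complex(real = rnorm(1, 0, 0.1), imaginary = rnorm(1, 0, 0.1))
    spec[ctr + dr, ctr + dc] <- v
    spec[ctr - dr, ctr - dc] <- Conj(v)  # Hermitian -> real object
  }
  spec[ctr, ctr] <- 8
  u <- ifft2u(ifftshift(spec))
  expect_lt(max(abs(Im(u))), 1e-10)
  amp <- Re(u)
  expect_gt(min(amp), 0)
  field <- complex_field(amp, pixel_size = system$hr_pixel)
  st <- simulate_stack(field, system, illum)
  # independent oracle: direct FFT crop of |o|^2's amplitude
  m <- system$lr_size
  idx <- ptychostain:::patch_index(M, m)
  lr_spec <- fftshift(fft2u(amp + 0i))[idx$rows, idx$cols] * (m / M)
  lr <- ifft2u(ifftshift(lr_spec))
  expect_lt(max(abs(st$images[[1]] - Mod(lr)^2)), 1e-6)
})

test_that("simulating an oblique LED equals modulating the object", {
  system <- desk_system(48)
  illum <- desk_illum(system, 3)
  ph <- make_phantom("texture", 48, seed = 2)
  st <- simulate_stack(ph, system, illum)
  bins <- ptychostain:::k_to_bins(illum, system)
  n <- which(illum$row == 1 & illum$col == 2)
  # premultiply by the bin-rounded plane wave and image through center LED
  M <- 48
  xs <- outer(rep(1, M), 0:(M - 1))
  ys <- outer(0:(M - 1), rep(1, M))
  ramp <- exp(2i * pi * (bins$dc[n] * xs + bins$dr[n] * ys) / M)
  u <- (ph$amplitude * exp(1i * ph$phase)) * ramp
  central <- structure(list(kx = 0, ky = 0, sin_x = 0, sin_y = 0,
                            row = 1, col = 1, n = 1),
                       class = "illumination_set")
  fieldm <- complex_field(Mod(u), Arg(u), system$hr_pixel)
  stm <- simulate_stack(fieldm, system, central)
  expect_lt(max(abs(stm$images[[1]] - st$images[[n]])), 1e-8)
})

test_that("pupil masking never increases image energy", {
  system <- desk_system(48)
  illum <- desk_illum(system, 3)
  ph <- make_phantom("texture", 48, seed = 9)
  energies <- sapply(c(1, 0.7, 0.45), function(frac) {
    p <- make_pupil(system)
    ax <- seq_len(p$size) - (floor(p$size / 2) + 1)
    r <- sqrt(outer(ax^2, ax^2, `+`))
    p$p[r > frac * p$cutoff_bins] <- 0
    st <- simulate_stack(ph, system, illum, p)
    sum(sapply(st$images, sum))
  })
  expect_true(all(diff(energies) <= 1e-9))
})

test_that("phantoms are reproducible, normalized, and carry geometry", {
  for (kind in c("bars", "disks", "texture")) {
    p1 <- make_phantom(kind, 64, seed = 5)
    p2 <- make_phantom(kind, 64, seed = 5)
    expect_identical(p1$amplitude, p2$amplitude)
    expect_gte(min(p1$amplitude), 0)
    expect_lte(max(p1$amplitude), 1)
  }
  bars <- make_phantom("bars", 96, seed = 1)
  expect_equal(bars$meta$finest_pitch, min(bars$meta$pitches))
  expect_error(make_phantom("nonsense", 64), "arg")
})

test_that("noise injection is seeded, scaled, and clipped", {
  d <- desk_stack(hr = 48, leds = 5, seed = 3)
  clean <- add_noise(d$stack, 0, seed = 1)
  expect_equal(max(sapply(clean$images, max)), 1)  # unit-max normalization
  n1 <- add_noise(d$stack, 1e-4, seed = 42)
  n2 <- add_noise(d$stack, 1e-4, seed = 42)
  expect_identical(n1$images, n2$images)
  expect_true(all(sapply(n1$images, min) >= 0))
  # empirical SD of the injected noise matches the nominal level
  resid <- unlist(n1$images) - unlist(clean$images)
  keep <- unlist(clean$images) > 5e-4  # clipping-free region
  expect_equal(sd(resid[keep]), 1e-4, tolerance = 0.05)
  expect_error(add_noise(d$stack, -1), ">= 0")
})

test_that("the printed benchmark protocol is wired as stated", {
  img <- make_phantom("texture", 64, seed = 8)$amplitude
  stacks <- baboon_protocol(img, noise_levels = c(0, 1e-4))
  expect_length(stacks, 2)
  expect_length(stacks[[1]]$images, 169)
  expect_equal(stacks[[1]]$protocol$cutoff, 0.13 / 505e-9,
               tolerance = 1e-6)
  expect_equal(stacks[[1]]$protocol$cutoff, 2.574e5, tolerance = 1e-3)
  # zero-noise stack equals the unit-normalized simulator output
  expect_equal(stacks[[1]]$noise_sd, 0)
})
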