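# Optics primitives: LED wave vectors, Zernike basis, pupils, transfer
# functions.

test_that("LED wave vectors follow the illumination-angle geometry", {
  system <- desk_system(96)
  geom <- led_array(13, 13, pitch = 8e-3, distance = 98e-3)
  illum <- led_wavevectors(geom, system)
  expect_equal(illum$n, 169)

  # central LED is on-axis
  central <- which(illum$row == 7 & illum$col == 7)
  expect_equal(illum$kx[central], 0)
  expect_equal(illum$ky[central], 0)

  # LED one pitch off-axis: sin(theta) = 8 / sqrt(8^2 + 98^2)
  led <- which(illum$row == 7 & illum$col == 8)
  sin_exp <- 8 / sqrt(8^2 + 98^2)
  expect_equal(illum$sin_x[led], sin_exp, tolerance = 1e-12)
  expect_equal(illum$kx[led], 2 * pi * sin_exp / 505e-9, tolerance = 1e-6)
  expect_equal(illum$kx[led], 1.0123e6, tolerance = 1e-4)

  # corner LED: offsets (48, 48) mm at 98 mm height -> NA ~ 0.570
  corner <- sqrt(2 * 48^2)
  expect_equal(illumination_na(illum), corner / sqrt(corner^2 + 98^2),
               tolerance = 1e-9)
  expect_equal(illumination_na(illum), 0.570, tolerance = 2e-3)
})

test_that("invalid LED geometry is rejected", {
  expect_error(led_array(13, 13, pitch = -1e-3, distance = 98e-3),
               "invalid")
  expect_error(led_array(13, 13, pitch = 8e-3, distance = 0), "invalid")
})

test_that("synthetic NA composes objective and illumination apertures", {
  expect_identical(synthetic_na(0.15, 0.4), 0.55)
})

test_that("Zernike modes use Noll indexing and normalization", {
  b <- zernike_basis(15, 129, 60)
  ctr <- c(65, 65)
  # piston is 1 on the disk
  expect_equal(b[ctr[1], ctr[2], 1], 1)
  inside <- b[, , 1] == 1
  expect_true(all(b[, , 1][!inside] == 0))
  # defocus at rho = 0 equals -sqrt(3)
  expect_equal(b[ctr[1], ctr[2], 4], -sqrt(3), tolerance = 1e-12)
  expect_error(zernike_basis(0, 64, 20))
})

test_that("disk-sampled Zernike modes are near-orthonormal", {
  n <- 257
  b <- zernike_basis(15, n, (n - 1) / 2)
  disk <- b[, , 1] > 0
  area <- sum(disk)
  G <- matrix(0, 15, 15)
  for (i in 1:15) for (j in i:15) {
    G[i, j] <- G[j, i] <- sum(b[, , i] * b[, , j]) / area
  }
  expect_lt(max(abs(G - diag(15))), 1e-2)
})

test_that("pupils are unimodular band-limited circ functions", {
  system <- desk_system(96)
  p0 <- make_pupil(system)
  expect_true(all(Mod(p0$p)[p0$support] == 1))
  expect_true(all(p0$p[!p0$support] == 0))
  expect_equal(max(Mod(p0$p)), 1)
  # defocus-only pupil: phase at the disk edge equals a4 * sqrt(3)
  p4 <- make_pupil(system, c(0, 0, 0, 0.5, rep(0, 11)))
  ctr <- floor(p4$size / 2) + 1
  edge_bin <- floor(p4$cutoff_bins)
  phase_edge <- Arg(p4$p[ctr, ctr + edge_bin])
  rho <- edge_bin / p4$cutoff_bins
  expect_equal(phase_edge, 0.5 * sqrt(3) * (2 * rho^2 - 1),
               tolerance = 1e-9)
  expect_error(make_pupil(system, c(NA, rep(0, 14))), "finite")
})

test_that("incoherent OTF is the normalized pupil autocorrelation", {
  system <- desk_system(96)
  pupil <- make_pupil(system)
  H <- intensity_otf(pupil)
  ctr <- floor(dim(H) / 2) + 1
  expect_equal(Re(H[ctr[1], ctr[2]]), 1, tolerance = 1e-12)
  # support doubles: zero beyond 2x cutoff, nonzero within
  ax <- seq_len(nrow(H)) - ctr[1]
  r <- sqrt(outer(ax^2, ax^2, `+`))
  expect_true(all(Mod(H)[r > 2 * pupil$cutoff_bins + 1.5] < 1e-10))
  # brute-force autocorrelation oracle: direct overlap sums of the
  # discrete aperture at a few axial shifts
  P <- Re(pupil$p)
  area <- sum(P^2)
  for (d in c(2, 5, 9)) {
    shifted <- matrix(0, nrow(P), ncol(P))
    shifted[, (d + 1):ncol(P)] <- P[, 1:(ncol(P) - d)]
    expect_equal(Re(H[ctr[1], ctr[2] + d]), sum(P * shifted) / area,
                 tolerance = 1e-10)
  }
  # continuum chord-overlap area formula (discretization-limited accuracy)
  rr <- pupil$cutoff_bins
  d_bins <- c(2, 5, 9)
  theo <- (2 * rr^2 * acos(d_bins / (2 * rr)) -
             (d_bins / 2) * sqrt(4 * rr^2 - d_bins^2)) / (pi * rr^2)
  expect_lt(max(abs(Re(H[ctr[1], ctr[2] + d_bins]) - theo)), 0.05)

  expect_identical(intensity_otf(pupil, "coherent"), pupil$p)
  empty <- pupil
  empty$p <- pupil$p * 0
  expect_error(intensity_otf(empty), "empty")
})

test_that("pupils with only odd-parity aberrations are Hermitian", {
  # odd azimuthal order modes (tilt, coma, trefoil) have odd phase, so
  # P(f) = conj(P(-f)); even modes such as defocus break the symmetry
  system <- desk_system(64)
  coeffs <- numeric(15)
  coeffs[c(2, 3, 7, 8, 9, 10)] <- c(0.4, 0.2, -0.3, 0.1, 0.05, -0.08)
  p <- make_pupil(system, coeffs)$p
  flipped <- p[c(1, nrow(p):2), c(1, ncol(p):2)]
  expect_lt(max(Mod(p - Conj(flipped))), 1e-12)
  pd <- make_pupil(system, c(0, 0, 0, 0.5, rep(0, 11)))$p
  fd <- pd[c(1, nrow(pd):2), c(1, ncol(pd):2)]
  expect_gt(max(Mod(pd - Conj(fd))), 0.1)
})

test_that("wave-vector to frequency-bin mapping round-trips within half a bin", {
  system <- desk_system(96)
  illum <- desk_illum(system, 7)
  bins <- ptychostain:::k_to_bins(illum, system)
  back <- ptychostain:::bins_to_k(bins, system)
  expect_true(all(abs(back$kx - illum$kx) <= pi * system$df + 1e-9))
  expect_true(all(abs(back$ky - illum$ky) <= pi * system$df + 1e-9))
})

test_that("LED ordering permutes wave vectors without changing their set", {
  system <- desk_system(96)
  illum <- desk_illum(system, 5)
  perm <- sample(illum$n)
  k1 <- sort(complex(real = illum$kx, imaginary = illum$ky))
  k2 <- sort(complex(real = illum$kx[perm], imaginary = illum$ky[perm]))
  expect_equal(k1, k2)
})
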