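# Fourier-optics primitives shared by the simulator and both reconstruction
# methods: optical-system description, LED geometry, illumination wave
# vectors, Zernike basis, pupil construction, transfer functions.

#' Describe the imaging system
#'
#' Bundles the optical parameters of a Fourier-ptychographic microscope: the
#' illumination wavelength, objective numerical aperture, magnification,
#' camera pixel size, and the reconstruction grid. The high-resolution (HR)
#' object grid has `upsample` times the sampling density of the captured
#' low-resolution (LR) images; the LR pixel size at the specimen plane is
#' `camera_pixel_size / magnification`.
#'
#' @param wavelength illumination wavelength in meters
#' @param na objective numerical aperture (0 < na < 1)
#' @param magnification objective magnification
#' @param camera_pixel_size physical camera pixel size in meters
#' @param hr_size side length of the square HR grid in pixels
#' @param upsample integer HR/LR sampling ratio; must divide `hr_size`
#' @return an object of class `optical_system`
#' @examples
#' sys <- optical_system(505e-9, 0.13, 4, 6.5e-6, hr_size = 96, upsample = 4)
#' sys$cutoff  # coherent cutoff NA / lambda, in 1/m
#' @export
optical_system <- function(wavelength, na, magnification, camera_pixel_size,
                           hr_size, upsample) {
  stopifnot(wavelength > 0, na > 0, na < 1, magnification > 0,
            camera_pixel_size > 0, hr_size >= 2)
  upsample <- as.integer(upsample)
  if (upsample < 1L || hr_size %% upsample != 0L) {
    stop("upsample must be a positive integer dividing hr_size")
  }
  lr_pixel <- camera_pixel_size / magnification
  hr_pixel <- lr_pixel / upsample
  cutoff <- na / wavelength                 # coherent cutoff frequency, 1/m
  nyquist_hr <- 1 / (2 * hr_pixel)
  if (cutoff >= nyquist_hr) {
    stop("pupil cutoff NA/lambda exceeds the HR grid Nyquist frequency; ",
         "increase upsample or reduce NA")
  }
  structure(list(
    wavelength = wavelength, na = na, magnification = magnification,
    camera_pixel_size = camera_pixel_size,
    hr_size = as.integer(hr_size), lr_size = as.integer(hr_size / upsample),
    upsample = upsample, lr_pixel = lr_pixel, hr_pixel = hr_pixel,
    cutoff = cutoff,
    df = 1 / (hr_size * hr_pixel)           # frequency bin width, 1/m
  ), class = "optical_system")
}

#' @export
print.optical_system <- function(x, ...) {
  cat(sprintf(
    "<optical_system> lambda=%.0f nm  NA=%.3f  mag=%gx  pixel=%.2f um\n",
    x$wavelength * 1e9, x$na, x$magnification, x$camera_pixel_size * 1e6))
  cat(sprintf("  HR %dpx (%.3f um) / LR %dpx (%.3f um), cutoff %.4g 1/m\n",
              x$hr_size, x$hr_pixel * 1e6, x$lr_size, x$lr_pixel * 1e6,
              x$cutoff))
  invisible(x)
}

#' Describe a planar LED illumination array
#'
#' @param rows,cols LED grid dimensions
#' @param pitch center-to-center LED spacing in meters
#' @param distance array-to-specimen distance in meters
#' @param center_offset lateral `(x, y)` offset of the array center from the
#'   optical axis, in meters
#' @return an object of class `led_array`
#' @export
led_array <- function(rows, cols, pitch, distance, center_offset = c(0, 0)) {
  stopifnot(rows >= 1, cols >= 1)
  if (pitch <= 0 || distance <= 0) {
    stop("invalid LED array configuration: pitch and distance must be > 0")
  }
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 pitch = pitch, distance = distance,
                 center_offset = as.numeric(center_offset)),
            class = "led_array")
}

#' Illumination wave vectors of an LED array
#'
#' Each LED at lateral offset `(dx, dy)` and height `h` below the specimen
#' illuminates with direction sines `dx/sqrt(dx^2+dy^2+h^2)` (likewise y),
#' giving the angular wave vector `k = 2*pi*sin(theta)/lambda` in rad/m.
#' LEDs are ordered row-major; the array is centered on the optical axis plus
#' `center_offset`.
#'
#' @param geom an [led_array()]
#' @param system an [optical_system()]
#' @return an object of class `illumination_set` with per-LED `kx`, `ky`
#'   (rad/m), direction sines, and row/col indices
#' @examples
#' g <- led_array(13, 13, 8e-3, 98e-3)
#' s <- optical_system(505e-9, 0.13, 4, 6.5e-6, 96, 4)
#' illum <- led_wavevectors(g, s)
#' @export
led_wavevectors <- function(geom, system) {
  if (!inherits(geom, "led_array")) stop("geom must be an led_array")
  if (system$wavelength <= 0) stop("invalid configuration: wavelength <= 0")
  i <- rep(seq_len(geom$rows), each = geom$cols)
  j <- rep(seq_len(geom$cols), times = geom$rows)
  dx <- (j - (geom$cols + 1) / 2) * geom$pitch + geom$center_offset[1]
  dy <- (i - (geom$rows + 1) / 2) * geom$pitch + geom$center_offset[2]
  h <- geom$distance
  rad <- sqrt(dx^2 + dy^2 + h^2)
  sinx <- dx / rad
  siny <- dy / rad
  structure(list(
    kx = 2 * pi * sinx / system$wavelength,
    ky = 2 * pi * siny / system$wavelength,
    sin_x = sinx, sin_y = siny,
    row = i, col = j, n = length(i)
  ), class = "illumination_set")
}

#' Illumination and synthetic numerical aperture
#'
#' `illumination_na` is the largest direction sine over the LEDs;
#' `synthetic_na` composes the objective and illumination apertures
#' additively, the standard resolution budget of Fourier ptychography.
#'
#' @param illum an `illumination_set`
#' @param objective_na,illum_na numerical apertures to compose
#' @return numeric scalar
#' @examples
#' synthetic_na(0.15, 0.4)  # 0.55
#' @export
illumination_na <- function(illum) {
  max(sqrt(illum$sin_x^2 + illum$sin_y^2))
}

#' @rdname illumination_na
#' @export
synthetic_na <- function(objective_na, illum_na) {
  stopifnot(objective_na > 0, illum_na >= 0)
  objective_na + illum_na
}

# Map illumination wave vectors to integer HR frequency-bin shifts; the
# residual sub-bin shift is returned alongside (classical FPM convention:
# spectra are displaced by whole bins).
k_to_bins <- function(illum, system) {
  fx <- illum$kx / (2 * pi)  # spatial frequency, 1/m
  fy <- illum$ky / (2 * pi)
  dc <- round(fx / system$df)
  dr <- round(fy / system$df)
  list(dr = as.integer(dr), dc = as.integer(dc),
       res_r = fy / system$df - dr, res_c = fx / system$df - dc)
}

# Bin shifts back to wave vectors (rad/m); round trip with k_to_bins is exact
# to within half a frequency bin.
bins_to_k <- function(bins, system) {
  list(kx = 2 * pi * bins$dc * system$df, ky = 2 * pi * bins$dr * system$df)
}

# Noll index -> (n, m) with sign convention: even j -> cosine (m > 0),
# odd j -> sine (m < 0); piston is j = 1.
noll_to_nm <- function(j) {
  stopifnot(j >= 1)
  n <- 0
  j1 <- j - 1
  while (j1 > n) {
    j1 <- j1 - (n + 1)
    n <- n + 1
  }
  mabs <- (n %% 2) + 2 * floor((j1 + ((n + 1) %% 2)) / 2)
  m <- if (mabs == 0) 0 else if (j %% 2 == 0) mabs else -mabs
  c(n = n, m = m)
}

# Radial Zernike polynomial R_n^m(rho), |m| <= n, (n - m) even.
zernike_radial <- function(n, m, rho) {
  m <- abs(m)
  s <- 0:((n - m) / 2)
  out <- 0
  for (k in s) {
    out <- out + (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + m) / 2 - k) * factorial((n - m) / 2 - k)) *
      rho^(n - 2 * k)
  }
  out
}

#' Zernike basis on a frequency grid
#'
#' Evaluates Noll-indexed, Noll-normalized Zernike modes `Z_1..Z_n` on the
#' pupil disk `rho = ||f|| / cutoff <= 1`, zero outside. Noll normalization
#' makes the modes orthonormal under the uniform disk measure:
#' piston is 1, defocus is `sqrt(3) (2 rho^2 - 1)`, etc.
#'
#' @param n_modes number of modes (>= 1); the package default is 15
#' @param size square grid side length in pixels
#' @param cutoff_bins pupil radius in frequency bins on that grid
#' @return array `size x size x n_modes`
#' @export
zernike_basis <- function(n_modes, size, cutoff_bins) {
  if (n_modes < 1) stop("n_modes must be >= 1")
  ax <- seq_len(size) - (floor(size / 2) + 1)
  r <- sqrt(outer(ax^2, ax^2, `+`))
  rho <- r / cutoff_bins
  theta <- atan2(outer(ax, rep(1, size)), outer(rep(1, size), ax))  # atan2(fy, fx)
  inside <- rho <= 1
  basis <- array(0, dim = c(size, size, n_modes))
  for (jmode in seq_len(n_modes)) {
    nm <- noll_to_nm(jmode)
    n <- nm[["n"]]; m <- nm[["m"]]
    R <- zernike_radial(n, m, pmin(rho, 1))
    if (m == 0) {
      Z <- sqrt(n + 1) * R
    } else if (m > 0) {
      Z <- sqrt(2 * (n + 1)) * R * cos(m * theta)
    } else {
      Z <- sqrt(2 * (n + 1)) * R * sin(-m * theta)
    }
    Z[!inside] <- 0
    basis[, , jmode] <- Z
  }
  basis
}

#' Construct a Zernike-parameterized pupil function
#'
#' `P(f) = circ(||f||/f_c) * exp(j * sum_i a_i Z_i(rho, theta))`: a binary
#' circular aperture carrying a phase aberration expanded in `length(coeffs)`
#' Noll Zernike modes (radians per mode). With all-zero coefficients the
#' pupil is the plain circ function. The piston coefficient `a_1` only adds a
#' global phase and is frozen at zero during learning.
#'
#' @param system an [optical_system()]
#' @param coeffs numeric vector of Zernike coefficients (default 15 zeros)
#' @param grid `"lr"` (default) samples the pupil on the LR-sized patch of
#'   the HR frequency lattice; `"hr"` samples on the full HR lattice
#' @return an object of class `pupil_function`: complex matrix `p`, support
#'   mask, cutoff (1/m and bins), coefficients
#' @export
make_pupil <- function(system, coeffs = numeric(15), grid = c("lr", "hr")) {
  grid <- match.arg(grid)
  if (any(!is.finite(coeffs))) stop("Zernike coefficients must be finite")
  size <- if (grid == "lr") system$lr_size else system$hr_size
  cutoff_bins <- system$cutoff / system$df
  basis <- zernike_basis(max(length(coeffs), 1L), size, cutoff_bins)
  ax <- seq_len(size) - (floor(size / 2) + 1)
  r <- sqrt(outer(ax^2, ax^2, `+`))
  support <- r <= cutoff_bins
  phase <- matrix(0, size, size)
  for (i in seq_along(coeffs)) {
    if (coeffs[i] != 0) phase <- phase + coeffs[i] * basis[, , i]
  }
  p <- ifelse(support, 1, 0) * exp(1i * phase)
  p[!support] <- 0
  structure(list(p = p, support = support, cutoff = system$cutoff,
                 cutoff_bins = cutoff_bins, coeffs = coeffs, grid = grid,
                 size = size),
            class = "pupil_function")
}

#' Intensity transfer function of a pupil
#'
#' In coherent mode the amplitude transfer function is the pupil itself.
#' In incoherent mode (the default for deconvolving an intensity average)
#' the optical transfer function is the normalized autocorrelation of the
#' pupil, `H(0) = 1`, with support twice the coherent cutoff.
#'
#' @param pupil a [make_pupil()] result or a complex matrix (DC-centered)
#' @param mode `"incoherent"` (default) or `"coherent"`
#' @return complex matrix `H(f)`, DC-centered, same size as the pupil grid
#' @export
intensity_otf <- function(pupil, mode = c("incoherent", "coherent")) {
  mode <- match.arg(mode)
  p <- if (inherits(pupil, "pupil_function")) pupil$p else pupil
  if (all(p == 0)) stop("empty pupil support")
  if (mode == "coherent") return(p)
  # linear (not circular) autocorrelation: the doubled support can exceed
  # the grid, so compute on a 2x zero-padded lattice and crop back
  n <- dim(p)
  pad <- matrix(0 + 0i, 2 * n[1], 2 * n[2])
  idx <- patch_index(2 * n[1], n[1])
  pad[idx$rows, idx$cols] <- p
  psf <- ifft2u(ifftshift(pad))          # coherent PSF (amplitude)
  h2 <- fftshift(fft2u(Mod(psf)^2))      # autocorrelation of P
  h <- h2[idx$rows, idx$cols]
  dc <- floor(n / 2) + 1
  h / h[dc[1], dc[2]]
}
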