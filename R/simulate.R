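# Forward simulator: generates multi-LED low-resolution intensity stacks from
# ground-truth complex objects with a band-limited coherent imaging model,
# plus procedural amplitude/phase phantoms and the standard noise protocol.

#' Construct a complex specimen field
#'
#' @param amplitude nonnegative real matrix
#' @param phase real matrix (radians), same shape; defaults to zeros
#' @param pixel_size physical pixel pitch in meters
#' @return object of class `complex_field`
#' @export
complex_field <- function(amplitude, phase = NULL, pixel_size = 1) {
  if (is.null(phase)) phase <- matrix(0, nrow(amplitude), ncol(amplitude))
  stopifnot(all(dim(amplitude) == dim(phase)))
  if (min(amplitude) < 0) stop("amplitude must be nonnegative")
  structure(list(amplitude = amplitude, phase = phase,
                 pixel_size = pixel_size),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field> %dx%d px, pixel %.3g m, amp [%.3g, %.3g]\n",
              nrow(x$amplitude), ncol(x$amplitude), x$pixel_size,
              min(x$amplitude), max(x$amplitude)))
  invisible(x)
}

as_complex_matrix <- function(field) field$amplitude * exp(1i * field$phase)

# Single shared implementation of the band-limited coherent forward model:
# the LED illumination shifts the object spectrum, the pupil selects
# the LR-sized patch, and the LR field is the inverse transform of that
# patch with energy-preserving scaling. Used by both the simulator and the
# learned reconstruction so the two agree exactly.
fpm_forward_core <- function(u, system, bins, P, gain, want_fields = FALSE) {
  M <- system$hr_size
  m <- system$lr_size
  scale <- m / M
  O <- fftshift(fft2u(u))
  nled <- length(bins$dr)
  images <- vector("list", nled)
  fields <- if (want_fields) vector("list", nled) else NULL
  for (n in seq_len(nled)) {
    idx <- patch_index(M, m, -bins$dr[n], -bins$dc[n])
    S <- O[idx$rows, idx$cols] * P
    g <- ifft2u(ifftshift(S)) * scale
    images[[n]] <- gain * Mod(g)^2
    if (want_fields) fields[[n]] <- g
  }
  list(images = images, fields = fields, O = O)
}

#' Procedural test phantoms
#'
#' Reproducible amplitude/phase objects standing in for resolution charts
#' and textured specimens:
#' * `"bars"` — groups of five parallel bars at geometrically decreasing
#'   pitches (resolution-chart style); the pitches are recorded in metadata.
#' * `"disks"` — random non-overlapping dark disks on a bright background.
#' * `"texture"` — Gaussian-correlated smooth random texture.
#' * `"stain-tissue"` — the grayscale interface render of a tissue phantom
#'   (see [generate_bundle()]), giving cell-like morphology.
#'
#' Amplitudes lie in `[0, 1]`. Unless `phase_scale = 0`, an
#' amplitude-correlated phase `phase_scale * amplitude` is attached, emulating
#' the optical-path-length coupling of unstained tissue.
#'
#' @param kind one of `"bars"`, `"disks"`, `"texture"`, `"stain-tissue"`
#' @param size grid side length in pixels
#' @param seed integer seed; generation is bit-reproducible
#' @param contrast amplitude range of the foreground relative to background
#' @param phase_scale multiplier mapping amplitude to phase radians
#'   (default `pi`)
#' @param pixel_size physical pixel pitch in meters
#' @return a [complex_field()] with a `meta` attribute describing geometry
#' @export
make_phantom <- function(kind = c("texture", "bars", "disks", "stain-tissue"),
                         size = 96, seed = 1, contrast = 0.8,
                         phase_scale = pi, pixel_size = 1) {
  kind <- match.arg(kind)
  amp <- with_seed(seed, switch(kind,
    "bars" = phantom_bars(size),
    "disks" = phantom_disks(size),
    "texture" = phantom_texture(size),
    "stain-tissue" = {
      spec <- tissue_phantom_spec(size = size, seed = seed)
      generate_bundle(spec)$interface
    }
  ))
  meta <- attr(amp, "meta")
  attr(amp, "meta") <- NULL
  amp <- norm01(unclass(amp)) * contrast + (1 - contrast) / 2
  field <- complex_field(amp, phase_scale * amp, pixel_size)
  field$meta <- c(list(kind = kind, seed = seed, contrast = contrast,
                       phase_scale = phase_scale), meta)
  field
}

phantom_bars <- function(size) {
  amp <- matrix(0.05, size, size)
  pitches <- c()
  pitch <- max(4L, round(size / 8))
  x0 <- 2L
  while (pitch >= 2L && x0 + 5 * pitch < size) {
    # five vertical bars of width pitch/2 at this pitch
    for (b in 0:4) {
      cols <- x0 + b * pitch + seq_len(max(1L, floor(pitch / 2))) - 1L
      cols <- cols[cols <= size]
      rows <- seq(2L, size %/% 2)
      amp[rows, cols] <- 1
    }
    pitches <- c(pitches, pitch)
    x0 <- x0 + 5L * pitch + pitch
    pitch <- max(1L, round(pitch / 2))
  }
  # horizontal bars in the lower half at the coarsest pitch
  p <- pitches[1]
  for (b in 0:4) {
    rows <- (size %/% 2 + 4L) + b * p + seq_len(max(1L, floor(p / 2))) - 1L
    rows <- rows[rows <= size]
    amp[rows, seq(2L, size - 1L)] <- 1
  }
  attr(amp, "meta") <- list(pitches = pitches, n_bars = 5L,
                            finest_pitch = min(pitches))
  amp
}

phantom_disks <- function(size, n = max(4L, size %/% 16)) {
  amp <- matrix(1, size, size)
  centers <- cbind(runif(n, 0.15, 0.85) * size, runif(n, 0.15, 0.85) * size)
  radii <- runif(n, 0.03, 0.08) * size
  xs <- matrix(rep(seq_len(size), size), size, byrow = TRUE)
  ys <- matrix(rep(seq_len(size), size), size)
  for (i in seq_len(n)) {
    d <- sqrt((xs - centers[i, 1])^2 + (ys - centers[i, 2])^2)
    amp <- pmin(amp, 0.15 + 0.85 * smoothstep((d - radii[i]) / 1.5))
  }
  attr(amp, "meta") <- list(centers = centers, radii = radii)
  amp
}

phantom_texture <- function(size, sigma = size / 32) {
  amp <- gaussian_blur(matrix(rnorm(size^2), size, size), max(1, sigma))
  attr(amp, "meta") <- list(sigma = sigma)
  amp
}

smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

#' Simulate a multi-LED FPM intensity stack
#'
#' The band-limited coherent forward model: for LED `n` with wave vector
#' `k_n`, the low-resolution intensity is
#' `I_n = s * |IFFT( P(f) * U(f - k_n) )|^2`, where `U` is the unitary FFT of
#' the complex object `A exp(j phi)`, the pupil `P` acts on the LR-sized
#' spectral patch centered at the LED's (bin-rounded) shift, and
#' downsampling is an ideal Fourier-domain crop to the LR grid.
#'
#' @param object a [complex_field()] on the HR grid
#' @param system an [optical_system()] matching the object size
#' @param pupil a [make_pupil()] on the `"lr"` grid (default aberration-free)
#' @param illum an `illumination_set` from [led_wavevectors()]
#' @param gain global intensity gain `s > 0`
#' @return object of class `fpm_stack`: list of LR intensity matrices,
#'   illumination, gain, system, and provenance metadata
#' @export
simulate_stack <- function(object, system, illum, pupil = NULL, gain = 1) {
  if (gain <= 0) stop("invalid configuration: gain s must be > 0")
  M <- system$hr_size
  if (!all(dim(object$amplitude) == c(M, M))) {
    stop("object grid does not match the system HR grid")
  }
  if (is.null(pupil)) pupil <- make_pupil(system)
  if (pupil$size != system$lr_size) {
    stop("pupil must be sampled on the LR frequency grid")
  }
  u <- as_complex_matrix(object)
  bins <- k_to_bins(illum, system)
  images <- fpm_forward_core(u, system, bins, pupil$p, gain)$images
  structure(list(images = images, illum = illum, system = system,
                 pupil_coeffs = pupil$coeffs, gain = gain, noise_sd = 0,
                 bins = bins,
                 provenance = object$meta %||% list()),
            class = "fpm_stack")
}

#' @export
print.fpm_stack <- function(x, ...) {
  cat(sprintf("<fpm_stack> N=%d images of %dx%d px, gain=%g, noise SD=%g\n",
              length(x$images), nrow(x$images[[1]]), ncol(x$images[[1]]),
              x$gain, x$noise_sd))
  invisible(x)
}

#' Add measurement noise to a stack
#'
#' Adds i.i.d. zero-mean Gaussian noise of standard deviation `sd` to every
#' image and clips negatives to zero. The stack is first rescaled so the
#' noiseless global maximum is 1 — `sd` is interpreted relative to that
#' scale, matching the convention of reporting noise levels as multiples of
#' `1e-4` on unit-normalized intensities.
#'
#' @param stack an `fpm_stack`
#' @param sd noise standard deviation (>= 0) on the unit-max scale
#' @param seed integer seed for reproducibility
#' @return a new `fpm_stack` with noise metadata recorded
#' @export
add_noise <- function(stack, sd, seed = 1) {
  if (sd < 0) stop("noise sd must be >= 0")
  mx <- max(vapply(stack$images, max, numeric(1)))
  if (mx <= 0) mx <- 1
  out <- stack
  out$images <- lapply(stack$images, function(im) im / mx)
  out$gain <- stack$gain / mx
  if (sd > 0) {
    out$images <- with_seed(seed, lapply(out$images, function(im) {
      pmax(im + matrix(rnorm(length(im), 0, sd), nrow(im)), 0)
    }))
  }
  out$noise_sd <- sd
  out$noise_seed <- seed
  out
}

#' The printed simulation protocol for a reference image
#'
#' Builds the benchmark optical configuration — 4x magnification, NA 0.13,
#' 6.5 um camera pixels, 505 nm illumination, a 13x13 LED array 98 mm below
#' the specimen with 8 mm pitch — and emits one noisy stack per requested
#' noise standard deviation.
#'
#' @param image HR amplitude matrix (values normalized to `[0, 1]`)
#' @param noise_levels noise SDs; default `{0, 0.2, ..., 1.0} * 1e-4`
#' @param upsample HR/LR sampling ratio (default 4)
#' @param phase_scale amplitude-to-phase coupling; default 0, treating the
#'   reference image as a pure amplitude object as the printed protocol does
#' @param seed base seed; stack for noise level `i` uses `seed + i`
#' @return list of `fpm_stack` objects, one per noise level, each carrying
#'   the cutoff frequency and protocol parameters in metadata
#' @export
baboon_protocol <- function(image, noise_levels = seq(0, 1e-4, by = 0.2e-4),
                            upsample = 4, phase_scale = 0, seed = 1) {
  size <- nrow(image)
  system <- optical_system(wavelength = 505e-9, na = 0.13, magnification = 4,
                           camera_pixel_size = 6.5e-6, hr_size = size,
                           upsample = upsample)
  geom <- led_array(13, 13, pitch = 8e-3, distance = 98e-3)
  illum <- led_wavevectors(geom, system)
  field <- complex_field(norm01(image), phase_scale * norm01(image),
                         system$hr_pixel)
  clean <- simulate_stack(field, system, illum)
  out <- lapply(seq_along(noise_levels), function(i) {
    st <- add_noise(clean, noise_levels[i], seed = seed + i)
    st$protocol <- list(cutoff = system$cutoff, na = 0.13,
                        wavelength = 505e-9, noise_sd = noise_levels[i])
    st
  })
  names(out) <- sprintf("sd_%g", noise_levels)
  out
}
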