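# Procedural tissue phantoms: paired (interface image, LAP2, DAPI, panCK,
# H&E) bundles whose channel geometry realizes the biological relations the
# cross-task losses assume — DAPI marks nucleus interiors, LAP2 the nuclear
# envelopes (annuli), panCK the epithelial cytoplasm away from nuclei, and
# H&E agrees with DAPI inside nuclei. LAP2 and panCK supports are disjoint
# exactly, by construction.

#' Specification of a tissue phantom
#'
#' @param size square image side in pixels (divisible by 4)
#' @param n_cells number of nuclei to place (non-overlapping disks)
#' @param radius_range nucleus radius range in pixels
#' @param envelope nuclear-envelope (LAP2 annulus) thickness in pixels
#' @param epithelial_fraction approximate area fraction of the epithelial
#'   (panCK-positive) region, in `[0, 1]`
#' @param texture_noise amplitude of the mild texture on the interface image
#' @param hard_edges use binary (non-anti-aliased) stain targets
#' @param seed integer seed; generation is bit-reproducible
#' @return object of class `tissue_phantom_spec`
#' @export
tissue_phantom_spec <- function(size = 96, n_cells = 8,
                                radius_range = c(5, 9), envelope = 2,
                                epithelial_fraction = 0.5,
                                texture_noise = 0.05, hard_edges = FALSE,
                                seed = 1) {
  stopifnot(size %% 4 == 0, n_cells >= 0, envelope >= 1,
            radius_range[1] > envelope,
            epithelial_fraction >= 0, epithelial_fraction <= 1)
  structure(list(size = as.integer(size), n_cells = as.integer(n_cells),
                 radius_range = radius_range, envelope = envelope,
                 epithelial_fraction = epithelial_fraction,
                 texture_noise = texture_noise, hard_edges = hard_edges,
                 seed = as.integer(seed)),
            class = "tissue_phantom_spec")
}

# Non-overlapping disk packing by bounded rejection sampling.
pack_disks <- function(n, size, radius_range, clearance, max_tries = 2000) {
  centers <- matrix(0, 0, 2)
  radii <- numeric(0)
  tries <- 0
  while (length(radii) < n) {
    tries <- tries + 1
    if (tries > max_tries) {
      stop("infeasible nucleus packing: too many cells for the field size")
    }
    r <- runif(1, radius_range[1], radius_range[2])
    margin <- r + clearance + 1
    if (2 * margin >= size) {
      stop("infeasible nucleus packing: too many cells for the field size")
    }
    cx <- runif(1, margin, size - margin)
    cy <- runif(1, margin, size - margin)
    ok <- TRUE
    if (length(radii) > 0) {
      d <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
      ok <- all(d > radii + r + 2 * clearance + 2)
    }
    if (ok) {
      centers <- rbind(centers, c(cx, cy))
      radii <- c(radii, r)
    }
  }
  list(centers = centers, radii = radii)
}

#' Generate a paired stain bundle
#'
#' Produces co-registered, `[0, 1]`-valued stain channels plus the grayscale
#' interface image of the same geometry:
#' * `dapi` — anti-aliased disk interiors (nuclei);
#' * `lap2` — annular envelopes around the same nuclei;
#' * `panck` — the epithelial region minus all nuclei-with-envelopes
#'   (`lap2 * panck == 0` everywhere, exactly);
#' * `he` — grayscale morphology render that equals `dapi` inside nuclear
#'   regions and shows lighter cytoplasm elsewhere.
#'
#' With `n_cells = 0` the nuclear channels are all-zero and `panck` equals
#' the epithelial mask.
#'
#' @param spec a [tissue_phantom_spec()]
#' @return object of class `stain_bundle`: `interface`, `channels`
#'   (named list `lap2`, `dapi`, `panck`, `he`), and `geometry` metadata
#' @export
generate_bundle <- function(spec) {
  stopifnot(inherits(spec, "tissue_phantom_spec"))
  with_seed(spec$seed, {
    n <- spec$size
    aa <- if (spec$hard_edges) 1e-6 else 1.2  # anti-alias width in px
    xs <- matrix(rep(seq_len(n), n), n, byrow = TRUE)
    ys <- matrix(rep(seq_len(n), n), n)

    # epithelial region: thresholded smooth random field
    blob <- gaussian_blur(matrix(rnorm(n^2), n), n / 10)
    thr <- stats::quantile(blob, 1 - spec$epithelial_fraction)
    epi <- smoothstep((blob - thr) / (stats::sd(blob) * 0.2 + 1e-9))
    if (spec$epithelial_fraction >= 1) epi <- matrix(1, n, n)

    dapi <- matrix(0, n, n)
    lap2 <- matrix(0, n, n)
    excl <- matrix(0, n, n)  # nuclei + envelopes, for carving panCK
    geom <- list(centers = matrix(0, 0, 2), radii = numeric(0))
    if (spec$n_cells > 0) {
      geom <- pack_disks(spec$n_cells, n, spec$radius_range, spec$envelope)
      for (i in seq_along(geom$radii)) {
        d <- sqrt((xs - geom$centers[i, 1])^2 + (ys - geom$centers[i, 2])^2)
        r <- geom$radii[i]
        dapi <- pmax(dapi, smoothstep((r - d) / aa))
        ring <- smoothstep((d - r) / aa) *
          smoothstep((r + spec$envelope - d) / aa)
        lap2 <- pmax(lap2, ring)
        excl <- pmax(excl,
                     smoothstep((r + spec$envelope + 2 * aa - d) / aa))
      }
    }
    panck <- epi * (1 - excl)
    panck[lap2 > 0] <- 0  # exact exclusivity with the envelope marker

    cyto <- 0.35 * epi + 0.15
    blend <- 1 - smoothstep((dapi - 0.2) / 0.3)  # ->0 inside nuclei
    he <- pmin(pmax(dapi + blend * cyto, 0), 1)

    texture <- gaussian_blur(matrix(rnorm(n^2), n), 1.5)
    interface <- 0.55 + 0.20 * epi - 0.40 * dapi - 0.15 * lap2 +
      spec$texture_noise * texture / max(abs(texture))
    interface <- pmin(pmax(interface, 0), 1)

    structure(list(interface = interface,
                   channels = list(lap2 = lap2, dapi = dapi,
                                   panck = panck, he = he),
                   geometry = c(geom, list(epithelial = epi)),
                   spec = spec),
              class = "stain_bundle")
  })
}

#' @export
print.stain_bundle <- function(x, ...) {
  cat(sprintf("<stain_bundle> %dx%d, %d nuclei, channels: %s\n",
              nrow(x$interface), ncol(x$interface),
              length(x$geometry$radii),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' FPM degradation of a stain bundle
#'
#' Uses the bundle's interface image as the high-resolution amplitude of a
#' complex object (with the default amplitude-correlated phase), simulates
#' the multi-LED low-resolution stack under the given optics, and returns
#' the stack alongside the untouched stain targets — the input pairing for
#' full-pipeline (reconstruct, then stain) experiments.
#'
#' @param bundle a `stain_bundle`
#' @param system an [optical_system()] whose HR grid equals the bundle size
#' @param illum an `illumination_set`
#' @param noise_sd Gaussian noise SD on unit-max intensities (0 = clean)
#' @param phase_scale amplitude-to-phase coupling
#' @param seed noise seed
#' @return list with `stack` (an `fpm_stack`) and `bundle` (unchanged)
#' @export
degrade_bundle <- function(bundle, system, illum, noise_sd = 0,
                           phase_scale = pi, seed = 1) {
  field <- complex_field(bundle$interface, phase_scale * bundle$interface,
                         system$hr_pixel)
  stack <- simulate_stack(field, system, illum)
  stack <- add_noise(stack, noise_sd, seed)  # also normalizes to unit max
  list(stack = stack, bundle = bundle)
}

#' Generate a seeded dataset of paired bundles
#'
#' Bundles are generated from disjoint seed ranges per split (train /
#' validation / test), mirroring slide-level separation: no geometry is
#' shared across splits.
#'
#' @param n total number of bundles
#' @param size image side in pixels
#' @param seed base seed
#' @param split proportions for train/val/test (sums to 1)
#' @param ... further arguments to [tissue_phantom_spec()]
#' @return list with elements `train`, `val`, `test` (lists of bundles)
#' @export
gen_tissue_dataset <- function(n, size = 96, seed = 1,
                               split = c(0.7, 0.15, 0.15), ...) {
  stopifnot(abs(sum(split) - 1) < 1e-9)
  counts <- c(floor(split[1] * n), floor(split[2] * n))
  counts <- c(counts, n - sum(counts))
  offsets <- c(0, 10000, 20000)  # disjoint seed ranges per split
  out <- lapply(1:3, function(k) {
    lapply(seq_len(counts[k]), function(i) {
      generate_bundle(tissue_phantom_spec(size = size,
                                          seed = seed + offsets[k] + i, ...))
    })
  })
  names(out) <- c("train", "val", "test")
  out
}
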