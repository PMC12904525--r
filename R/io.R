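# File I/O: multi-page 16-bit TIFF for image stacks and stain channels
# (with JSON sidecars carrying scale factors and acquisition metadata),
# RDS for lossless complex fields, JSON for metric logs.

#' Write / read an FPM stack as multi-page TIFF + JSON sidecar
#'
#' Images are stored as 16-bit TIFF pages scaled by the recorded
#' `scale` (the global maximum); the sidecar holds wave vectors, gain,
#' noise metadata and the scale, so the round trip recovers intensities to
#' within 16-bit quantization.
#'
#' @param stack an `fpm_stack`
#' @param path output `.tif` path (the sidecar gets `.json` appended)
#' @return `path`, invisibly
#' @export
write_stack_tiff <- function(stack, path) {
  mx <- max(vapply(stack$images, max, numeric(1)))
  if (mx <= 0) mx <- 1
  pages <- lapply(stack$images, function(im) pmin(pmax(im / mx, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  meta <- list(scale = mx, gain = stack$gain, noise_sd = stack$noise_sd,
               kx = stack$illum$kx, ky = stack$illum$ky,
               n = stack$illum$n)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  images <- lapply(pages, function(p) p * meta$scale)
  illum <- structure(list(kx = meta$kx, ky = meta$ky, n = meta$n,
                          sin_x = NULL, sin_y = NULL),
                     class = "illumination_set")
  structure(list(images = images, illum = illum, gain = meta$gain,
                 noise_sd = meta$noise_sd, system = NULL),
            class = "fpm_stack")
}

#' Lossless storage of complex fields and predictions
#'
#' @param x any reconstruction object (e.g. [complex_field()],
#'   `bidir_prediction`)
#' @param path `.rds` path
#' @return `path` / the restored object
#' @export
write_field <- function(x, path) {
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) readRDS(path)

#' Write / read a stain bundle as one TIFF per channel
#'
#' Layout: `<dir>/<id>_input.tif` for the interface image and
#' `<dir>/<id>_<channel>.tif` for `lap2`, `dapi`, `panck`, `he`
#' (16-bit, values clipped to `[0, 1]`).
#'
#' @param bundle a `stain_bundle`
#' @param dir output directory (created if needed)
#' @param id sample identifier used as the filename prefix
#' @return the directory / the restored `stain_bundle`
#' @export
write_bundle <- function(bundle, dir, id = "sample") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  clip <- function(m) pmin(pmax(m, 0), 1)
  tiff::writeTIFF(clip(bundle$interface),
                  file.path(dir, paste0(id, "_input.tif")),
                  bits.per.sample = 16)
  for (ch in names(bundle$channels)) {
    tiff::writeTIFF(clip(bundle$channels[[ch]]),
                    file.path(dir, paste0(id, "_", ch, ".tif")),
                    bits.per.sample = 16)
  }
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir, id = "sample") {
  iint <- tiff::readTIFF(file.path(dir, paste0(id, "_input.tif")))
  channels <- lapply(STAIN_CHANNELS, function(ch) {
    tiff::readTIFF(file.path(dir, paste0(id, "_", ch, ".tif")))
  })
  names(channels) <- STAIN_CHANNELS
  structure(list(interface = iint, channels = channels, geometry = NULL,
                 spec = NULL),
            class = "stain_bundle")
}

#' Render a two-color display version of an H&E channel
#'
#' Maps the single grayscale H&E channel to a fixed
#' hematoxylin/eosin-style RGB rendering (dark purple nuclei, pink
#' cytoplasm). Display only: the quantitative channel remains grayscale.
#'
#' @param he matrix in `[0, 1]`
#' @return `H x W x 3` RGB array in `[0, 1]`
#' @export
render_he_rgb <- function(he) {
  he <- pmin(pmax(he, 0), 1)
  rgb <- array(0, dim = c(dim(he), 3))
  # background white, low values pink (eosin), high values purple
  rgb[, , 1] <- 1 - 0.25 * he - 0.35 * he^2
  rgb[, , 2] <- 1 - 0.75 * he
  rgb[, , 3] <- 1 - 0.15 * he - 0.25 * he^2
  pmin(pmax(rgb, 0), 1)
}

#' Write a JSON metrics log
#'
#' @param x named list / data frame of metrics
#' @param path output `.json` path
#' @return `path`, invisibly
#' @export
write_metrics_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_metrics_json
#' @export
read_metrics_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
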