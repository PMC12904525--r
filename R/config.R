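# YAML run configuration: schema-validated blocks for optics, LED array,
# reconstruction and staining, with the published defaults filled in.

default_run_config <- function() {
  list(
    optics = list(wavelength_nm = 505, na = 0.13, magnification = 4,
                  pixel_um = 6.5, hr_size = 96, upsample = 4),
    array = list(rows = 13, cols = 13, pitch_mm = 8, distance_mm = 98),
    reconstruction = list(method = "bidir-fpm", epochs = 200, iters = 20,
                          freeze_epochs = 10, lr = 2e-4,
                          lambda_d = 0.1, lambda_tv = 1e-4,
                          lambda_p = 1e-3, alpha_wiener = 1e-3),
    staining = list(lambda1 = 10.0, lambda2 = 0.2, lambda3 = 1.0,
                    alpha = 1.0, beta = 0.5, gamma = 0.2, tau = 0.5,
                    lambda_s = 0.5, lambda_s_start = 0.1,
                    warmup_epochs = 10, lr = 1e-4, batch = 8,
                    epochs = 150),
    seed = 1
  )
}

nonneg_keys <- c("lambda_d", "lambda_tv", "lambda_p", "alpha_wiener",
                 "lambda1", "lambda2", "lambda3", "alpha", "beta", "gamma",
                 "lambda_s", "lambda_s_start", "lr")

#' Load (and validate) a run configuration
#'
#' Reads a YAML file with optional blocks `optics`, `array`,
#' `reconstruction`, `staining` and scalar `seed`; missing values are
#' filled from the published defaults (loss weights 10.0 / 0.2 / 1.0,
#' cross-task 1.0 / 0.5 / 0.2, regularizers 1e-4 / 1e-3, deconvolution
#' weight 0.1, warm-up 0.1 to 0.5 over 10 epochs, learning rates 2e-4 and
#' 1e-4, batch 8). Unknown keys and negative weights are rejected.
#'
#' @param path YAML file path; an empty or missing-block file yields the
#'   full default configuration
#' @return a validated nested configuration list of class `run_config`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- default_run_config()
  bad <- setdiff(names(user), c(names(defaults)))
  if (length(bad) > 0) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  }
  for (blk in intersect(names(user), names(defaults))) {
    if (is.list(defaults[[blk]])) {
      extra <- setdiff(names(user[[blk]]), names(defaults[[blk]]))
      if (length(extra) > 0) {
        stop(sprintf("unknown keys in '%s': %s", blk,
                     paste(extra, collapse = ", ")))
      }
    }
  }
  cfg <- modifyList(defaults, user)
  for (blk in c("reconstruction", "staining")) {
    for (k in intersect(names(cfg[[blk]]), nonneg_keys)) {
      if (cfg[[blk]][[k]] < 0) {
        stop(sprintf("negative weight '%s' in '%s'", k, blk))
      }
    }
  }
  with(cfg$optics, stopifnot(wavelength_nm > 0, na > 0, na < 1))
  with(cfg$array, stopifnot(rows >= 1, cols >= 1, pitch_mm > 0,
                            distance_mm > 0))
  structure(cfg, class = "run_config")
}

#' Save a run configuration
#'
#' @param cfg configuration list
#' @param path output YAML path
#' @return `path`, invisibly
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Instantiate optics objects from a configuration
#'
#' @param cfg a `run_config`
#' @return list with `system` ([optical_system()]), `geom` ([led_array()])
#'   and `illum` ([led_wavevectors()])
#' @export
config_optics <- function(cfg) {
  system <- optical_system(cfg$optics$wavelength_nm * 1e-9, cfg$optics$na,
                           cfg$optics$magnification,
                           cfg$optics$pixel_um * 1e-6,
                           cfg$optics$hr_size, cfg$optics$upsample)
  geom <- led_array(cfg$array$rows, cfg$array$cols,
                    cfg$array$pitch_mm * 1e-3, cfg$array$distance_mm * 1e-3)
  list(system = system, geom = geom, illum = led_wavevectors(geom, system))
}
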