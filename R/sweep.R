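# Evaluation harnesses: the noise-robustness sweep over reconstruction
# methods and the staining-model ablation study.

SWEEP_METHODS <- c("bicubic", "ap-epry", "bidir-fpm", "bidir-fpm-psf-only",
                   "bidir-fpm-pbnn-only")

# One reconstruction by the named method; returns the amplitude estimate
# least-squares matched to the reference scale.
reconstruct_by_method <- function(method, stack, system, truth_amp,
                                  ap_iters = 20, bidir_epochs = 120) {
  amp <- switch(method,
    "bicubic" = {
      iavg <- Reduce(`+`, stack$images) / length(stack$images)
      bicubic_resample(sqrt(pmax(iavg, 0)),
                       size = c(system$hr_size, system$hr_size))
    },
    "ap-epry" = {
      ap_epry_reconstruct(stack, system,
                          ap_config(n_iterations = ap_iters))$field$amplitude
    },
    "bidir-fpm" = {
      bidir_fpm_train(stack, bidir_train_config(epochs = bidir_epochs),
                    bidir_loss_weights())$prediction$amplitude
    },
    "bidir-fpm-pbnn-only" = {
      # physics network without the PSF/deconvolution supervision
      bidir_fpm_train(stack, bidir_train_config(epochs = bidir_epochs),
                    bidir_loss_weights(lambda_d = 0))$prediction$amplitude
    },
    "bidir-fpm-psf-only" = {
      # Wiener inverse path only, no learned prior
      wiener_only_reconstruct(stack, system)$amplitude
    },
    stop("unknown method: ", method))
  match_scale(amp, truth_amp)
}

#' Noise-robustness sweep
#'
#' Reconstructs a battery of `n_patches` seeded phantoms at each noise
#' level with each method and reports mean and SD of MAE / PSNR / SSIM
#' (and the critic score when a critic is supplied) against the
#' ground-truth amplitude.
#'
#' @param methods subset of
#'   `c("bicubic", "ap-epry", "bidir-fpm", "bidir-fpm-psf-only",
#'   "bidir-fpm-pbnn-only")`; the last two disable the learned prior and the
#'   deconvolution supervision, respectively
#' @param system an [optical_system()]
#' @param illum an `illumination_set`
#' @param noise_levels noise SDs (default `{0, 0.2, ..., 1} * 1e-4`)
#' @param n_patches phantom patches per cell (>= 2, or SD is undefined)
#' @param seed battery seed (phantom `i` uses `seed + i`)
#' @param phantom_kind [make_phantom()] kind for the battery
#' @param phase_scale phantom amplitude-to-phase coupling; the default 0
#'   mirrors the printed benchmark protocol, which measures reconstruction
#'   fidelity against a reference image used as a pure amplitude object
#' @param critic optional trained critic: adds a quality column computed
#'   with the locally trained synthetic-distortion critic (not comparable
#'   to externally trained quality scores)
#' @param ap_iters,bidir_epochs method budgets
#' @return object of class `sweep_result`: long-format data frame with
#'   per-cell mean/sd plus the per-patch values in `attr(, "raw")`
#' @export
noise_sweep <- function(methods = SWEEP_METHODS, system, illum,
                        noise_levels = seq(0, 1e-4, by = 0.2e-4),
                        n_patches = 3, seed = 1, phantom_kind = "texture",
                        phase_scale = 0, critic = NULL, ap_iters = 20,
                        bidir_epochs = 120) {
  stopifnot(all(methods %in% SWEEP_METHODS))
  if (n_patches < 2) stop("n_patches must be >= 2 (SD undefined otherwise)")
  raw <- list()
  for (pi in seq_len(n_patches)) {
    ph <- make_phantom(phantom_kind, size = system$hr_size,
                       seed = seed + pi, phase_scale = phase_scale)
    clean <- simulate_stack(ph, system, illum)
    for (nl in noise_levels) {
      st <- add_noise(clean, nl, seed = seed * 1000 + pi)
      for (me in methods) {
        amp <- reconstruct_by_method(me, st, system, ph$amplitude,
                                     ap_iters, bidir_epochs)
        m <- image_metrics(pmin(pmax(amp, 0), 1), ph$amplitude)
        row <- data.frame(method = me, noise = nl, patch = pi,
                          mae = m["mae"], psnr = m["psnr"],
                          ssim = m["ssim"])
        if (!is.null(critic)) {
          row$dpiqa <- dpiqa_assess(critic,
                                    pmin(pmax(amp, 0), 1))$q_main
        }
        raw[[length(raw) + 1]] <- row
      }
    }
  }
  raw <- do.call(rbind, raw)
  rownames(raw) <- NULL
  metrics <- intersect(c("mae", "psnr", "ssim", "dpiqa"), names(raw))
  agg <- do.call(rbind, lapply(split(raw, raw[c("method", "noise")]),
    function(d) {
      if (nrow(d) == 0) return(NULL)
      out <- data.frame(method = d$method[1], noise = d$noise[1],
                        n = nrow(d))
      for (m in metrics) {
        out[[paste0(m, "_mean")]] <- mean(d[[m]])
        out[[paste0(m, "_sd")]] <- sd(d[[m]])
      }
      out
    }))
  rownames(agg) <- NULL
  attr(agg, "raw") <- raw
  class(agg) <- c("sweep_result", class(agg))
  agg
}

#' Ablation study variants
#'
#' The staining-model ablation axes: single-component removals, the
#' single-task (four independent generators) variant, the decoupled
#' training variant, and the Stage-I feature-fusion toggle (with
#' `"Stage-I features"` naming the feature-fused configuration explicitly).
#'
#' @return character vector of variant names
#' @export
ablation_variants <- function() {
  c("full", "w/o WTConv", "w/o FS-FF", "w/o SE block", "w/o DP Net",
    "Single-task", "w/o Joint Training", "w/o Stage-I features",
    "Stage-I features")
}

variant_config <- function(variant, base = stain_net_config()) {
  cfg <- base
  switch(variant,
    "full" = , "Stage-I features" = , "w/o Joint Training" = cfg,
    "w/o WTConv" = { cfg$use_wtconv <- FALSE; cfg },
    "w/o FS-FF" = { cfg$use_fsff <- FALSE; cfg },
    "w/o SE block" = { cfg$use_se <- FALSE; cfg },
    "w/o DP Net" = { cfg$use_dpiqa <- FALSE; cfg },
    "Single-task" = { cfg$single_task <- TRUE; cfg },
    "w/o Stage-I features" = { cfg$use_features <- FALSE; cfg },
    stop("unknown ablation variant: ", variant))
}

#' Ablation harness for the staining model
#'
#' Trains each requested variant on the training pairs and evaluates SSIM
#' and MAE per stain channel on the test pairs. All variants except
#' `"w/o Joint Training"` train the staining stage on ground-truth
#' interface images; `"w/o Joint Training"` (and `"full"`, for the
#' comparison to be meaningful) can instead be trained through the full
#' degraded pipeline by supplying `degraded` samples.
#'
#' @param variants subset of [ablation_variants()] (default all)
#' @param train_pairs,test_pairs lists of `stain_bundle`s
#' @param base a base [stain_net_config()] (seed included)
#' @param critic optional frozen critic for variants with the perceptual
#'   term
#' @param epochs,lr training budget per variant
#' @param degraded optional list of [degrade_bundle()] outputs enabling the
#'   joint/decoupled comparison
#' @param joint_epochs,recon_epochs budgets for the pipeline-level variants
#' @return data frame: one row per variant with per-channel SSIM and MAE
#' @export
ablation_harness <- function(variants = ablation_variants(), train_pairs,
                             test_pairs, base = stain_net_config(),
                             critic = NULL, epochs = 10, lr = 1e-3,
                             degraded = NULL, joint_epochs = 4,
                             recon_epochs = 2) {
  stopifnot(all(variants %in% ablation_variants()))
  rows <- lapply(variants, function(vn) {
    cfg <- variant_config(vn, base)
    uses_pipeline <- vn == "w/o Joint Training" && !is.null(degraded)
    if (uses_pipeline) {
      fit <- train_joint(degraded, cfg, critic = critic,
                         epochs = joint_epochs,
                         recon_epochs = recon_epochs, lr = lr,
                         joint = FALSE, seed = cfg$seed)
      model <- fit$model
    } else {
      model <- train_stain(train_pairs, cfg, critic = critic,
                           epochs = epochs, lr = lr, seed = cfg$seed)
    }
    out <- data.frame(variant = vn)
    for (ch in STAIN_CHANNELS) {
      vs <- sapply(test_pairs, function(b) {
        pred <- stain_predict(model, b$interface)
        m <- image_metrics(pred$channels[[ch]], b$channels[[ch]])
        c(m["ssim"], m["mae"])
      })
      out[[paste0("ssim_", ch)]] <- mean(vs[1, ])
      out[[paste0("mae_", ch)]] <- mean(vs[2, ])
    }
    out
  })
  do.call(rbind, rows)
}
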