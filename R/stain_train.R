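# Training loops for the staining stage: paired-supervised GAN training of
# the multi-task generator, and joint end-to-end training coupling the
# self-supervised reconstruction with the staining objective through a
# warm-up-scheduled balance weight.

augment_bundle <- function(iint, channels) {
  fliph <- runif(1) < 0.5
  flipv <- runif(1) < 0.5
  rotk <- sample(0:3, 1)
  jitter <- runif(1, -0.1, 0.1)
  tf <- function(m) {
    if (fliph) m <- m[, rev(seq_len(ncol(m)))]
    if (flipv) m <- m[rev(seq_len(nrow(m))), ]
    if (rotk > 0) for (k in seq_len(rotk)) m <- t(m[rev(seq_len(nrow(m))), ])
    m
  }
  list(iint = pmin(pmax(tf(iint) + jitter, 0), 1),
       channels = lapply(channels, tf))
}

new_stain_model <- function(cfg, feat_ch = 2) {
  if (cfg$single_task) {
    gens <- lapply(seq_along(STAIN_CHANNELS), function(i) {
      ci <- cfg; ci$seed <- cfg$seed + i
      stain_generator_new(ci, out_ch = 1, feat_ch = feat_ch)
    })
    names(gens) <- STAIN_CHANNELS
  } else {
    gens <- list(shared = stain_generator_new(cfg, out_ch = 4,
                                              feat_ch = feat_ch))
  }
  discs <- lapply(seq_along(STAIN_CHANNELS), function(i) {
    ci <- cfg; ci$seed <- cfg$seed + 100 + i
    patchgan_new(ci)
  })
  names(discs) <- STAIN_CHANNELS
  structure(list(cfg = cfg, gens = gens, discs = discs), class = "stain_model")
}

model_predict <- function(model, iint, feats = NULL) {
  cfg <- model$cfg
  if (cfg$use_features && is.null(feats)) feats <- structural_features(iint)
  if (cfg$single_task) {
    preds <- lapply(model$gens, function(g) {
      stain_generate(g, cfg, iint, feats)$y[, , 1]
    })
    out <- array(0, dim = c(dim(iint), 4))
    for (i in seq_along(STAIN_CHANNELS)) out[, , i] <- preds[[i]]
    out
  } else {
    stain_generate(model$gens$shared, cfg, iint, feats)$y
  }
}

#' Predict stains for an interface image
#'
#' @param model a trained `stain_model` (see [train_stain()])
#' @param iint interface image in `[0, 1]`
#' @return a `stain_bundle` with predicted channels
#' @export
stain_predict <- function(model, iint) {
  y <- model_predict(model, iint)
  structure(list(interface = iint,
                 channels = setNames(lapply(seq_len(4), function(i) y[, , i]),
                                     STAIN_CHANNELS),
                 geometry = NULL, spec = NULL),
            class = "stain_bundle")
}

#' Paired-supervised training of the staining model
#'
#' Per-sample alternating optimization: each step updates the four
#' conditional PatchGAN discriminators on (real, generated) pairs and the
#' generator(s) on the composite objective — LSGAN generator terms, pixel
#' L1 (`lambda1`), the frozen perceptual critic (`lambda2`, if configured
#' and supplied), and the cross-task structural constraints (`lambda3`).
#'
#' @param pairs list of `stain_bundle` training pairs
#' @param cfg a [stain_net_config()]
#' @param obj_w a [stain_objective_weights()]
#' @param ct_w a [cross_task_weights()]
#' @param critic optional frozen [dpiqa_new()] critic (required for the
#'   perceptual term when `cfg$use_dpiqa`)
#' @param epochs training epochs over the pair list
#' @param lr Adam learning rate (the desk preset default compensates for
#'   single-sample updates; the full-scale schedule uses 1e-4 with batches)
#' @param augment random flips / 90-degree rotations / brightness jitter
#' @param seed ordering and augmentation seed
#' @param loss_scale global multiplier on generator gradients (used by
#'   joint training to apply the lambda_s schedule)
#' @param model optional warm-start `stain_model`
#' @return a `stain_model` with a `history` data frame attached
#' @export
train_stain <- function(pairs, cfg = stain_net_config(),
                        obj_w = stain_objective_weights(),
                        ct_w = cross_task_weights(), critic = NULL,
                        epochs = 30, lr = 1e-3, augment = TRUE, seed = 1,
                        loss_scale = 1, model = NULL) {
  if (length(pairs) == 0) stop("no training pairs supplied")
  model <- model %||% new_stain_model(cfg)
  gstates <- attr(model, "gstates") %||% lapply(model$gens, adam_new)
  dstates <- attr(model, "dstates") %||% lapply(model$discs, adam_new)
  hist <- vector("list", epochs)

  for (ep in seq_len(epochs)) {
    ep_seed <- mix_seed(seed, ep)
    ord <- with_seed(ep_seed, sample(seq_along(pairs)))
    acc <- c(l1 = 0, gan = 0, dpiqa = 0, crosstask = 0, d_loss = 0)
    for (si in seq_along(ord)) {
      b <- pairs[[ord[si]]]
      dat <- if (augment) {
        with_seed(mix_seed(ep_seed, si),
                  augment_bundle(b$interface, b$channels))
      } else {
        list(iint = b$interface, channels = b$channels)
      }
      iint <- dat$iint
      targets <- dat$channels
      feats <- if (cfg$use_features) structural_features(iint) else NULL

      if (cfg$single_task) {
        fws <- lapply(model$gens, function(g) {
          stain_generate(g, cfg, iint, feats)
        })
        pred <- array(0, dim = c(dim(iint), 4))
        for (i in seq_len(4)) pred[, , i] <- fws[[i]]$y[, , 1]
      } else {
        fw <- stain_generate(model$gens$shared, cfg, iint, feats)
        pred <- fw$y
      }

      dpred <- array(0, dim = dim(pred))
      npix <- length(iint)

      for (i in seq_len(4)) {
        ch <- STAIN_CHANNELS[i]
        tgt <- targets[[ch]]
        pc <- pred[, , i]
        # pixel L1
        acc["l1"] <- acc["l1"] + mean(abs(pc - tgt))
        dpred[, , i] <- dpred[, , i] +
          obj_w$lambda1 * sign(pc - tgt) / npix
        # adversarial
        fr <- patchgan_fwd(model$discs[[ch]], concat_c(iint, tgt))
        ff <- patchgan_fwd(model$discs[[ch]], concat_c(iint, pc))
        np <- length(ff$y)
        acc["gan"] <- acc["gan"] + mean((ff$y - 1)^2)
        bgen <- patchgan_bwd(model$discs[[ch]], ff$cache,
                             2 * (ff$y - 1) / np)
        dpred[, , i] <- dpred[, , i] + bgen$dx[, , 2]
        # discriminator step (LSGAN, labels 1 real / 0 fake)
        acc["d_loss"] <- acc["d_loss"] +
          0.5 * (mean((fr$y - 1)^2) + mean(ff$y^2))
        br <- patchgan_bwd(model$discs[[ch]], fr$cache, (fr$y - 1) / np)
        bf <- patchgan_bwd(model$discs[[ch]], ff$cache, ff$y / np)
        du <- adam_update(model$discs[[ch]],
                          tree_add(br$grads, bf$grads),
                          dstates[[ch]], lr)
        model$discs[[ch]] <- du$params
        dstates[[ch]] <- du$state
        # perceptual critic (frozen)
        if (cfg$use_dpiqa && !is.null(critic)) {
          dd <- dpiqa_distance(critic, pc, tgt, scales = 3,
                               want_grad = TRUE)
          acc["dpiqa"] <- acc["dpiqa"] + dd$d
          dpred[, , i] <- dpred[, , i] + obj_w$lambda2 * dd$grad
        }
      }

      ct <- cross_task_losses(pred, ct_w, with_grads = TRUE)
      acc["crosstask"] <- acc["crosstask"] + ct$total
      for (i in seq_len(4)) {
        dpred[, , i] <- dpred[, , i] +
          obj_w$lambda3 * ct$grads[[STAIN_CHANNELS[i]]]
      }

      dpred <- dpred * loss_scale
      if (cfg$single_task) {
        for (i in seq_len(4)) {
          bg <- stain_generate_bwd(model$gens[[i]], cfg, fws[[i]]$cache,
                                   dpred[, , i, drop = FALSE])
          gu <- adam_update(model$gens[[i]], bg$grads, gstates[[i]], lr)
          model$gens[[i]] <- gu$params
          gstates[[i]] <- gu$state
        }
      } else {
        bg <- stain_generate_bwd(model$gens$shared, cfg, fw$cache, dpred)
        gu <- adam_update(model$gens$shared, bg$grads, gstates$shared, lr)
        model$gens$shared <- gu$params
        gstates$shared <- gu$state
      }
    }
    hist[[ep]] <- data.frame(epoch = ep,
                             t(acc / length(pairs)))
  }
  attr(model, "gstates") <- gstates
  attr(model, "dstates") <- dstates
  attr(model, "history") <- do.call(rbind, hist)
  model
}

#' Joint end-to-end training of reconstruction and staining
#'
#' Optimizes `L_total = L_recon + lambda_s L_stain` with the linear
#' `lambda_s` warm-up: each epoch, every sample's per-specimen
#' reconstruction parameters take `recon_epochs` physics-objective steps
#' (with the staining loss gradient on the amplitude injected, scaled by
#' the scheduled `lambda_s`), then the staining model trains on the current
#' interface images with its gradients scaled by the same `lambda_s`. With
#' `joint = FALSE` (decoupled ablation) the reconstruction is trained to
#' completion first and the staining model afterwards, with no gradient
#' coupling.
#'
#' @param degraded list of [degrade_bundle()] outputs (stack + targets)
#' @param cfg a [stain_net_config()]
#' @param obj_w a [stain_objective_weights()] (holds the warm-up schedule)
#' @param ct_w a [cross_task_weights()]
#' @param critic optional frozen critic
#' @param epochs joint epochs
#' @param recon_epochs reconstruction steps per sample per joint epoch
#' @param recon_config a [bidir_train_config()] preset for the per-sample
#'   reconstructions
#' @param lr staining learning rate
#' @param joint couple the stages (FALSE = decoupled training ablation)
#' @param seed seed
#' @return list with `model` (stain model), `recon` (per-sample
#'   predictions), and `lambda_s_trace`
#' @export
train_joint <- function(degraded, cfg = stain_net_config(),
                        obj_w = stain_objective_weights(),
                        ct_w = cross_task_weights(), critic = NULL,
                        epochs = 10, recon_epochs = 2,
                        recon_config = bidir_train_config(epochs = 40,
                                                        freeze_epochs = 5),
                        lr = 1e-3, joint = TRUE, seed = 1) {
  for (d in degraded) {
    if (is.null(d$stack) || is.null(d$bundle)) {
      stop("joint training requires paired (stack, bundle) samples")
    }
  }
  n <- length(degraded)
  states <- vector("list", n)
  lam_trace <- numeric(epochs)

  if (!joint) {
    # decoupled: full reconstruction first, then supervised staining
    for (i in seq_len(n)) {
      states[[i]] <- bidir_fpm_train(degraded[[i]]$stack,
                                   recon_config)$prediction
    }
    ifaces <- lapply(seq_len(n), function(i) {
      bun <- degraded[[i]]$bundle
      bun$interface <- export_interface(states[[i]])$interface
      bun
    })
    model <- train_stain(ifaces, cfg, obj_w, ct_w, critic,
                         epochs = epochs, lr = lr, seed = seed)
    return(list(model = model, recon = states,
                lambda_s_trace = rep(obj_w$lambda_s, epochs)))
  }

  # warm start each specimen's reconstruction
  short <- recon_config
  model <- NULL
  for (ep in seq_len(epochs)) {
    lam <- lambda_s_schedule(ep - 1, obj_w)
    lam_trace[ep] <- lam
    ifaces <- vector("list", n)
    for (i in seq_len(n)) {
      st <- degraded[[i]]$stack
      extra <- NULL
      if (!is.null(states[[i]]) && !is.null(model)) {
        # staining-loss gradient on the amplitude, through the interface
        # normalization (extrema treated as constants)
        A <- states[[i]]$amplitude
        rng <- max(A) - min(A)
        iint <- norm01(A)
        feats <- if (cfg$use_features) structural_features(iint) else NULL
        fwm <- stain_generate(model$gens$shared, cfg, iint, feats)
        tgt <- degraded[[i]]$bundle$channels
        dpred <- array(0, dim = dim(fwm$y))
        for (k in seq_len(4)) {
          dpred[, , k] <- sign(fwm$y[, , k] - tgt[[STAIN_CHANNELS[k]]]) *
            obj_w$lambda1 / length(iint)
        }
        bgm <- stain_generate_bwd(model$gens$shared, cfg, fwm$cache, dpred)
        if (rng > 1e-12) extra <- lam * bgm$dinput[, , 1] / rng
      }
      cfg_i <- short
      cfg_i$epochs <- recon_epochs
      cfg_i$freeze_epochs <- 0L
      fit <- bidir_fpm_train(st, cfg_i, init = states[[i]],
                           extra_grad_A = extra)
      states[[i]] <- fit$prediction
      bun <- degraded[[i]]$bundle
      bun$interface <- export_interface(states[[i]])$interface
      ifaces[[i]] <- bun
    }
    model <- train_stain(ifaces, cfg, obj_w, ct_w, critic, epochs = 1,
                         lr = lr, seed = mix_seed(seed, ep),
                         loss_scale = lam, model = model)
  }
  list(model = model, recon = states, lambda_s_trace = lam_trace)
}
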