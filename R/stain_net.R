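# Stage II: multi-task virtual staining. A shared encoder-fusion-decoder
# generator maps the reconstructed-amplitude interface image (optionally
# with Stage-I structural features) to four stain channels (LAP2, DAPI,
# panCK, H&E); per-channel 70x70 least-squares PatchGAN discriminators,
# pixel L1, a frozen difference-perception quality critic, and cross-task
# structural constraints form the training objective.

STAIN_CHANNELS <- c("lap2", "dapi", "panck", "he")

#' Staining network configuration
#'
#' @param base_width stem channel count (doubled at each downsampling)
#' @param disc_width first-layer channel count of each discriminator
#' @param use_wtconv wavelet-convolution frequency branch (ablation:
#'   replaced by a plain 3x3 convolution when off)
#' @param use_fsff difference-aware frequency-spatial fusion (off: spatial
#'   features pass straight to the decoder)
#' @param use_se squeeze-and-excitation recalibration in the decoder
#' @param use_dpiqa perceptual critic term in the objective
#' @param use_features condition the spatial branch on Stage-I structural
#'   features (off: the network's own encoder features are used)
#' @param single_task train four independent single-channel generators
#' @param reduction SE bottleneck reduction factor
#' @param seed parameter-initialization seed
#' @return object of class `stain_net_config`
#' @export
stain_net_config <- function(base_width = 8, disc_width = 8,
                             use_wtconv = TRUE, use_fsff = TRUE,
                             use_se = TRUE, use_dpiqa = TRUE,
                             use_features = TRUE, single_task = FALSE,
                             reduction = 8, seed = 1) {
  structure(list(base_width = as.integer(base_width),
                 disc_width = as.integer(disc_width),
                 use_wtconv = use_wtconv, use_fsff = use_fsff,
                 use_se = use_se, use_dpiqa = use_dpiqa,
                 use_features = use_features, single_task = single_task,
                 reduction = as.integer(reduction),
                 seed = as.integer(seed)),
            class = "stain_net_config")
}

#' Create generator parameters
#'
#' @param cfg a [stain_net_config()]
#' @param out_ch output channels (4 for the multi-task generator, 1 per
#'   network in single-task mode)
#' @param feat_ch channel count of the Stage-I features
#' @return parameter list
#' @export
stain_generator_new <- function(cfg, out_ch = 4, feat_ch = 2) {
  C <- cfg$base_width
  with_seed(cfg$seed, {
    p <- list(
      stem = he_conv(3, 1, C),
      down1 = he_conv(3, C, 2 * C),
      down2 = he_conv(3, 2 * C, 4 * C),
      up1 = he_conv(3, 4 * C + 2 * C, 2 * C),
      up2 = he_conv(3, 2 * C + C, C),
      head = he_conv(3, C, out_ch)
    )
    if (cfg$use_features) p$fproj <- he_conv(1, feat_ch, 4 * C)
    if (cfg$use_wtconv) {
      p$freq <- wtconv_new(4 * C, identity_init = FALSE)
    } else {
      p$freq_plain <- he_conv(3, 4 * C, 4 * C)
    }
    if (cfg$use_fsff) p$fsff <- fsff_new(4 * C)
    if (cfg$use_se) {
      p$se1 <- se_new(2 * C, cfg$reduction)
      p$se2 <- se_new(C, cfg$reduction)
    }
    p
  })
}

#' Generator forward pass
#'
#' @param p parameters from [stain_generator_new()]
#' @param cfg the matching [stain_net_config()]
#' @param iint interface image, `H x W` matrix in `[0, 1]`
#' @param feats optional 3-scale feature list ([structural_features()]);
#'   required when `cfg$use_features` is on
#' @return list with `y` (`H x W x out_ch`, sigmoid range) and `cache`
#' @export
stain_generate <- function(p, cfg, iint, feats = NULL) {
  if (cfg$use_features && is.null(feats)) {
    stop("Stage-I features are required when the feature branch is enabled")
  }
  x0 <- as_cube(iint)
  c_stem <- conv_fwd(p$stem, x0); r_stem <- relu_fwd(c_stem$y)
  c_d1 <- conv_fwd(p$down1, r_stem$y, stride = 2); r_d1 <- relu_fwd(c_d1$y)
  c_d2 <- conv_fwd(p$down2, r_d1$y, stride = 2); r_d2 <- relu_fwd(c_d2$y)

  if (cfg$use_features) {
    c_fp <- conv_fwd(p$fproj, as_cube(feats[[3]]), pad = 0)
    fs <- c_fp$y
  } else {
    c_fp <- NULL
    fs <- r_d2$y
  }
  if (cfg$use_wtconv) {
    c_fr <- wtconv_fwd(p$freq, r_d2$y)
  } else {
    c_fr <- conv_fwd(p$freq_plain, r_d2$y)
  }
  ffq <- c_fr$y
  if (cfg$use_fsff) {
    c_fu <- fsff_fwd(p$fsff, fs, ffq)
    fused <- c_fu$y
  } else {
    c_fu <- NULL
    fused <- fs
  }

  u1 <- upsample2_fwd(fused)
  cat1 <- concat_c(u1$y, r_d1$y)
  c_u1 <- conv_fwd(p$up1, cat1); r_u1 <- relu_fwd(c_u1$y)
  if (cfg$use_se) { s1 <- se_fwd(p$se1, r_u1$y); f_u1 <- s1$y }
  else { s1 <- NULL; f_u1 <- r_u1$y }

  u2 <- upsample2_fwd(f_u1)
  cat2 <- concat_c(u2$y, r_stem$y)
  c_u2 <- conv_fwd(p$up2, cat2); r_u2 <- relu_fwd(c_u2$y)
  if (cfg$use_se) { s2 <- se_fwd(p$se2, r_u2$y); f_u2 <- s2$y }
  else { s2 <- NULL; f_u2 <- r_u2$y }

  c_h <- conv_fwd(p$head, f_u2)
  sg <- sigmoid_fwd(c_h$y)
  list(y = sg$y,
       cache = list(c_stem = c_stem, r_stem = r_stem, c_d1 = c_d1,
                    r_d1 = r_d1, c_d2 = c_d2, r_d2 = r_d2, c_fp = c_fp,
                    c_fr = c_fr, c_fu = c_fu, u1 = u1, c_u1 = c_u1,
                    r_u1 = r_u1, s1 = s1, u2 = u2, c_u2 = c_u2,
                    r_u2 = r_u2, s2 = s2, c_h = c_h, sg = sg,
                    C = cfg$base_width))
}

# Generator backward pass: dy is the gradient w.r.t. the sigmoid output.
stain_generate_bwd <- function(p, cfg, cache, dy) {
  g <- list()
  C <- cache$C
  dh <- sigmoid_bwd(cache$sg, as_cube(dy))
  bh <- conv_bwd(p$head, cache$c_h, dh); g$head <- bh$grads
  df2 <- bh$dx
  if (cfg$use_se) {
    bs2 <- se_bwd(p$se2, cache$s2, df2); g$se2 <- bs2$grads; df2 <- bs2$dx
  }
  dr2 <- relu_bwd(cache$r_u2, df2)
  bu2 <- conv_bwd(p$up2, cache$c_u2, dr2); g$up2 <- bu2$grads
  sp2 <- split_c(bu2$dx, 2 * C)
  dskip_stem <- sp2$b
  df1 <- upsample2_bwd(cache$u2, sp2$a)
  if (cfg$use_se) {
    bs1 <- se_bwd(p$se1, cache$s1, df1); g$se1 <- bs1$grads; df1 <- bs1$dx
  }
  dr1 <- relu_bwd(cache$r_u1, df1)
  bu1 <- conv_bwd(p$up1, cache$c_u1, dr1); g$up1 <- bu1$grads
  sp1 <- split_c(bu1$dx, 4 * C)
  dskip_d1 <- sp1$b
  dfused <- upsample2_bwd(cache$u1, sp1$a)

  de3 <- array(0, dim = dim(cache$r_d2$y))
  if (cfg$use_fsff) {
    bf <- fsff_bwd(p$fsff, cache$c_fu, dfused)
    g$fsff <- bf$grads
    dfs <- bf$dfs
    dff <- bf$dff
  } else {
    dfs <- dfused
    dff <- NULL
  }
  if (!is.null(dff)) {
    if (cfg$use_wtconv) {
      bq <- wtconv_bwd(p$freq, cache$c_fr, dff); g$freq <- bq$grads
    } else {
      bq <- conv_bwd(p$freq_plain, cache$c_fr, dff); g$freq_plain <- bq$grads
    }
    de3 <- de3 + bq$dx
  }
  dfeat3 <- NULL
  if (cfg$use_features) {
    bp <- conv_bwd(p$fproj, cache$c_fp, dfs); g$fproj <- bp$grads
    dfeat3 <- bp$dx
  } else {
    de3 <- de3 + dfs
  }

  dd2 <- relu_bwd(cache$r_d2, de3)
  bd2 <- conv_bwd(p$down2, cache$c_d2, dd2); g$down2 <- bd2$grads
  de2 <- bd2$dx + dskip_d1
  dd1 <- relu_bwd(cache$r_d1, de2)
  bd1 <- conv_bwd(p$down1, cache$c_d1, dd1); g$down1 <- bd1$grads
  de1 <- bd1$dx + dskip_stem
  ds <- relu_bwd(cache$r_stem, de1)
  bs <- conv_bwd(p$stem, cache$c_stem, ds); g$stem <- bs$grads
  list(grads = g, dinput = bs$dx, dfeat3 = dfeat3)
}

# ---- PatchGAN discriminator ---------------------------------------------

#' Create a 70x70-receptive-field PatchGAN discriminator
#'
#' The canonical four-downsampling-free configuration: 4x4 kernels, strides
#' 2/2/2/1/1, padding 1, leaky-ReLU slope 0.2; each unit of the final patch
#' map sees a 70x70 window of the input. Input is the interface image
#' concatenated with one stain channel (conditional discrimination).
#'
#' @param cfg a [stain_net_config()]
#' @param in_ch input channels (default 2: condition + channel)
#' @return parameter list
#' @export
patchgan_new <- function(cfg, in_ch = 2) {
  Cd <- cfg$disc_width
  with_seed(cfg$seed + 1000, list(
    l1 = he_conv(4, in_ch, Cd),
    l2 = he_conv(4, Cd, 2 * Cd),
    l3 = he_conv(4, 2 * Cd, 4 * Cd),
    l4 = he_conv(4, 4 * Cd, 8 * Cd),
    l5 = he_conv(4, 8 * Cd, 1)
  ))
}

#' Discriminator forward / backward
#'
#' @param p parameters from [patchgan_new()]
#' @param x `H x W x in_ch` input
#' @return `patchgan_fwd`: list with the patch map `y` and `cache`;
#'   `patchgan_bwd`: list with `dx` and `grads`
#' @export
patchgan_fwd <- function(p, x) {
  c1 <- conv_fwd(p$l1, as_cube(x), stride = 2, pad = 1); a1 <- lrelu_fwd(c1$y)
  c2 <- conv_fwd(p$l2, a1$y, stride = 2, pad = 1); a2 <- lrelu_fwd(c2$y)
  c3 <- conv_fwd(p$l3, a2$y, stride = 2, pad = 1); a3 <- lrelu_fwd(c3$y)
  c4 <- conv_fwd(p$l4, a3$y, stride = 1, pad = 1); a4 <- lrelu_fwd(c4$y)
  c5 <- conv_fwd(p$l5, a4$y, stride = 1, pad = 1)
  list(y = c5$y,
       cache = list(c1 = c1, a1 = a1, c2 = c2, a2 = a2, c3 = c3, a3 = a3,
                    c4 = c4, a4 = a4, c5 = c5))
}

#' @rdname patchgan_fwd
#' @param cache forward cache
#' @param dy upstream gradient on the patch map
#' @export
patchgan_bwd <- function(p, cache, dy) {
  g <- list()
  b5 <- conv_bwd(p$l5, cache$c5, as_cube(dy)); g$l5 <- b5$grads
  d4 <- lrelu_bwd(cache$a4, b5$dx)
  b4 <- conv_bwd(p$l4, cache$c4, d4); g$l4 <- b4$grads
  d3 <- lrelu_bwd(cache$a3, b4$dx)
  b3 <- conv_bwd(p$l3, cache$c3, d3); g$l3 <- b3$grads
  d2 <- lrelu_bwd(cache$a2, b3$dx)
  b2 <- conv_bwd(p$l2, cache$c2, d2); g$l2 <- b2$grads
  d1 <- lrelu_bwd(cache$a1, b2$dx)
  b1 <- conv_bwd(p$l1, cache$c1, d1); g$l1 <- b1$grads
  list(dx = b1$dx, grads = g)
}

#' Least-squares adversarial losses
#'
#' LSGAN with labels 1 (real) / 0 (fake) on the patch map:
#' generator term `mean((D(fake) - 1)^2)`, discriminator term
#' `0.5 (mean((D(real) - 1)^2) + mean(D(fake)^2))`.
#'
#' @param d_real,d_fake discriminator patch maps
#' @return list with `g` (generator term, `d_real` may be NULL) and `d`
#' @export
lsgan_losses <- function(d_real, d_fake) {
  g <- mean((d_fake - 1)^2)
  d <- if (is.null(d_real)) NULL else
    0.5 * (mean((d_real - 1)^2) + mean(d_fake^2))
  list(g = g, d = d)
}

#' Per-channel adversarial loss report
#'
#' Applies each channel's conditional discriminator to the real and
#' generated stain, returning the LSGAN generator and discriminator terms
#' per channel.
#'
#' @param pred `H x W x 4` generated stains
#' @param targets named list of ground-truth channel matrices
#' @param discs named list of per-channel discriminator parameter lists
#' @param iint conditioning interface image
#' @return `loss_report` with per-channel `G_*` and `D_*` terms
#' @export
adversarial_losses <- function(pred, targets, discs, iint) {
  terms <- c()
  for (i in seq_along(STAIN_CHANNELS)) {
    ch <- STAIN_CHANNELS[i]
    fr <- patchgan_fwd(discs[[ch]], concat_c(iint, targets[[ch]]))
    ff <- patchgan_fwd(discs[[ch]], concat_c(iint, pred[, , i]))
    ls <- lsgan_losses(fr$y, ff$y)
    terms[paste0("G_", ch)] <- ls$g
    terms[paste0("D_", ch)] <- ls$d
  }
  structure(list(terms = terms, weights = setNames(rep(1, length(terms)),
                                                   names(terms)),
                 weighted = terms, total = sum(terms)),
            class = "loss_report")
}

# ---- cross-task structural constraints ----------------------------------

#' Cross-task constraint weights
#'
#' @param alpha nuclear consistency (DAPI vs H&E inside the nuclear mask)
#' @param beta spatial exclusivity (LAP2 x panCK overlap)
#' @param gamma relative attention consistency (DAPI anchor)
#' @param tau nuclear-mask threshold on the DAPI prediction, in (0, 1)
#' @return object of class `cross_task_weights`
#' @export
cross_task_weights <- function(alpha = 1.0, beta = 0.5, gamma = 0.2,
                               tau = 0.5) {
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0, tau > 0, tau < 1)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, tau = tau),
            class = "cross_task_weights")
}

# Soft attention pooling: absolute values normalized to unit sum.
attn_map <- function(y) {
  s <- sum(abs(y))
  if (s <= 0) return(y * 0)
  abs(y) / s
}

#' Cross-task structural constraint losses
#'
#' * consistency — masked mean squared difference between the DAPI and H&E
#'   predictions inside the nuclear mask `M = 1[dapi > tau]` (mask treated
#'   as a constant; an empty mask yields 0 with a warning);
#' * exclusivity — `mean(lap2 * panck)`;
#' * relative — L1 distance between soft-attention maps
#'   (`abs()` normalized to unit sum) of DAPI and of each of LAP2 and
#'   panCK, averaged over the two targets.
#'
#' The total is the weighted combination `alpha*consistency +
#' beta*exclusive + gamma*relative`.
#'
#' @param pred `H x W x 4` array or named list of channel matrices, in
#'   channel order LAP2, DAPI, panCK, H&E
#' @param w a [cross_task_weights()]
#' @param with_grads also return gradients w.r.t. each channel
#' @return a `loss_report` (with `grads` when requested)
#' @export
cross_task_losses <- function(pred, w = cross_task_weights(),
                              with_grads = FALSE) {
  ch <- if (is.list(pred)) pred else {
    setNames(lapply(seq_len(dim(pred)[3]), function(i) pred[, , i]),
             STAIN_CHANNELS)
  }
  lap2 <- ch$lap2; dapi <- ch$dapi; panck <- ch$panck; he <- ch$he
  npix <- length(dapi)

  mask <- dapi > w$tau
  nmask <- sum(mask)
  if (nmask == 0) {
    warning("empty nuclear mask: consistency loss defined as 0")
    lcons <- 0
  } else {
    lcons <- sum(((dapi - he)^2)[mask]) / nmask
  }
  lexcl <- mean(lap2 * panck)

  a_d <- attn_map(dapi)
  a_l <- attn_map(lap2)
  a_p <- attn_map(panck)
  lrel <- (sum(abs(a_d - a_l)) + sum(abs(a_d - a_p))) / 2

  terms <- c(consistency = lcons, exclusive = lexcl, relative = lrel)
  wts <- c(consistency = w$alpha, exclusive = w$beta, relative = w$gamma)
  rep <- structure(list(terms = terms, weights = wts,
                        weighted = terms * wts,
                        total = sum(terms * wts)),
                   class = "loss_report")
  if (!with_grads) return(rep)

  g <- list(lap2 = lap2 * 0, dapi = dapi * 0, panck = panck * 0,
            he = he * 0)
  if (nmask > 0) {
    d <- 2 * (dapi - he) * mask / nmask
    g$dapi <- g$dapi + w$alpha * d
    g$he <- g$he - w$alpha * d
  }
  g$lap2 <- g$lap2 + w$beta * panck / npix
  g$panck <- g$panck + w$beta * lap2 / npix

  # gradient of the attention L1 terms through the unit-sum normalization
  attn_chain <- function(y, a, dLda) {
    s <- sum(abs(y))
    if (s <= 0) return(y * 0)
    sign(y) * (dLda - sum(dLda * a)) / s
  }
  dl_ad <- (sign(a_d - a_l) + sign(a_d - a_p)) / 2
  g$dapi <- g$dapi + w$gamma * attn_chain(dapi, a_d, dl_ad)
  g$lap2 <- g$lap2 + w$gamma * attn_chain(lap2, a_l, -sign(a_d - a_l) / 2)
  g$panck <- g$panck + w$gamma * attn_chain(panck, a_p, -sign(a_d - a_p) / 2)
  rep$grads <- g
  rep
}

# ---- total staining objective -------------------------------------------

#' Staining objective weights
#'
#' @param lambda1 pixel L1 weight (default 10.0)
#' @param lambda2 perceptual-critic weight (default 0.2)
#' @param lambda3 cross-task constraint weight (default 1.0)
#' @param lambda_s joint-training balance between reconstruction and
#'   staining losses (default 0.5)
#' @param warmup_epochs epochs over which `lambda_s` ramps linearly from
#'   `lambda_s_start` to `lambda_s`
#' @param lambda_s_start initial `lambda_s`
#' @return object of class `stain_objective_weights`
#' @export
stain_objective_weights <- function(lambda1 = 10.0, lambda2 = 0.2,
                                    lambda3 = 1.0, lambda_s = 0.5,
                                    warmup_epochs = 10,
                                    lambda_s_start = 0.1) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, lambda3 >= 0, lambda_s >= 0,
            warmup_epochs >= 0)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 lambda_s = lambda_s, warmup_epochs = warmup_epochs,
                 lambda_s_start = lambda_s_start),
            class = "stain_objective_weights")
}

#' Joint-training warm-up schedule for `lambda_s`
#'
#' Linear ramp from `lambda_s_start` to `lambda_s` over the first
#' `warmup_epochs` epochs, constant afterwards.
#'
#' @param epoch 0-based epoch index
#' @param w a [stain_objective_weights()]
#' @return numeric `lambda_s` value at that epoch
#' @export
lambda_s_schedule <- function(epoch, w = stain_objective_weights()) {
  if (w$warmup_epochs == 0) return(w$lambda_s)
  frac <- pmin(pmax(epoch / w$warmup_epochs, 0), 1)
  w$lambda_s_start + (w$lambda_s - w$lambda_s_start) * frac
}

#' Assemble the total staining objective
#'
#' `L_stain = sum_c (L_GAN^c + lambda1 L_L1^c + lambda2 L_DPIQA^c) +
#' lambda3 L_crosstask`. Components are passed as named vectors over the
#' four channels; a missing component raises an error naming it.
#'
#' @param gan,l1,dpiqa named numeric vectors over the stain channels
#' @param crosstask total cross-task constraint loss (scalar)
#' @param w a [stain_objective_weights()]
#' @return a `loss_report`; `total` equals the weighted sum of the parts
#' @export
stain_objective <- function(gan, l1, dpiqa, crosstask,
                            w = stain_objective_weights()) {
  for (ch in STAIN_CHANNELS) {
    for (nm in c("gan", "l1", "dpiqa")) {
      v <- get(nm)
      if (is.null(v[ch]) || is.na(v[ch])) {
        stop(sprintf("missing %s loss for channel %s", nm, ch))
      }
    }
  }
  terms <- c(setNames(as.numeric(gan[STAIN_CHANNELS]),
                      paste0("GAN_", STAIN_CHANNELS)),
             setNames(as.numeric(l1[STAIN_CHANNELS]),
                      paste0("L1_", STAIN_CHANNELS)),
             setNames(as.numeric(dpiqa[STAIN_CHANNELS]),
                      paste0("DPIQA_", STAIN_CHANNELS)),
             crosstask = crosstask)
  wts <- c(rep(1, 4), rep(w$lambda1, 4), rep(w$lambda2, 4), w$lambda3)
  names(wts) <- names(terms)
  structure(list(terms = terms, weights = wts, weighted = terms * wts,
                 total = sum(terms * wts)),
            class = "loss_report")
}
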