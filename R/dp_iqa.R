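# Difference-Perception image-quality critic: a main quality-regression
# branch (strided conv encoder) plus a wavelet difference branch (two-level
# Haar decomposition, subband convolutions, multi-scale asymmetric feature
# fusion) that predicts a symmetric perceptual dissimilarity d_hat for an
# image pair. Used as a frozen perceptual critic inside the staining
# objective and as a standalone quality score.

#' Create critic parameters
#'
#' @param width channel width of the wavelet branch (main branch uses
#'   `width` and `2*width`)
#' @param seed initialization seed
#' @return parameter list of class `dpiqa_critic`
#' @export
dpiqa_new <- function(width = 8, seed = 1) {
  C <- as.integer(width)
  with_seed(seed, structure(list(
    lv1 = he_conv(3, 4, C),
    lv2 = he_conv(3, 4, C),
    affm = msaffm_new(C, 2),
    m1 = he_conv(3, 1, C),
    m2 = he_conv(3, C, 2 * C),
    aux1 = he_dense(C + 10, C), aux2 = he_dense(C, 1),
    dif1 = he_dense(C, C), dif2 = he_dense(C, 1),
    mh1 = he_dense(2 * C + C + C + 10, 2 * C), mh2 = he_dense(2 * C, 1),
    width = C
  ), class = "dpiqa_critic"))
}

# Detail subbands carry the quality-relevant signal but are an order of
# magnitude smaller than the approximation band; rebalance before the
# subband convolutions.
DETAIL_GAIN <- 4
FEAT_DAMP <- 0.1

# Hand-set image statistics injected into the quality heads: mean absolute
# detail energy per wavelet band and level, global contrast, gradient
# energy, and the flat-pixel fraction (a quantization signature). Treated
# as constants w.r.t. the image in backprop (they only feed the
# absolute-quality heads, not the difference branch).
dpiqa_stats <- function(img) {
  sb1 <- dwt2_haar(img)
  sb2 <- dwt2_haar(sb1$LL)
  dx <- img[, -1] - img[, -ncol(img)]
  dy <- img[-1, ] - img[-nrow(img), ]
  c(mean(abs(sb1$LH)), mean(abs(sb1$HL)), mean(abs(sb1$HH)),
    stats::sd(sb1$LL),
    mean(abs(sb2$LH)), mean(abs(sb2$HL)), mean(abs(sb2$HH)),
    stats::sd(img),
    mean(abs(dx)) + mean(abs(dy)),
    mean(abs(dx) < 1e-9))
}

# Wavelet auxiliary branch: two-level Haar + subband convs + MS-AFFM.
dpiqa_aux_fwd <- function(p, img) {
  sb1 <- dwt2_haar(img)
  arr1 <- array(0, dim = c(dim(sb1$LL), 4))
  arr1[, , 1] <- sb1$LL
  arr1[, , 2] <- DETAIL_GAIN * sb1$LH
  arr1[, , 3] <- DETAIL_GAIN * sb1$HL
  arr1[, , 4] <- DETAIL_GAIN * sb1$HH
  sb2 <- dwt2_haar(sb1$LL)
  arr2 <- array(0, dim = c(dim(sb2$LL), 4))
  arr2[, , 1] <- sb2$LL
  arr2[, , 2] <- DETAIL_GAIN * sb2$LH
  arr2[, , 3] <- DETAIL_GAIN * sb2$HL
  arr2[, , 4] <- DETAIL_GAIN * sb2$HH
  c1 <- conv_fwd(p$lv1, arr1); a1 <- relu_fwd(c1$y)
  c2 <- conv_fwd(p$lv2, arr2); a2 <- relu_fwd(c2$y)
  af <- msaffm_fwd(p$affm, list(a1$y, a2$y))
  list(fused = af$y, c1 = c1, a1 = a1, c2 = c2, a2 = a2, af = af,
       dims = dim(img))
}

# Backward of the auxiliary branch: returns param grads and d(img).
dpiqa_aux_bwd <- function(p, cache, dfused) {
  bm <- msaffm_bwd(p$affm, cache$af, dfused)
  da1 <- relu_bwd(cache$a1, bm$dfeats[[1]])
  b1 <- conv_bwd(p$lv1, cache$c1, da1)
  da2 <- relu_bwd(cache$a2, bm$dfeats[[2]])
  b2 <- conv_bwd(p$lv2, cache$c2, da2)
  # level-2 input gradient flows into the LL band of level 1
  dsb2 <- list(LL = b2$dx[, , 1], LH = DETAIL_GAIN * b2$dx[, , 2],
               HL = DETAIL_GAIN * b2$dx[, , 3],
               HH = DETAIL_GAIN * b2$dx[, , 4])
  dLL1_extra <- idwt2_haar(dsb2)  # adjoint of level-2 DWT
  dsb1 <- list(LL = b1$dx[, , 1] + dLL1_extra,
               LH = DETAIL_GAIN * b1$dx[, , 2],
               HL = DETAIL_GAIN * b1$dx[, , 3],
               HH = DETAIL_GAIN * b1$dx[, , 4])
  dimg <- idwt2_haar(dsb1)        # adjoint of level-1 DWT
  list(grads = list(lv1 = b1$grads, lv2 = b2$grads, affm = bm$grads),
       dimg = dimg)
}

#' Assess one image or an image pair
#'
#' Returns the absolute quality scores `q_main` and `q_aux` of the first
#' image (both in `(0, 1)`) and the perceptual dissimilarity `d >= 0` of
#' the pair, computed from the absolute difference of the two images'
#' fused wavelet features — symmetric in its arguments by construction.
#' With a single image, `d = d(I, I)`.
#'
#' @param p a [dpiqa_new()] critic
#' @param i1 grayscale matrix in `[0, 1]`, dimensions divisible by 4
#' @param i2 optional second image of the same shape
#' @param want_cache keep forward caches (for training/backprop)
#' @return list with `q_main`, `q_aux`, `d`, `f_diff`, and optionally
#'   `cache`
#' @export
dpiqa_assess <- function(p, i1, i2 = NULL, want_cache = FALSE) {
  if (is.null(i2)) i2 <- i1
  if (!all(dim(i1) == dim(i2))) stop("images must have equal shapes")
  A1 <- dpiqa_aux_fwd(p, i1)
  A2 <- dpiqa_aux_fwd(p, i2)
  fdiff <- abs(A1$fused - A2$fused)
  gd <- gap_fwd(fdiff)
  d1 <- dense_fwd(p$dif1, gd$y); dr <- relu_fwd(d1$y)
  d2 <- dense_fwd(p$dif2, dr$y); dsp <- softplus_fwd(d2$y)
  st1 <- dpiqa_stats(i1)
  ga <- gap_fwd(A1$fused)
  # pooled conv features enter the quality heads damped, so the
  # well-conditioned band statistics dominate early optimization
  x1 <- dense_fwd(p$aux1, c(FEAT_DAMP * ga$y, st1)); xr <- relu_fwd(x1$y)
  x2 <- dense_fwd(p$aux2, xr$y); xsg <- sigmoid_fwd(x2$y)
  cm1 <- conv_fwd(p$m1, as_cube(i1), stride = 2); am1 <- relu_fwd(cm1$y)
  cm2 <- conv_fwd(p$m2, am1$y, stride = 2); am2 <- relu_fwd(cm2$y)
  gm <- gap_fwd(am2$y)
  feat <- c(FEAT_DAMP * gm$y, FEAT_DAMP * ga$y, FEAT_DAMP * gd$y, st1)
  h1 <- dense_fwd(p$mh1, feat); hr <- relu_fwd(h1$y)
  h2 <- dense_fwd(p$mh2, hr$y); hsg <- sigmoid_fwd(h2$y)
  out <- list(q_main = as.numeric(hsg$y), q_aux = as.numeric(xsg$y),
              d = as.numeric(dsp$y), f_diff = fdiff)
  if (want_cache) {
    out$cache <- list(A1 = A1, A2 = A2, fdiff = fdiff, gd = gd, d1 = d1,
                      dr = dr, d2 = d2, dsp = dsp, ga = ga, x1 = x1,
                      xr = xr, x2 = x2, xsg = xsg, cm1 = cm1, am1 = am1,
                      cm2 = cm2, am2 = am2, gm = gm, h1 = h1, hr = hr,
                      h2 = h2, hsg = hsg, s1 = A1$fused - A2$fused)
  }
  out
}

# Full backward of dpiqa_assess given upstream scalars (dq_main, dq_aux,
# dd). Returns parameter gradients and the gradient w.r.t. the first image.
dpiqa_assess_bwd <- function(p, cache, dq_main = 0, dq_aux = 0, dd = 0) {
  g <- list()
  C <- p$width
  # main head
  dh2 <- sigmoid_bwd(cache$hsg, dq_main)
  b_h2 <- dense_bwd(p$mh2, cache$h2, dh2); g$mh2 <- b_h2$grads
  dhr <- relu_bwd(cache$hr, b_h2$dx)
  b_h1 <- dense_bwd(p$mh1, cache$h1, dhr); g$mh1 <- b_h1$grads
  dfeat <- b_h1$dx
  dgm <- FEAT_DAMP * dfeat[seq_len(2 * C)]
  dga_m <- FEAT_DAMP * dfeat[2 * C + seq_len(C)]
  dgd_m <- FEAT_DAMP * dfeat[3 * C + seq_len(C)]
  # trailing band-statistics entries: constants w.r.t. the image
  # main conv chain
  dam2 <- gap_bwd(cache$gm, dgm)
  dcm2 <- relu_bwd(cache$am2, dam2)
  b_m2 <- conv_bwd(p$m2, cache$cm2, dcm2); g$m2 <- b_m2$grads
  dam1 <- relu_bwd(cache$am1, b_m2$dx)
  b_m1 <- conv_bwd(p$m1, cache$cm1, dam1); g$m1 <- b_m1$grads
  dimg_main <- b_m1$dx[, , 1]
  # aux quality head
  dx2 <- sigmoid_bwd(cache$xsg, dq_aux)
  b_x2 <- dense_bwd(p$aux2, cache$x2, dx2); g$aux2 <- b_x2$grads
  dxr <- relu_bwd(cache$xr, b_x2$dx)
  b_x1 <- dense_bwd(p$aux1, cache$x1, dxr); g$aux1 <- b_x1$grads
  dga <- FEAT_DAMP * b_x1$dx[seq_len(C)] + dga_m
  dfused1_q <- gap_bwd(cache$ga, dga)
  # difference head
  dd2 <- softplus_bwd(cache$dsp, dd)
  b_d2 <- dense_bwd(p$dif2, cache$d2, dd2); g$dif2 <- b_d2$grads
  ddr <- relu_bwd(cache$dr, b_d2$dx)
  b_d1 <- dense_bwd(p$dif1, cache$d1, ddr); g$dif1 <- b_d1$grads
  dgd <- b_d1$dx + dgd_m
  dfdiff <- gap_bwd(cache$gd, dgd)
  dfused1_d <- dfdiff * sign(cache$s1)
  # wavelet branch: the shared parameters receive gradients through BOTH
  # images' feature paths; only the first image's input gradient is kept
  aux_b <- dpiqa_aux_bwd(p, cache$A1, dfused1_q + dfused1_d)
  aux_b2 <- dpiqa_aux_bwd(p, cache$A2, -dfused1_d)
  g$lv1 <- tree_add(aux_b$grads$lv1, aux_b2$grads$lv1)
  g$lv2 <- tree_add(aux_b$grads$lv2, aux_b2$grads$lv2)
  g$affm <- tree_add(aux_b$grads$affm, aux_b2$grads$affm)
  list(grads = g, dimg = aux_b$dimg + dimg_main)
}

#' Difference-perception training loss
#'
#' `L_IQA = L_main + lambda1 L_aux + lambda2 L_diff` with L1 residuals:
#' `L_main = |q_main - q|`, `L_aux = |q_aux - q|`,
#' `L_diff = |d - |q1 - q2||`.
#'
#' @param assessment a [dpiqa_assess()] result
#' @param q quality label of the first image in `[0, 1]`
#' @param q2 quality label of the second image (for the pair term)
#' @param lambda1,lambda2 auxiliary and difference weights (default 0.5)
#' @return a `loss_report`
#' @export
dpiqa_loss <- function(assessment, q, q2 = q, lambda1 = 0.5,
                       lambda2 = 0.5) {
  if (is.null(q)) stop("missing quality labels")
  terms <- c(main = abs(assessment$q_main - q),
             aux = abs(assessment$q_aux - q),
             diff = abs(assessment$d - abs(q - q2)))
  wts <- c(main = 1, aux = lambda1, diff = lambda2)
  structure(list(terms = terms, weights = wts, weighted = terms * wts,
                 total = sum(terms * wts)),
            class = "loss_report")
}

#' Synthetic distortions with quality labels
#'
#' Applies Gaussian blur (sigma up to 3 px), Gaussian noise (SD up to 0.1)
#' or gray-level quantization at a normalized strength `s` in `[0, 1]`,
#' labeled `q = 1 - s` (an undistorted image has q = 1).
#'
#' @param img matrix in `[0, 1]`
#' @param type `"blur"`, `"noise"` or `"quant"`
#' @param strength normalized strength in `[0, 1]`
#' @param seed noise seed
#' @return list with `img` and label `q`
#' @export
distort_image <- function(img, type = c("blur", "noise", "quant"),
                          strength = 0.5, seed = 1) {
  type <- match.arg(type)
  stopifnot(strength >= 0, strength <= 1)
  out <- switch(type,
    blur = gaussian_blur(img, 3 * strength),
    noise = with_seed(seed, pmin(pmax(
      img + matrix(rnorm(length(img), 0, 0.1 * strength), nrow(img)),
      0), 1)),
    quant = {
      levels <- max(2, round(2^(8 - 6 * strength)))
      round(img * (levels - 1)) / (levels - 1)
    })
  list(img = out, q = 1 - strength, type = type, strength = strength)
}

#' Train the critic on synthetically distorted phantoms
#'
#' Generates distorted variants of a grayscale corpus with quality labels
#' `q = 1 - strength`, trains the critic with Adam on the combined
#' absolute/relative objective (pairs drawn from variants of the same base
#' image), and evaluates rank agreement between labels and predicted
#' quality on a held-out image subset.
#'
#' @param corpus list of grayscale matrices in `[0, 1]` (at least 50)
#' @param seed training seed
#' @param steps optimizer steps (each averages gradients over `batch`
#'   image pairs)
#' @param lr Adam learning rate
#' @param width critic width
#' @param n_variants distorted variants per image
#' @param holdout fraction of base images held out for validation
#' @param batch pairs per gradient step
#' @return list with `critic`, `spearman` (held-out rank correlation
#'   between q and q_main), and the training loss trace
#' @export
train_dpiqa <- function(corpus, seed = 1, steps = 500, lr = 3e-3,
                        width = 8, n_variants = 6, holdout = 0.2,
                        batch = 8) {
  if (length(corpus) < 50) {
    stop("corpus too small: at least 50 images are required")
  }
  p <- dpiqa_new(width = width, seed = seed)
  n_hold <- max(2L, floor(holdout * length(corpus)))
  idx_hold <- seq(length(corpus) - n_hold + 1, length(corpus))
  idx_rest <- setdiff(seq_along(corpus), idx_hold)
  # a further split for in-training model selection (early stopping)
  n_val <- max(2L, floor(0.2 * length(idx_rest)))
  idx_val <- tail(idx_rest, n_val)
  idx_train <- setdiff(idx_rest, idx_val)

  make_variants <- function(img, base_seed) {
    lapply(seq_len(n_variants), function(v) {
      with_seed(base_seed + 71 * v, {
        type <- sample(c("blur", "noise", "quant"), 1)
        s <- if (v == 1) 0 else runif(1)
        distort_image(img, type, s, seed = base_seed + 13 + 71 * v)
      })
    })
  }

  variants <- lapply(seq_along(corpus), function(i) {
    make_variants(corpus[[i]], mix_seed(seed, i * 1000))
  })

  state <- adam_new(p)
  trace <- numeric(steps)
  best_rho <- -Inf
  best_p <- NULL
  eval_every <- max(25L, steps %/% 20L)
  with_seed(seed, {
    for (t in seq_len(steps)) {
      gacc <- NULL
      tot <- 0
      for (bi in seq_len(batch)) {
        i <- sample(idx_train, 1)
        vs <- sample(n_variants, 2)
        v1 <- variants[[i]][[vs[1]]]
        v2 <- variants[[i]][[vs[2]]]
        a <- dpiqa_assess(p, v1$img, v2$img, want_cache = TRUE)
        tot <- tot + dpiqa_loss(a, v1$q, v2$q)$total
        dq_main <- sign(a$q_main - v1$q) / batch
        dq_aux <- 0.5 * sign(a$q_aux - v1$q) / batch
        dd <- 0.5 * sign(a$d - abs(v1$q - v2$q)) / batch
        b <- dpiqa_assess_bwd(p, a$cache, dq_main, dq_aux, dd)
        gacc <- tree_add(gacc, b$grads)
      }
      trace[t] <- tot / batch
      upd <- adam_update(p, gacc, state, lr)
      p <- upd$params
      state <- upd$state
      if (t %% eval_every == 0 || t == steps) {
        vq <- c(); vqh <- c()
        for (i in idx_val) {
          for (v in variants[[i]]) {
            vq <- c(vq, v$q)
            vqh <- c(vqh, dpiqa_assess(p, v$img)$q_main)
          }
        }
        rho <- suppressWarnings(cor(vq, vqh, method = "spearman"))
        if (is.finite(rho) && rho > best_rho) {
          best_rho <- rho
          best_p <- p
        }
      }
    }
  })
  if (!is.null(best_p)) p <- best_p

  qs <- c(); qhat <- c()
  for (i in idx_hold) {
    for (v in variants[[i]]) {
      qs <- c(qs, v$q)
      qhat <- c(qhat, dpiqa_assess(p, v$img)$q_main)
    }
  }
  list(critic = p, spearman = cor(qs, qhat, method = "spearman"),
       trace = trace, holdout_q = qs, holdout_qhat = qhat)
}

# Average-pool an image by 2 (Haar LL / 2) for multi-scale critic use.
avgpool2 <- function(x) dwt2_haar(x)$LL / 2

#' Perceptual distance from a frozen critic
#'
#' The critic's dissimilarity `d` averaged over `scales` dyadic scales.
#' With `want_grad = TRUE` the gradient with respect to the first image is
#' returned (the critic itself is frozen: its parameters are not touched).
#'
#' @param p a trained critic
#' @param x,y equal-shape grayscale matrices
#' @param scales number of dyadic scales (default 3)
#' @param want_grad also compute `d distance / d x`
#' @return list with `d` and optionally `grad`
#' @export
dpiqa_distance <- function(p, x, y, scales = 3, want_grad = FALSE) {
  total <- 0
  grad <- if (want_grad) x * 0 else NULL
  xs <- x; ys <- y
  pool_caches <- list()
  for (sidx in seq_len(scales)) {
    a <- dpiqa_assess(p, xs, ys, want_cache = want_grad)
    total <- total + a$d
    if (want_grad) {
      b <- dpiqa_assess_bwd(p, a$cache, dd = 1)
      gs <- b$dimg
      # chain back through the average-pooling operations
      if (sidx > 1) {
        for (k in seq(sidx - 1, 1)) {
          up <- array(0, dim = c(2 * nrow(gs), 2 * ncol(gs)))
          r1 <- seq(1, 2 * nrow(gs), 2); c1 <- seq(1, 2 * ncol(gs), 2)
          up[r1, c1] <- gs / 4; up[r1 + 1, c1] <- gs / 4
          up[r1, c1 + 1] <- gs / 4; up[r1 + 1, c1 + 1] <- gs / 4
          gs <- up
        }
      }
      grad <- grad + gs
    }
    if (sidx < scales) {
      if (min(dim(xs)) < 8) break
      xs <- avgpool2(xs)
      ys <- avgpool2(ys)
    }
  }
  out <- list(d = total / scales)
  if (want_grad) out$grad <- grad / scales
  out
}
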