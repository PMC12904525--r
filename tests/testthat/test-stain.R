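# Multi-task staining network: generator contracts, adversarial and
# cross-task loss arithmetic, objective assembly, training behavior.

small_cfg <- function(...) {
  stain_net_config(base_width = 4, disc_width = 4, use_dpiqa = FALSE,
                   seed = 3, ...)
}

test_that("generator outputs a sigmoid-range 4-channel stain map", {
  cfg <- small_cfg()
  gen <- stain_generator_new(cfg)
  b <- tiny_bundle(4)
  feats <- structural_features(b$interface)
  out <- stain_generate(gen, cfg, b$interface, feats)
  expect_equal(dim(out$y), c(32, 32, 4))
  expect_true(all(out$y > 0 & out$y < 1))
  # deterministic given parameters
  out2 <- stain_generate(gen, cfg, b$interface, feats)
  expect_identical(out$y, out2$y)
  expect_error(stain_generate(gen, cfg, b$interface, NULL), "features")
  # feature-branch ablation keeps the output shape
  cfg2 <- small_cfg(use_features = FALSE)
  gen2 <- stain_generator_new(cfg2)
  expect_equal(dim(stain_generate(gen2, cfg2, b$interface)$y),
               c(32, 32, 4))
})

test_that("generator backpropagation matches finite differences", {
  set.seed(8)
  cfg <- small_cfg()
  gen <- stain_generator_new(cfg)
  iint <- matrix(runif(16 * 16), 16)
  feats <- structural_features(iint)
  tgt <- array(runif(16 * 16 * 4), c(16, 16, 4))
  loss <- function(g) {
    sum((stain_generate(g, cfg, iint, feats)$y - tgt)^2) / 2
  }
  fw <- stain_generate(gen, cfg, iint, feats)
  bw <- stain_generate_bwd(gen, cfg, fw$cache, fw$y - tgt)
  h <- 1e-5
  # spot-check representative parameters across the network
  for (nm in c("stem", "down2", "up1", "head")) {
    w <- gen[[nm]]$w
    ij <- c(2, 1)
    gp <- gen; gp[[nm]]$w[ij[1], ij[2]] <- w[ij[1], ij[2]] + h
    gm <- gen; gm[[nm]]$w[ij[1], ij[2]] <- w[ij[1], ij[2]] - h
    fd <- (loss(gp) - loss(gm)) / (2 * h)
    expect_equal(bw$grads[[nm]]$w[ij[1], ij[2]], fd, tolerance = 1e-4,
                 label = paste("grad", nm))
  }
})

test_that("LSGAN losses hit their closed-form values", {
  half <- matrix(0.5, 10, 10)
  expect_equal(lsgan_losses(NULL, half)$g, 0.25)
  ones <- matrix(1, 10, 10)
  zeros <- matrix(0, 10, 10)
  expect_equal(lsgan_losses(ones, zeros)$d, 0)
  d <- lsgan_losses(ones, zeros)
  expect_equal(d$g, 1)  # fooled-never generator term
})

test_that("PatchGAN receptive field is the canonical 70x70", {
  cfg <- small_cfg()
  disc <- patchgan_new(cfg)
  x <- array(0.5, c(256, 256, 2))
  f <- patchgan_fwd(disc, x)
  # probe the footprint of one central output unit via input gradients
  dy <- f$y * 0
  ctr <- floor(dim(f$y)[1:2] / 2)
  dy[ctr[1], ctr[2], 1] <- 1
  b <- patchgan_bwd(disc, f$cache, dy)
  nz <- which(apply(abs(b$dx), c(1, 2), max) > 0, arr.ind = TRUE)
  extent <- apply(nz, 2, function(v) diff(range(v)) + 1)
  expect_lte(max(extent), 70)
  expect_gte(min(extent), 63)
})

test_that("cross-task losses realize their analytic extremes", {
  n <- 8
  ones <- matrix(1, n, n)
  zeros <- matrix(0, n, n)
  # identical DAPI and H&E: zero consistency
  pred <- list(lap2 = ones * 0.5, dapi = ones, panck = zeros, he = ones)
  r <- cross_task_losses(pred)
  expect_equal(r$terms[["consistency"]], 0)
  # full co-activation / disjoint supports for the exclusivity term
  p2 <- list(lap2 = ones, dapi = ones, panck = ones, he = ones)
  expect_equal(cross_task_losses(p2)$terms[["exclusive"]], 1)
  left <- zeros; left[, 1:4] <- 1
  right <- zeros; right[, 5:8] <- 1
  p3 <- list(lap2 = left, dapi = ones, panck = right, he = ones)
  expect_equal(cross_task_losses(p3)$terms[["exclusive"]], 0)
  # masked-mean consistency arithmetic on a 2x2 toy
  dapi <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  he <- dapi - matrix(c(0.5, 0, 0, 0.5), 2, byrow = TRUE)
  p4 <- list(lap2 = matrix(0, 2, 2), dapi = dapi,
             panck = matrix(0, 2, 2), he = he)
  r4 <- cross_task_losses(p4)
  expect_equal(r4$terms[["consistency"]], 0.25)
  # empty nuclear mask: defined as zero, with a warning
  p5 <- list(lap2 = zeros, dapi = zeros + 0.1, panck = zeros, he = ones)
  expect_warning(r5 <- cross_task_losses(p5), "empty")
  expect_equal(r5$terms[["consistency"]], 0)
  # weighted total with unit sub-losses
  ru <- structure(list(), class = "x")
  w <- cross_task_weights(alpha = 1.0, beta = 0.5, gamma = 0.2)
  expect_equal(sum(c(1, 1, 1) * c(w$alpha, w$beta, w$gamma)), 1.7)
})

test_that("cross-task gradients match finite differences", {
  set.seed(9)
  pred <- array(runif(6 * 6 * 4, 0.05, 0.95), c(6, 6, 4))
  r <- cross_task_losses(pred, with_grads = TRUE)
  h <- 1e-6
  for (ci in 1:4) {
    for (px in list(c(2, 3), c(5, 1))) {
      pp <- pred; pp[px[1], px[2], ci] <- pp[px[1], px[2], ci] + h
      pm <- pred; pm[px[1], px[2], ci] <- pm[px[1], px[2], ci] - h
      fd <- (cross_task_losses(pp)$total - cross_task_losses(pm)$total) /
        (2 * h)
      ana <- r$grads[[ptychostain:::STAIN_CHANNELS[ci]]][px[1], px[2]]
      expect_equal(ana, fd, tolerance = 1e-5,
                   label = sprintf("channel %d px (%d,%d)", ci, px[1],
                                   px[2]))
    }
  }
})

test_that("the staining objective assembles with the published weights", {
  gan <- setNames(rep(1, 4), ptychostain:::STAIN_CHANNELS)
  l1 <- gan; dp <- gan
  rep <- stain_objective(gan, l1, dp, crosstack <- 1.7)
  expect_equal(rep$total, 4 * (1 + 10.0 + 0.2) + 1.0 * 1.7)
  expect_equal(rep$total, 46.5)
  expect_identical(rep$total, sum(rep$weighted))
  # perfect predictions zero the non-adversarial terms
  z <- setNames(rep(0, 4), ptychostain:::STAIN_CHANNELS)
  rep0 <- stain_objective(gan, z, z, 0)
  expect_equal(rep0$total, 4)
  expect_error(stain_objective(gan[1:3], l1, dp, 0), "missing")
})

test_that("the joint-training balance weight warms up linearly", {
  w <- stain_objective_weights()
  expect_equal(lambda_s_schedule(0, w), 0.1)
  expect_equal(lambda_s_schedule(5, w), 0.3)
  expect_equal(lambda_s_schedule(10, w), 0.5)
  expect_equal(lambda_s_schedule(20, w), 0.5)
})

test_that("short supervised training learns and respects determinism", {
  pairs <- lapply(1:6, function(i) {
    tiny_bundle(20 + i)
  })
  cfg <- small_cfg()
  m1 <- suppressWarnings(train_stain(pairs, cfg, epochs = 2, lr = 2e-3,
                                     seed = 5))
  m2 <- suppressWarnings(train_stain(pairs, cfg, epochs = 2, lr = 2e-3,
                                     seed = 5))
  expect_identical(m1$gens$shared$head$w, m2$gens$shared$head$w)
  h <- attr(m1, "history")
  expect_equal(nrow(h), 2)
  # L1 decreases over epochs at this scale
  expect_lt(h$l1[2], h$l1[1])
})

test_that("single-task mode instantiates four independent generators", {
  cfg <- small_cfg(single_task = TRUE)
  m <- ptychostain:::new_stain_model(cfg)
  expect_length(m$gens, 4)
  expect_named(m$gens, ptychostain:::STAIN_CHANNELS)
  expect_false(identical(m$gens$lap2$head$w, m$gens$dapi$head$w))
  b <- tiny_bundle(1)
  y <- ptychostain:::model_predict(m, b$interface)
  expect_equal(dim(y), c(32, 32, 4))
})
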