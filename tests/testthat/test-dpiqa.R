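# Difference-perception quality critic.

test_that("assessment scores are finite, bounded, and symmetric", {
  p <- dpiqa_new(width = 4, seed = 2)
  set.seed(3)
  for (k in 1:5) {
    i1 <- matrix(runif(24 * 24), 24)
    i2 <- matrix(runif(24 * 24), 24)
    a12 <- dpiqa_assess(p, i1, i2)
    a21 <- dpiqa_assess(p, i2, i1)
    expect_true(is.finite(a12$q_main) && is.finite(a12$d))
    expect_true(a12$q_main > 0 && a12$q_main < 1)
    expect_true(a12$q_aux > 0 && a12$q_aux < 1)
    expect_gte(a12$d, 0)
    expect_equal(a12$d, a21$d, tolerance = 1e-6)
  }
  expect_error(dpiqa_assess(p, matrix(0, 24, 24), matrix(0, 12, 12)),
               "equal shapes")
})

test_that("an identical pair has zero difference target by construction", {
  p <- dpiqa_new(width = 4, seed = 2)
  i1 <- matrix(runif(16 * 16), 16)
  a <- dpiqa_assess(p, i1, i1)
  expect_true(all(a$f_diff == 0))
  # with d trained on |q1 - q2| labels, the identical-pair target is 0
  expect_equal(abs(1 - 1), 0)
})

test_that("the combined quality loss follows its stated arithmetic", {
  a <- list(q_main = 0.8, q_aux = 0.7, d = 0.5)
  r <- dpiqa_loss(a, q = 0.6, q2 = 0.8)
  expect_equal(unname(r$terms["main"]), 0.2)
  expect_equal(unname(r$terms["aux"]), 0.1)
  expect_equal(unname(r$terms["diff"]), 0.3)
  expect_equal(r$total, 0.2 + 0.5 * 0.1 + 0.5 * 0.3)
  expect_equal(r$total, 0.4)
  # perfect predictions and nonnegativity
  perf <- list(q_main = 0.6, q_aux = 0.6, d = 0.2)
  expect_equal(dpiqa_loss(perf, q = 0.6, q2 = 0.4)$total, 0)
  expect_gte(dpiqa_loss(a, 0.1, 0.9)$total, 0)
  expect_error(dpiqa_loss(a, q = NULL), "labels")
})

test_that("distortion labeling is monotone in strength", {
  img <- make_phantom("texture", 32, seed = 4)$amplitude
  expect_equal(distort_image(img, "blur", 0)$q, 1)
  qs <- sapply(c(0.2, 0.5, 0.9), function(s) {
    distort_image(img, "blur", s)$q
  })
  expect_true(all(diff(qs) < 0))
  # stronger blur never gets a larger label than weaker blur
  expect_true(all(qs <= 1))
  # distortions stay in range
  for (tp in c("blur", "noise", "quant")) {
    d <- distort_image(img, tp, 0.8, seed = 9)
    expect_gte(min(d$img), 0)
    expect_lte(max(d$img), 1)
  }
})

test_that("critic parameter gradients match finite differences", {
  set.seed(5)
  p <- dpiqa_new(width = 4, seed = 6)
  i1 <- matrix(runif(16 * 16), 16)
  i2 <- matrix(runif(16 * 16), 16)
  a <- dpiqa_assess(p, i1, i2, want_cache = TRUE)
  b <- dpiqa_assess_bwd(p, a$cache, dq_main = 1, dq_aux = 0.5, dd = 0.25)
  h <- 1e-5
  val <- function(pp) {
    aa <- dpiqa_assess(pp, i1, i2)
    aa$q_main + 0.5 * aa$q_aux + 0.25 * aa$d
  }
  for (nm in c("lv1", "m1", "mh1", "dif1")) {
    pp <- p; pp[[nm]]$w[1, 1] <- p[[nm]]$w[1, 1] + h
    pm <- p; pm[[nm]]$w[1, 1] <- p[[nm]]$w[1, 1] - h
    fd <- (val(pp) - val(pm)) / (2 * h)
    expect_equal(b$grads[[nm]]$w[1, 1], fd, tolerance = 1e-4,
                 label = paste("grad", nm))
  }
  # image gradient (used by the frozen-critic perceptual distance)
  d1 <- dpiqa_distance(p, i1, i2, scales = 2, want_grad = TRUE)
  px <- c(3, 7)
  ip <- i1; ip[px[1], px[2]] <- ip[px[1], px[2]] + h
  im <- i1; im[px[1], px[2]] <- im[px[1], px[2]] - h
  fd <- (dpiqa_distance(p, ip, i2, scales = 2)$d -
           dpiqa_distance(p, im, i2, scales = 2)$d) / (2 * h)
  expect_equal(d1$grad[px[1], px[2]], fd, tolerance = 1e-4)
})

test_that("the critic stays frozen during generator updates", {
  pairs <- lapply(1:3, function(i) {
    tiny_bundle(30 + i)
  })
  critic <- dpiqa_new(width = 4, seed = 1)
  snapshot <- unserialize(serialize(critic, NULL))
  cfg <- stain_net_config(base_width = 4, disc_width = 4,
                          use_dpiqa = TRUE, seed = 3)
  m <- suppressWarnings(train_stain(pairs, cfg, critic = critic,
                                    epochs = 1, lr = 1e-3, seed = 2))
  expect_identical(critic, snapshot)
})

test_that("training on synthetic distortions yields rank-consistent scores", {
  corpus <- lapply(1:55, function(i) {
    make_phantom("texture", 32, seed = 100 + i)$amplitude
  })
  fit <- train_dpiqa(corpus, seed = 1, steps = 300, lr = 4e-3, width = 8,
                     n_variants = 8)
  # smoke-scale bound; the full-scale battery is exercised in the
  # acceptance suite at the documented corpus size and budget
  expect_gte(fit$spearman, 0.5)
  expect_lt(mean(tail(fit$trace, 30)), mean(head(fit$trace, 30)))
  expect_error(train_dpiqa(corpus[1:10]), "too small")
})
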