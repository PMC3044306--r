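test_that("logistic fit is symmetric on symmetric data and flips with labels", {
  scores <- c(rep(1, 10), rep(-1, 10)) + rep(c(0.3, -0.3), 10)
  labels <- rep(c(1, -1), each = 10)
  fit <- fit_lr(scores, labels)
  expect_equal(lr_posterior(fit, 0), 0.5, tolerance = 1e-6)
  flip <- fit_lr(scores, -labels)
  expect_equal(flip$slope, -fit$slope, tolerance = 1e-6)
  expect_equal(lr_posterior(flip, 0.7), 1 - lr_posterior(fit, 0.7),
               tolerance = 1e-6)
})

test_that("separated data falls back to bounded ridge coefficients matching IRLS", {
  scores <- c(-2, -1, 1, 2)
  labels <- c(-1, -1, 1, 1)
  expect_warning(fit <- fit_lr(scores, labels), "separation")
  want <- unname(oracle_irls_logistic(scores, as.integer(labels > 0),
                                      lambda = 1e-6))
  expect_equal(fit$intercept, want[1], tolerance = 1e-4)
  expect_equal(fit$slope, want[2], tolerance = 1e-4)
  expect_true(is.finite(fit$slope) && abs(fit$slope) < 1e3)
})

test_that("non-separable fits agree with glm and the posterior behaves", {
  set.seed(61)
  scores <- c(rnorm(40, 1), rnorm(40, -1))
  labels <- rep(c(1, -1), each = 40)
  fit <- fit_lr(scores, labels)
  ref <- stats::glm(I(labels > 0) ~ scores, family = stats::binomial())
  expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-8)
  expect_equal(fit$slope, unname(coef(ref)[2]), tolerance = 1e-8)
  # in range, monotone, sigmoid center at the decision score
  s <- seq(-5, 5, by = 0.5)
  p <- lr_posterior(fit, s)
  expect_true(all(p > 0 & p < 1))
  expect_true(all(diff(p) > 0))
  s0 <- -fit$intercept / fit$slope
  expect_equal(lr_posterior(fit, s0), 0.5, tolerance = 1e-10)
  expect_equal(lr_posterior(fit, 1e6), 1, tolerance = 1e-6)
})

test_that("the empirical null is deterministic, location-equivariant and calibrated", {
  set.seed(62)
  # Gumbel-min sample: the fitted family, so the CDF checks are sharp
  g <- 1.1 - 0.3 * log(-log(runif(400)))   # Gumbel-max
  r <- pmax(2.2 - (g - 1.1), 0.05)          # reflect into a min-type sample
  tm <- make_template(4, seed = 62)
  m1 <- fit_pints_null(r, tm)
  m2 <- fit_pints_null(r, tm)
  expect_identical(m1, m2)
  expect_gt(m1$null_scale, 0)
  expect_equal(m1$matched_atom_count, 4L)

  shifted <- fit_pints_null(r + 1, tm)
  expect_equal(shifted$null_location, m1$null_location + 1, tolerance = 1e-10)
  expect_equal(shifted$null_scale, m1$null_scale, tolerance = 1e-10)

  # expected frequency at the null median ~ 0.5 * n within sampling error
  no_pen <- function(m) 0
  f_med <- exp(pints_logF(m1, stats::median(r), size_penalty = no_pen))
  expect_equal(f_med / length(r), 0.5, tolerance = 0.12)
  # and at the 5th percentile ~ 0.05 * n
  f_05 <- exp(pints_logF(m1, stats::quantile(r, 0.05), size_penalty = no_pen))
  expect_equal(f_05 / length(r), 0.05, tolerance = 0.6)
  expect_error(fit_pints_null(r[1:10], tm), "at least 20")
})

test_that("logF is monotone in deviation and in template size", {
  set.seed(63)
  r <- abs(rnorm(100, 1.5, 0.4))
  m4 <- fit_pints_null(r, 4L)
  m8 <- fit_pints_null(r, 8L)
  dev <- seq(0, 2, by = 0.1)   # below CDF saturation in double precision
  lf <- pints_logF(m4, dev)
  expect_true(all(diff(lf) > 0))
  expect_lt(pints_logF(m8, 1.0), pints_logF(m4, 1.0))
  # deviation zero is the minimum over any non-negative deviation
  expect_true(all(pints_logF(m4, 0) <= pints_logF(m4, dev)))
})

test_that("posterior transforms preserve within-template ranking", {
  set.seed(64)
  scores <- rnorm(30)
  labels <- sign(scores + rnorm(30, sd = 2))
  labels[labels == 0] <- 1
  fit <- fit_lr(scores, labels)
  expect_equal(order(lr_posterior(fit, scores)), order(scores))
})

test_that("merged rankings keep duplicate template hits and break ties deterministically", {
  scored <- data.frame(
    structure_id = c("p1", "p1", "p2"),
    residue_key = c("A:1+A:2", "A:1+A:2", "A:9+A:8"),
    template_id = c("t1", "t2", "t1"),
    score = c(0.5, 0.5, 0.5),
    confidence = c(0.9, 0.9, 0.9),
    orientation = "deviation",
    stringsAsFactors = FALSE
  )
  rk <- merge_rankings(scored, method = "lr")
  expect_equal(nrow(rk), 3L)
  expect_equal(rk$rank, 1:3)
  # same site under two templates keeps two rows
  expect_equal(sum(rk$residue_key == "A:1+A:2"), 2L)
  # ties resolved by (structure_id, residue_key, template_id)
  expect_equal(rk$template_id[rk$residue_key == "A:1+A:2"], c("t1", "t2"))
})

test_that("direct ranking refuses mixed orientations and sorts each correctly", {
  base <- data.frame(
    structure_id = c("p1", "p2"), residue_key = c("A:1", "A:2"),
    template_id = "t1", score = c(0.2, 0.8), confidence = NA_real_,
    stringsAsFactors = FALSE
  )
  dev <- transform(base, orientation = "deviation")
  sim <- transform(base, orientation = "similarity")
  expect_equal(merge_rankings(dev, "direct")$score, c(0.2, 0.8))
  expect_equal(merge_rankings(sim, "direct")$score, c(0.8, 0.2))
  mixed <- rbind(dev, sim)
  expect_error(merge_rankings(mixed, "direct"), "configuration error")
})

test_that("trained models survive a JSON round trip", {
  cfg <- heterogeneous_benchmark()
  tm <- make_template(cfg$m, seed = 65)
  sites <- make_sites(tm, 8, 32, cfg$profile, seed = 65)
  wm <- train_wmd(sites, tm)
  dm <- train_dsds_sites(sites, tm)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(wm, f)
  wm2 <- read_model(f)
  expect_equal(wm2$weights$beta, wm$weights$beta, tolerance = 1e-12)
  expect_equal(wm2$threshold, wm$threshold, tolerance = 1e-12)
  write_model(dm, f)
  dm2 <- read_model(f)
  expect_equal(dm2$coefficients, dm$coefficients, tolerance = 1e-12)
})
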