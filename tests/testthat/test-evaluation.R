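test_that("roc_score handles the canonical endpoint and tie cases", {
  expect_equal(roc_score(c(3, 4, 1, 2), c(1, 1, -1, -1)), 1.0)
  expect_equal(roc_score(rep(1, 10), rep(c(1, -1), 5)), 0.5)
  expect_equal(roc_score(c(0.9, 0.4, 0.6, 0.1), c(1, 1, -1, -1)), 0.75)
  expect_error(roc_score(1:3, c(1, 1, 1)), "both classes")
})

test_that("roc_score equals brute-force pair counting on random instances", {
  set.seed(71)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    y <- c(1, -1, sample(c(-1, 1), n - 2, replace = TRUE))
    s <- sample(round(rnorm(n), 2))   # rounding creates ties
    expect_equal(roc_score(s, y), oracle_roc_paircount(s, y),
                 tolerance = 1e-12)
  }
})

test_that("roc5 endpoint and worked cases are exact", {
  # perfect ranking
  expect_equal(roc5_score(c(9, 8, 7, 1, 2, 3, 4, 5, 6) / 10,
                          c(1, 1, 1, rep(-1, 6))), 1.0)
  # single positive buried below 5 negatives
  expect_equal(roc5_score(c(1, 9, 8, 7, 6, 5, 4), c(1, rep(-1, 6))), 0.0)
  # single positive below exactly 2 of >= 5 negatives
  expect_equal(roc5_score(c(7, 9, 8, 6, 5, 4, 3), c(1, rep(-1, 6))), 0.6)
})

test_that("roc5 equals roc when there are exactly five negatives", {
  set.seed(72)
  for (i in 1:30) {
    y <- c(rep(1, sample(2:6, 1)), rep(-1, 5))
    s <- rnorm(length(y))
    expect_equal(roc5_score(s, y), roc_score(s, y), tolerance = 1e-12)
  }
})

test_that("roc5 is 1 exactly when no positive ranks below a top-5 negative", {
  set.seed(73)
  for (i in 1:30) {
    n_pos <- sample(2:5, 1); n_neg <- sample(6:15, 1)
    s <- rnorm(n_pos + n_neg)
    y <- c(rep(1, n_pos), rep(-1, n_neg))
    v <- roc5_score(s, y)
    # the truncated area is full exactly when every positive outranks the
    # first false positive, i.e. the highest-scoring negative
    clean <- all(s[y > 0] > max(s[y < 0]))
    expect_lte(v, 1)
    expect_equal(v == 1, clean)
  }
})

test_that("sensitivity at 95% specificity follows the conservative convention", {
  # perfect separation
  expect_equal(sensitivity_at_specificity(c(5, 4, 1, 2, 3) / 10,
                                          c(1, 1, -1, -1, -1)), 1.0)
  # indistinguishable classes with >= 20 negatives
  expect_equal(sensitivity_at_specificity(rep(1, 25),
                                          c(rep(1, 5), rep(-1, 20))), 0.0)
  # one positive on top of 20 spread negatives: FPR 1/20 = 0.05 is admitted
  s <- c(0.9, 0.8 - 0.01 * (0:19))
  y <- c(1, rep(-1, 20))
  expect_equal(sensitivity_at_specificity(s, y), 1.0)
  # raising the specificity requirement cannot raise sensitivity
  set.seed(74)
  sc <- rnorm(60); yy <- rep(c(1, -1), 30)
  sens <- vapply(c(0.8, 0.9, 0.95, 0.99), function(sp) {
    sensitivity_at_specificity(sc, yy, sp)
  }, 1)
  expect_true(all(diff(sens) <= 1e-12))
})

test_that("roc curves are monotone with the right endpoints", {
  set.seed(75)
  cv <- roc_curve(rnorm(40), rep(c(1, -1), 20))
  expect_equal(cv$fpr[1], 0); expect_equal(cv$tpr[1], 0)
  expect_equal(cv$fpr[nrow(cv)], 1); expect_equal(cv$tpr[nrow(cv)], 1)
  expect_true(all(diff(cv$fpr) >= 0))
  expect_true(all(diff(cv$tpr) >= 0))
})

test_that("splits are deterministic, balanced and template-covering", {
  set.seed(76)
  tab <- data.frame(
    structure_id = rep(sprintf("S%03d", 1:20), each = 3),
    template_id = rep(c("t1", "t2", "t3"), 20),
    label = -1, stringsAsFactors = FALSE
  )
  # give each template positives in 4 distinct structures
  for (tid in c("t1", "t2", "t3")) {
    rows <- which(tab$template_id == tid)
    tab$label[rows[seq(1, 12, by = 3)]] <- 1
  }
  p1 <- make_splits(tab, n_repeats = 5, seed = 9)
  p2 <- make_splits(tab, n_repeats = 5, seed = 9)
  expect_identical(p1, p2)
  for (pl in p1) {
    expect_length(intersect(pl$train_ids, pl$test_ids), 0L)
    expect_equal(length(pl$train_ids), 10L)
    for (tid in c("t1", "t2", "t3")) {
      pos_structs <- tab$structure_id[tab$template_id == tid & tab$label > 0]
      expect_true(any(pos_structs %in% pl$train_ids))
    }
  }
})

test_that("a two-structure dataset is forced into opposite halves", {
  tab <- data.frame(structure_id = c("a", "b"), template_id = "t1",
                    label = c(1, 1), stringsAsFactors = FALSE)
  plans <- make_splits(tab, n_repeats = 4, seed = 2)
  for (pl in plans) {
    expect_length(pl$train_ids, 1L)
    expect_length(pl$test_ids, 1L)
  }
})

test_that("an uncoverable template is reported by name", {
  tab <- data.frame(structure_id = c("a", "a", "b"),
                    template_id = c("t1", "t1", "t2"),
                    label = c(1, -1, 1), stringsAsFactors = FALSE)
  expect_error(make_splits(tab, n_repeats = 1, seed = 1), "t1")
})

test_that("percentile curves reduce correctly on identical and paired input", {
  cv <- data.frame(fpr = c(0, 0.5, 1), tpr = c(0, 0.8, 1))
  agg <- aggregate_curves(list(cv, cv, cv))
  expect_equal(agg$p25, agg$p50)
  expect_equal(agg$p50, agg$p75)
  lo <- data.frame(fpr = c(0, 1), tpr = c(0, 1))         # diagonal
  hi <- data.frame(fpr = c(0, 0, 1), tpr = c(0, 1, 1))   # perfect
  agg2 <- aggregate_curves(list(lo, hi), percentiles = 50)
  grid <- agg2$fpr
  expect_equal(agg2$p50, (grid + 1) / 2, tolerance = 1e-12)
  expect_error(aggregate_curves(list()), "no curves")
})

test_that("three step curves aggregate to hand-computed percentiles", {
  c1 <- data.frame(fpr = c(0, 0.2, 1), tpr = c(0, 0.2, 1))
  c2 <- data.frame(fpr = c(0, 0.2, 1), tpr = c(0, 0.6, 1))
  c3 <- data.frame(fpr = c(0, 0.2, 1), tpr = c(0, 1.0, 1))
  agg <- aggregate_curves(list(c1, c2, c3), percentiles = c(25, 50, 75),
                          grid = c(0, 0.2, 1))
  expect_equal(agg$p50[2], 0.6)
  expect_equal(agg$p25[2], 0.4)   # quantile type 7 between 0.2 and 0.6
  expect_equal(agg$p75[2], 0.8)
})
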