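test_that("time-series folds follow the expanding-window geometry", {
  d <- as.Date("2000-01-01") + 1:12
  folds <- time_series_folds(d, 5)
  expect_length(folds, 5)
  expect_equal(vapply(folds, function(f) length(f$test), 0L),
               rep(2L, 5))
  expect_equal(vapply(folds, function(f) length(f$train), 0L),
               c(2L, 4L, 6L, 8L, 10L))
  # n = 6: singleton test blocks
  folds6 <- time_series_folds(as.Date("2000-01-01") + 1:6, 5)
  expect_equal(vapply(folds6, function(f) length(f$test), 0L),
               rep(1L, 5))
  expect_error(time_series_folds(as.Date("2000-01-01") + 1:5, 5),
               "more than")
})

test_that("every test compound is strictly newer than its training
           compounds", {
  for (seed in 1:5) {
    d <- withr::with_seed(seed,
      sample(seq(as.Date("2001-01-01"), as.Date("2015-01-01"), by = "day"),
             40))
    folds <- time_series_folds(d, 5)
    for (f in folds) {
      expect_gt(min(as.numeric(d[f$test])), max(as.numeric(d[f$train])))
      expect_length(intersect(f$train, f$test), 0)
    }
    # training sets are nested and chronological
    sizes <- vapply(folds, function(f) length(f$train), 0L)
    expect_true(all(diff(sizes) > 0))
  }
})

test_that("classification metrics follow the confusion matrix and leave
           undefined precision as NA", {
  m <- classification_metrics(c(0.9, 0.8, 0.2, 0.1),
                              c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(unlist(m), c(precision = 1, recall = 1, f1 = 1))
  # TP = 2, FP = 1, FN = 1
  m2 <- classification_metrics(c(0.9, 0.8, 0.7, 0.2),
                               c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(m2$precision, 2 / 3)
  expect_equal(m2$recall, 2 / 3)
  expect_equal(m2$f1, 2 / 3)
  # no positive calls
  m3 <- classification_metrics(c(0.1, 0.2), c(TRUE, FALSE))
  expect_true(is.na(m3$precision))
  expect_equal(m3$recall, 0)
  expect_error(classification_metrics(numeric(0), logical(0)), "no pred")
})

test_that("F1 equals an independent confusion-matrix oracle on random
           fixtures", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(4:40, 1)
    p <- runif(n)
    y <- runif(n) < 0.4
    if (!any(y)) y[1] <- TRUE
    m <- classification_metrics(p, y)
    pred <- p > 0.5
    tp <- sum(pred & y); fp <- sum(pred & !y); fn <- sum(!pred & y)
    f1_oracle <- if (tp + fp == 0) NA_real_
                 else if (2 * tp + fp + fn == 0) 0
                 else 2 * tp / (2 * tp + fp + fn)
    expect_identical(is.na(m$f1), is.na(f1_oracle))
    if (!is.na(f1_oracle)) expect_equal(m$f1, f1_oracle)
  }
})

test_that("PR-AUC matches a brute-force threshold sweep", {
  # perfect ranking
  expect_equal(pr_auc(c(0.9, 0.8, 0.2, 0.1),
                      c(TRUE, TRUE, FALSE, FALSE)), 1)
  # brute-force step-sum oracle with tie grouping
  brute_pr_auc <- function(s, y) {
    area <- 0; prev_recall <- 0
    for (thr in sort(unique(s), decreasing = TRUE)) {
      pred <- s >= thr
      recall <- sum(pred & y) / sum(y)
      precision <- sum(pred & y) / sum(pred)
      area <- area + (recall - prev_recall) * precision
      prev_recall <- recall
    }
    area
  }
  # reversed perfect ranking, 5 actives / 95 inactives
  y <- c(rep(TRUE, 5), rep(FALSE, 95))
  s <- seq(0.01, 1, length.out = 100)   # actives get the lowest scores
  expect_equal(pr_auc(s, y), brute_pr_auc(s, y))
  set.seed(7)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    s <- round(runif(n), 2)             # ties likely
    y <- runif(n) < 0.3
    if (!any(y)) y[1] <- TRUE
    if (all(y)) y[1] <- FALSE
    expect_equal(pr_auc(s, y), brute_pr_auc(s, y))
  }
  expect_error(pr_auc(1:3, c(TRUE, TRUE, TRUE)), "single-class")
})

test_that("PR-AUC of random scores approaches the class prevalence", {
  set.seed(31)
  n <- 20000
  y <- runif(n) < 0.1
  s <- runif(n)
  expect_equal(pr_auc(s, y), mean(y), tolerance = 0.05)
})

test_that("BEDROC reaches its extremes and tolerates the degenerate
           all-active input", {
  n <- 10; N <- 1000
  y_best <- c(rep(TRUE, n), rep(FALSE, N - n))
  s <- seq(1, 0.001, length.out = N)
  expect_equal(bedroc(s, y_best, 20), 1, tolerance = 0.01)
  y_worst <- c(rep(FALSE, N - n), rep(TRUE, n))
  expect_equal(bedroc(s, y_worst, 20), 0, tolerance = 0.01)
  expect_warning(v <- bedroc(1:5, rep(TRUE, 5)), "degenerate")
  expect_equal(v, 1)
  expect_error(bedroc(1:5, rep(FALSE, 5)), "without actives")
})

test_that("BEDROC is invariant under strictly monotone score
           transforms", {
  set.seed(41)
  s <- rnorm(300)
  y <- runif(300) < 0.1
  if (!any(y)) y[1] <- TRUE
  base <- bedroc(s, y, 20)
  expect_equal(bedroc(2 * s + 3, y, 20), base)
  expect_equal(bedroc(exp(s), y, 20), base)
  expect_equal(bedroc(rank(s, ties.method = "first"), y, 20), base)
})

test_that("small-alpha BEDROC is linear in the mean active rank", {
  set.seed(51)
  N <- 400; n <- 20
  vals <- t(vapply(1:12, function(i) {
    s <- runif(N)
    y <- rep(FALSE, N)
    y[sample(N, n)] <- TRUE
    r <- which(y[order(-s)])
    c(bedroc(s, y, alpha = 1e-3), mean(r))
  }, numeric(2)))
  fit <- stats::lm(vals[, 1] ~ vals[, 2])
  expect_gt(summary(fit)$r.squared, 0.999)
  expect_lt(stats::coef(fit)[2], 0)    # earlier actives, higher score
})

test_that("per-target cross-validation produces the metric suite per
           fold", {
  toy <- separable_toy(n_active = 24, n_inactive = 48)
  d <- as.Date("2005-01-01") + withr::with_seed(61, sample(3000, 72))
  cv <- cv_target(toy$x, toy$y, d, metric_config(n_splits = 4),
                  seed = 3, algorithm = "bernoulli_nb", alpha = 1)
  expect_equal(nrow(cv), 4)
  done <- !is.na(cv$f1)
  expect_true(any(done))
  expect_true(all(cv$f1[done] >= 0 & cv$f1[done] <= 1))
  expect_true(all(cv$bedroc[!is.na(cv$bedroc)] <= 1))
})

test_that("benchmark pairing reports deltas, medians and the
           stable-or-improved share", {
  mk <- function(f1s) lapply(f1s, function(v)
    data.frame(fold = 1:2, n_train = 10, n_test = 5,
               precision = v, recall = v, f1 = v,
               pr_auc = v, bedroc = v))
  before <- mk(c(a = 0.5, b = 0.7, c = 0.9))
  # identical arms: all deltas zero, 100% stable-or-improved
  rep0 <- benchmark(before, before)
  expect_true(all(rep0$per_target$f1_delta == 0))
  expect_equal(rep0$summary$share_stable_or_improved_f1, 1)
  # one arm strictly better everywhere
  after <- mk(c(a = 0.6, b = 0.8, c = 0.95))
  rep1 <- benchmark(before, after)
  expect_equal(rep1$summary$share_stable_or_improved_f1, 1)
  expect_gt(rep1$summary$median_f1_delta, 0)
  # medians match a sorting oracle
  expect_equal(rep1$summary$f1_before[["median"]],
               sort(c(0.5, 0.7, 0.9))[2])
  expect_equal(rep1$summary$f1_after[["median"]],
               sort(c(0.6, 0.8, 0.95))[2])
  expect_error(benchmark(before, after[1:2]), "same targets")
})

test_that("the external-validation harness scores labelled compounds", {
  toy <- separable_toy(n_active = 20, n_inactive = 60)
  fit <- target_model(toy$x, toy$y, "linear_svm", seed = 9)
  ext <- separable_toy(n_active = 10, n_inactive = 30, seed = 123)
  out <- external_validate(fit, ext$x, ext$y)
  expect_equal(out$n, 40)
  expect_true(out$f1 > 0.5)
  expect_true(out$pr_auc > 0.5)
})
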