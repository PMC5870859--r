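#' Metric settings for model evaluation
#'
#' @param decision_threshold probability above which a compound is called
#'   active (default 0.5).
#' @param bedroc_alpha early-recognition exponent for BEDROC (default 20).
#' @param n_splits number of time-series folds (default 5).
#' @return a `metric_config` list.
#' @export
metric_config <- function(decision_threshold = 0.5, bedroc_alpha = 20,
                          n_splits = 5L) {
  stopifnot(decision_threshold > 0, decision_threshold < 1,
            bedroc_alpha > 0, n_splits >= 2)
  structure(list(decision_threshold = decision_threshold,
                 bedroc_alpha = bedroc_alpha,
                 n_splits = as.integer(n_splits)),
            class = "metric_config")
}

#' Expanding-window time-series cross-validation folds
#'
#' Records are ordered by date (missing dates last, original order
#' preserved among ties).  With `t = floor(n / (n_splits + 1))`, the test
#' blocks are the `n_splits` consecutive windows of size `t` ending at the
#' newest record; fold `k` trains on everything older than its test
#' block, so training sets are nested and strictly chronological and the
#' oldest `n - n_splits * t` records are never tested.
#'
#' @param dates vector of dates (or anything orderable) per record.
#' @param n_splits number of folds.
#' @return list of `n_splits` elements, each `list(train =, test =)` with
#'   integer indices into the original record order.
#' @export
time_series_folds <- function(dates, n_splits = 5L) {
  n <- length(dates)
  if (n <= n_splits)
    stop("need more than n_splits = ", n_splits, " records, got ", n,
         call. = FALSE)
  o <- order(dates, na.last = TRUE)
  t <- n %/% (n_splits + 1L)
  lapply(seq_len(n_splits), function(k) {
    test_end <- n - (n_splits - k) * t
    test_start <- test_end - t + 1L
    list(train = o[seq_len(test_start - 1L)],
         test = o[test_start:test_end])
  })
}

#' Precision, recall and F1 at a probability threshold
#'
#' Standard confusion-matrix definitions with predictions called active
#' at `p > threshold`.  When no compound is predicted active the
#' precision (and hence F1) is undefined and reported as `NA`, not zero.
#'
#' @param p predicted activity probabilities.
#' @param labels true activity labels.
#' @param threshold decision threshold (default 0.5).
#' @return list with `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(p, labels, threshold = 0.5) {
  if (length(p) == 0L) stop("no predictions to score", call. = FALSE)
  y <- as_active(labels)
  pred <- p > threshold
  tp <- sum(pred & y); fp <- sum(pred & !y); fn <- sum(!pred & y)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall)) NA_real_
        else if (precision + recall == 0) 0
        else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

#' Area under the precision-recall curve
#'
#' Interpolation-free step summation over score thresholds: descending
#' through the distinct scores (tied scores enter together), the area
#' accumulates `(recall_i - recall_{i-1}) * precision_i`.
#'
#' @param scores ranking scores (higher = more active).
#' @param labels true activity labels (both classes required).
#' @return area in `[0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  y <- as_active(labels)
  if (!any(y) || all(y))
    stop("PR-AUC undefined for single-class labels", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  y <- y[o]; s <- scores[o]
  last <- !duplicated(s, fromLast = TRUE)  # close each tie group
  tp <- cumsum(y)[last]
  npred <- seq_along(y)[last]
  recall <- tp / sum(y)
  precision <- tp / npred
  sum(diff(c(0, recall)) * precision)
}

#' BEDROC early-recognition metric
#'
#' Boltzmann-enhanced discrimination of ROC (Truchon-Bayly).  With `n`
#' actives among `N` compounds ranked by descending score at positions
#' `r_i`, the robust initial enhancement is
#' `RIE = sum(exp(-alpha * r_i / N)) / ((n/N) * (1 - exp(-alpha)) /
#' (exp(alpha/N) - 1))` and
#' `BEDROC = RIE * Ra * sinh(alpha/2) / (cosh(alpha/2) -
#' cosh(alpha/2 - alpha*Ra)) + 1 / (1 - exp(alpha * (1 - Ra)))` with
#' `Ra = n/N`.  Higher `alpha` concentrates the reward on the top of the
#' ranking; the conventional 20 weights roughly the top 8%.  Tied scores
#' are broken by stable input order with a warning.  The degenerate
#' all-active input is defined as 1.
#'
#' @param scores ranking scores.
#' @param labels true activity labels.
#' @param alpha early-recognition exponent (default 20).
#' @return value in `[0, 1]`.
#' @export
bedroc <- function(scores, labels, alpha = 20) {
  y <- as_active(labels)
  N <- length(y); n <- sum(y)
  if (n == 0) stop("BEDROC undefined without actives", call. = FALSE)
  if (n == N) {
    warning("all compounds active; BEDROC degenerate, returning 1")
    return(1)
  }
  if (anyDuplicated(scores))
    warning("tied scores broken by stable input order")
  o <- order(-scores)           # stable for ties
  r <- which(y[o])
  ra <- n / N
  rie <- sum(exp(-alpha * r / N)) /
    (ra * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  rie * ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra)) +
    1 / (1 - exp(alpha * (1 - ra)))
}

#' Time-series cross-validation of one target model
#'
#' Splits the target's records chronologically with
#' [time_series_folds()], trains a calibrated model on each fold's
#' training window and scores its test window.  Folds whose training
#' window contains a single class are reported with `NA` metrics (early
#' windows of sparse targets); ranking metrics additionally need both
#' classes in the test window.
#'
#' @param x fingerprint matrix for all of the target's records.
#' @param y activity labels.
#' @param dates per-record dates driving the split.
#' @param config a [metric_config()].
#' @param seed RNG seed passed to [target_model()].
#' @param ... algorithm and hyper-parameters for [target_model()].
#' @return data.frame with one row per fold: sizes and the metric suite.
#' @export
cv_target <- function(x, y, dates, config = metric_config(), seed = 1L,
                      ...) {
  y <- as_active(y)
  folds <- time_series_folds(dates, config$n_splits)
  rows <- lapply(seq_along(folds), function(k) {
    f <- folds[[k]]
    out <- data.frame(fold = k, n_train = length(f$train),
                      n_test = length(f$test),
                      precision = NA_real_, recall = NA_real_,
                      f1 = NA_real_, pr_auc = NA_real_,
                      bedroc = NA_real_)
    ytr <- y[f$train]
    if (length(unique(ytr)) < 2 || sum(ytr) < 2 || sum(!ytr) < 2)
      return(out)
    fit <- target_model(x[f$train, , drop = FALSE], ytr, seed = seed, ...)
    p <- predict(fit, x[f$test, , drop = FALSE])
    yte <- y[f$test]
    cm <- classification_metrics(p, yte, config$decision_threshold)
    out$precision <- cm$precision; out$recall <- cm$recall
    out$f1 <- cm$f1
    if (any(yte) && !all(yte)) {
      out$pr_auc <- pr_auc(p, yte)
      out$bedroc <- suppressWarnings(bedroc(p, yte, config$bedroc_alpha))
    }
    out
  })
  do.call(rbind, rows)
}

#' Pair two cross-validated model collections
#'
#' Compares per-target metrics between two arms sharing the same target
#' list and fold definitions -- canonically, training sets before and
#' after orthologue inclusion.  Per-target values are fold means; the
#' summary reports paired deltas, the share of targets with
#' stable-or-improved F1, and medians with interquartile ranges.
#'
#' @param before,after named lists (by target accession) of per-fold
#'   metric tables from [cv_target()].
#' @return a `benchmark_report` with `per_target` and `summary`.
#' @export
benchmark <- function(before, after) {
  if (!setequal(names(before), names(after)) ||
      is.null(names(before)) || anyNA(names(before)))
    stop("the two arms must cover the same targets", call. = FALSE)
  targets <- sort(names(before))
  agg <- function(cvres, metric)
    mean(cvres[[metric]], na.rm = TRUE)
  metrics <- c("precision", "recall", "f1", "pr_auc", "bedroc")
  per <- data.frame(target_accession = targets)
  for (m in metrics) {
    per[[paste0(m, "_before")]] <-
      vapply(before[targets], agg, 0, metric = m)
    per[[paste0(m, "_after")]] <-
      vapply(after[targets], agg, 0, metric = m)
    per[[paste0(m, "_delta")]] <-
      per[[paste0(m, "_after")]] - per[[paste0(m, "_before")]]
  }
  d <- per$f1_delta[!is.na(per$f1_delta)]
  med_iqr <- function(v) {
    v <- v[!is.na(v)]
    c(median = stats::median(v), iqr = stats::IQR(v))
  }
  summary <- list(
    n_targets = length(targets),
    share_stable_or_improved_f1 = if (length(d)) mean(d >= 0) else NA_real_,
    median_f1_delta = if (length(d)) stats::median(d) else NA_real_,
    f1_before = med_iqr(per$f1_before),
    f1_after = med_iqr(per$f1_after),
    bedroc_before = med_iqr(per$bedroc_before),
    bedroc_after = med_iqr(per$bedroc_after))
  structure(list(per_target = per, summary = summary),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  s <- x$summary
  cat("Paired cross-validation benchmark (", s$n_targets, " targets)\n",
      sep = "")
  cat(sprintf("  median F1 before/after : %.3f / %.3f (delta %+0.3f)\n",
              s$f1_before[["median"]], s$f1_after[["median"]],
              s$median_f1_delta))
  cat(sprintf("  stable or improved F1  : %.0f%%\n",
              100 * s$share_stable_or_improved_f1))
  cat(sprintf("  median BEDROC before/after : %.3f / %.3f\n",
              s$bedroc_before[["median"]], s$bedroc_after[["median"]]))
  invisible(x)
}

#' External-validation harness
#'
#' Scores an externally labelled compound table with a fitted model and
#' computes the full metric suite, the role in-house screening data plays
#' for realized models.
#'
#' @param model a [target_model()].
#' @param x fingerprints of the external compounds.
#' @param labels external activity labels.
#' @param config a [metric_config()].
#' @return one-row data.frame of metrics.
#' @export
external_validate <- function(model, x, labels,
                              config = metric_config()) {
  p <- predict(model, x)
  y <- as_active(labels)
  cm <- classification_metrics(p, y, config$decision_threshold)
  data.frame(n = length(p),
             precision = cm$precision, recall = cm$recall, f1 = cm$f1,
             pr_auc = if (any(y) && !all(y)) pr_auc(p, y) else NA_real_,
             bedroc = if (any(y) && !all(y))
               suppressWarnings(bedroc(p, y, config$bedroc_alpha))
             else NA_real_)
}
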