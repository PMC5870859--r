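#' Train a calibrated per-target activity classifier
#'
#' Fits one of three classifier families on binary fingerprints -- random
#' forest, Bernoulli naive Bayes or linear-kernel SVM -- and wraps it in
#' two-fold ensemble Platt calibration: the training data is split into
#' two stratified halves, the classifier is fitted on each half with a
#' sigmoid calibrator fitted on the held-out half, and predictions average
#' the two calibrated probabilities.  Class weighting balances the active
#' and inactive classes (weights inversely proportional to class
#' frequency), compensating for the typical 1:100 active:inactive ratio.
#'
#' Hyper-parameters follow the benchmarked grid: `trees` in {5, 50, 500}
#' for the forest (mtry = floor(sqrt(p)), unlimited depth), Laplace
#' `alpha` in {1.0, 0.1} for naive Bayes, and `cost` in {1e-2, 1, 1e2}
#' for the SVM.
#'
#' @param x binary fingerprint matrix (rows = compounds).
#' @param y activity labels: logical, or anything coercible with `TRUE` /
#'   `"active"` marking actives.
#' @param algorithm classifier family.
#' @param trees,alpha,cost hyper-parameters (used by their own family).
#' @param class_weighting balance classes by inverse frequency
#'   (default `TRUE`).
#' @param seed integer controlling the calibration split and forest
#'   randomness; fixed seed gives an identical model.
#' @param target_accession optional label stored in the model.
#' @return an object of class `target_model` with `predict`, `print` and
#'   `summary` methods.
#' @export
target_model <- function(x, y,
                         algorithm = c("random_forest", "bernoulli_nb",
                                       "linear_svm"),
                         trees = 500L, alpha = 1.0, cost = 1.0,
                         class_weighting = TRUE, seed = 1L,
                         target_accession = NULL) {
  algorithm <- match.arg(algorithm)
  y <- as_active(y)
  if (!any(y)) stop("training set has no active compounds", call. = FALSE)
  if (all(y)) stop("training set has no inactive compounds", call. = FALSE)
  x <- as_fp_matrix(x)
  halves <- withr::with_seed(seed, stratified_halves(y))
  members <- lapply(1:2, function(m) {
    fit_idx <- halves[[m]]
    cal_idx <- halves[[3 - m]]
    clf <- fit_base_classifier(x[fit_idx, , drop = FALSE], y[fit_idx],
                               algorithm, trees, alpha, cost,
                               class_weighting, seed + m)
    platt <- fit_platt(classifier_score(clf, x[cal_idx, , drop = FALSE]),
                       y[cal_idx])
    list(classifier = clf, platt = platt)
  })
  structure(list(members = members,
                 algorithm = algorithm,
                 hyperparams = switch(algorithm,
                                      random_forest = list(trees = trees),
                                      bernoulli_nb = list(alpha = alpha),
                                      linear_svm = list(cost = cost)),
                 class_weighting = class_weighting,
                 n_active = sum(y), n_inactive = sum(!y),
                 width = ncol(x), seed = as.integer(seed),
                 target_accession = target_accession),
            class = "target_model")
}

as_active <- function(y) {
  if (is.logical(y)) return(y)
  if (is.numeric(y)) return(y != 0)
  tolower(as.character(y)) %in% c("active", "true", "1")
}

as_fp_matrix <- function(x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("b", seq_len(ncol(x)))
  x
}

# Deterministic stratified 2-fold split (both halves see both classes
# whenever a class has >= 2 members).
stratified_halves <- function(y) {
  pick <- function(idx) {
    idx <- sample(idx)
    split(idx, rep(1:2, length.out = length(idx)))
  }
  a <- pick(which(y)); b <- pick(which(!y))
  list(sort(c(a[[1]], b[[1]])), sort(c(a[[2]], b[[2]])))
}

class_weights <- function(y, balanced) {
  if (!balanced) return(c(active = 1, inactive = 1))
  n <- length(y)
  c(active = n / (2 * sum(y)), inactive = n / (2 * sum(!y)))
}

# Fit one uncalibrated classifier; the fitted state is scored through
# classifier_score() so that model bundles stay free of closures (and of
# the training data their environments would drag along).
fit_base_classifier <- function(x, y, algorithm, trees, alpha, cost,
                                class_weighting, seed) {
  w <- class_weights(y, class_weighting)
  if (algorithm == "random_forest") {
    yf <- factor(ifelse(y, "active", "inactive"),
                 levels = c("inactive", "active"))
    fit <- ranger::ranger(x = x, y = yf, probability = TRUE,
                          num.trees = trees,
                          mtry = max(1L, floor(sqrt(ncol(x)))),
                          min.node.size = 1,
                          case.weights = unname(w[ifelse(y, "active",
                                                         "inactive")]),
                          seed = seed, num.threads = 1)
    flip <- 1
  } else if (algorithm == "bernoulli_nb") {
    fit <- bnb_fit(x, y, alpha = alpha, balanced = class_weighting)
    flip <- 1
  } else {
    yf <- factor(ifelse(y, "active", "inactive"),
                 levels = c("inactive", "active"))
    fit <- e1071::svm(x = x, y = yf, kernel = "linear", cost = cost,
                      scale = FALSE,
                      class.weights = w[levels(yf)])
    flip <- svm_orientation(fit, x, y)
  }
  structure(list(state = fit, algorithm = algorithm, flip = flip),
            class = "base_classifier")
}

# Monotone activity score (higher = more likely active) for a fitted
# base classifier on new fingerprints.
classifier_score <- function(clf, newx) {
  newx <- as_fp_matrix(newx)
  switch(clf$algorithm,
    random_forest = stats::predict(clf$state, data = newx,
                                   num.threads = 1)$predictions[, "active"],
    bernoulli_nb = bnb_log_odds(clf$state, newx),
    linear_svm = {
      dv <- attr(stats::predict(clf$state, newx, decision.values = TRUE),
                 "decision.values")[, 1]
      clf$flip * unname(dv)
    })
}

# libsvm orients decision values towards the first label it saw; fix the
# orientation empirically so higher always means more active.
svm_orientation <- function(fit, x, y) {
  dv <- attr(stats::predict(fit, x, decision.values = TRUE),
             "decision.values")[, 1]
  if (mean(dv[y]) >= mean(dv[!y])) 1 else -1
}

# -- Bernoulli naive Bayes -------------------------------------------------
# Feature-presence probabilities with Laplace smoothing; matrix algebra
# keeps 2048-bit fingerprints fast.  Balanced mode sets equal class
# priors, the class-weighting analogue for a generative model.

bnb_fit <- function(x, y, alpha = 1.0, balanced = TRUE) {
  n1 <- colSums(x[y, , drop = FALSE])
  n0 <- colSums(x[!y, , drop = FALSE])
  th1 <- (n1 + alpha) / (sum(y) + 2 * alpha)
  th0 <- (n0 + alpha) / (sum(!y) + 2 * alpha)
  prior_odds <- if (balanced) 0 else log(sum(y) / sum(!y))
  list(w = log(th1) - log(th0) - (log1p(-th1) - log1p(-th0)),
       b = sum(log1p(-th1)) - sum(log1p(-th0)) + prior_odds,
       alpha = alpha)
}

bnb_log_odds <- function(fit, x) {
  as.numeric(x %*% fit$w) + fit$b
}

#' Fit a Platt sigmoid calibrator
#'
#' Maximum-likelihood fit of `p = 1 / (1 + exp(A*s + B))` to classifier
#' scores, with Platt's smoothed targets `(n+ + 1)/(n+ + 2)` and
#' `1/(n- + 2)` guarding against overconfidence on small calibration
#' sets.  For scores oriented so that larger means more active the fitted
#' slope `A` is non-positive, making the calibrated probability a
#' monotone non-decreasing function of the score.
#'
#' @param scores numeric classifier scores.
#' @param labels activity labels (see [target_model()] for coercion).
#' @return named numeric vector `c(A, B)`.
#' @export
fit_platt <- function(scores, labels) {
  y <- as_active(labels)
  if (!any(y) || all(y))
    stop("calibration fold contains a single class (missing ",
         if (any(y)) "inactives" else "actives", ")", call. = FALSE)
  np <- sum(y); nn <- sum(!y)
  t <- ifelse(y, (np + 1) / (np + 2), 1 / (nn + 2))
  s <- as.numeric(scores)
  nll <- function(ab) {
    f <- ab[1] * s + ab[2]
    # log p = -log(1+e^f), log(1-p) = f - log(1+e^f)
    lse <- ifelse(f > 30, f, log1p(exp(f)))
    sum(t * lse - (1 - t) * (f - lse))
  }
  init <- c(A = 0, B = log((nn + 1) / (np + 1)))
  fit <- stats::optim(init, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  out <- fit$par
  names(out) <- c("A", "B")
  out
}

platt_probability <- function(scores, ab) {
  1 / (1 + exp(ab[["A"]] * as.numeric(scores) + ab[["B"]]))
}

#' Predict calibrated activity probabilities
#'
#' @param object a [target_model()].
#' @param x fingerprint matrix with the training width.
#' @param type `"prob"` for the averaged calibrated probability,
#'   `"score"` for the averaged raw classifier score.
#' @param ... unused.
#' @return numeric vector, one value per row of `x`.
#' @export
predict.target_model <- function(object, x, type = c("prob", "score"),
                                 ...) {
  type <- match.arg(type)
  x <- as_fp_matrix(x)
  if (ncol(x) != object$width)
    stop("fingerprint width ", ncol(x), " does not match training width ",
         object$width, call. = FALSE)
  per_member <- vapply(object$members, function(m) {
    s <- classifier_score(m$classifier, x)
    if (type == "score") s else platt_probability(s, m$platt)
  }, numeric(nrow(x)))
  rowMeans(matrix(per_member, nrow = nrow(x)))
}

#' @export
print.target_model <- function(x, ...) {
  hp <- paste(names(x$hyperparams), unlist(x$hyperparams), sep = " = ",
              collapse = ", ")
  cat("Calibrated target-activity model",
      if (!is.null(x$target_accession))
        paste0(" [", x$target_accession, "]"), "\n", sep = "")
  cat("  algorithm : ", x$algorithm, " (", hp, ")\n", sep = "")
  cat(sprintf("  training  : %d actives / %d inactives (%s weighting)\n",
              x$n_active, x$n_inactive,
              if (x$class_weighting) "balanced" else "no"))
  cat("  calibration: 2-fold ensemble Platt scaling\n")
  invisible(x)
}

#' @export
summary.target_model <- function(object, ...) {
  pl <- t(vapply(object$members, function(m) m$platt, numeric(2)))
  out <- list(algorithm = object$algorithm,
              hyperparams = object$hyperparams,
              n_active = object$n_active,
              n_inactive = object$n_inactive,
              platt = data.frame(member = 1:2, A = pl[, 1], B = pl[, 2]))
  class(out) <- "summary.target_model"
  out
}

#' @export
print.summary.target_model <- function(x, ...) {
  cat("target_model:", x$algorithm, "\n")
  cat(sprintf("  %d actives / %d inactives\n", x$n_active, x$n_inactive))
  cat("  Platt calibrators:\n")
  print(x$platt, row.names = FALSE)
  invisible(x)
}

#' The benchmarked algorithm / hyper-parameter grid
#'
#' @return data.frame with `algorithm` and the active hyper-parameter per
#'   row: forests of 5, 50 and 500 trees, naive Bayes with alpha 1.0 and
#'   0.1, and linear SVMs with cost 0.01, 1 and 100.
#' @export
hyperparameter_grid <- function() {
  rbind(
    data.frame(algorithm = "random_forest", trees = c(5, 50, 500),
               alpha = NA, cost = NA),
    data.frame(algorithm = "bernoulli_nb", trees = NA, alpha = c(1, 0.1),
               cost = NA),
    data.frame(algorithm = "linear_svm", trees = NA, alpha = NA,
               cost = c(1e-2, 1, 1e2)))
}

#' Save / load a model bundle
#'
#' A bundle is a directory holding a JSON manifest (target, algorithm,
#' hyper-parameters, training counts, seed, format version) next to the
#' serialized model state.
#'
#' @param model a [target_model()].
#' @param dir bundle directory (created if needed).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(format_version = 1L,
                   target_accession = model$target_accession,
                   algorithm = model$algorithm,
                   hyperparams = model$hyperparams,
                   n_active = model$n_active,
                   n_inactive = model$n_inactive,
                   seed = model$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  readRDS(file.path(dir, "model.rds"))
}
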