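#' Split trials into fitting and testing sets
#'
#' Simple random 4:1 split by default (fit size `floor(fit_fraction * n)`).
#' The test set is marked no-rebalance so imbalance correction can never be
#' applied to it. With rare events a non-stratified split can leave the test
#' set single-class; this is warned about, and downstream metrics that need
#' both classes are flagged rather than computed.
#'
#' @param trials A `labelled_features` set (see [labelled_features()]).
#' @param fit_fraction Fraction of rows used for fitting (default 4/5).
#' @param stratified If `TRUE`, split within each outcome class.
#' @return List with `fit` and `test` (the latter marked no-rebalance).
#' @export
split_trials <- function(trials, fit_fraction = 0.8, stratified = FALSE) {
  n <- nrow(trials)
  if (n < 10L) stop("need at least 10 rows to split")
  if (length(unique(trials$collision)) < 2L)
    stop("both outcome classes must be present")
  n_fit <- floor(fit_fraction * n)
  if (stratified) {
    idx_fit <- integer(0)
    for (cl in unique(trials$collision)) {
      idx <- which(trials$collision == cl)
      idx_fit <- c(idx_fit, sample(idx, round(fit_fraction * length(idx))))
    }
  } else {
    idx_fit <- sample.int(n, n_fit)
  }
  fit <- trials[sort(idx_fit), , drop = FALSE]
  test <- trials[-sort(idx_fit), , drop = FALSE]
  rownames(fit) <- rownames(test) <- NULL
  class(fit) <- class(test) <- class(trials)
  if (length(unique(test$collision)) < 2L)
    warning("test set contains a single outcome class; AUC and calibration undefined")
  list(fit = fit, test = mark_no_rebalance(test))
}

#' Classification accuracy at a risk threshold
#'
#' Proportion of rows whose thresholded prediction matches the outcome; a
#' predicted probability at or above the threshold is classified positive
#' (the boundary counts as high risk). The default threshold .10 reflects
#' the high cost of missing a collision relative to a false alarm.
#'
#' @param probs Predicted probabilities in `[0, 1]`.
#' @param y Binary outcomes.
#' @param threshold Risk threshold.
#' @return Proportion correct in `[0, 1]`.
#' @export
accuracy <- function(probs, y, threshold = 0.10) {
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  mean((probs >= threshold) == (y == 1L))
}

#' K-fold cross-validation prediction error
#'
#' Mean held-out cost over seeded stratified folds, refitting the supplied
#' model in each fold. The default cost is the Brier score (mean squared
#' error of the predicted probability); misclassification at 0.5 is also
#' available.
#'
#' @param X Design matrix.
#' @param y Binary outcomes.
#' @param K Number of folds (default 5); `K = n` gives leave-one-out.
#' @param fitter Function `(X, y) -> collision_fit` (default [fit_glm()]).
#' @param cost `"brier"` or `"misclass"`.
#' @return Mean held-out cost (observation-weighted across folds).
#' @export
kfold_cv_error <- function(X, y, K = 5L, fitter = fit_glm,
                           cost = c("brier", "misclass")) {
  cost <- match.arg(cost)
  n <- length(y)
  if (K > n) stop("K cannot exceed the number of rows")
  for (attempt in 1:10) {
    fold <- if (K == n) seq_len(n) else stratified_folds(y, K)
    ok <- all(vapply(seq_len(K), function(k)
      length(unique(y[fold != k])) == 2L, logical(1)))
    if (ok) break
    if (attempt == 10) stop("could not form folds with both classes in every training part")
  }
  err <- 0
  for (k in seq_len(K)) {
    tr <- fold != k
    fit <- fitter(X[tr, , drop = FALSE], y[tr])
    p <- stats::plogis(drop(X[!tr, , drop = FALSE] %*% fit$coefficients))
    err <- err + if (cost == "brier") sum((p - y[!tr])^2)
                 else sum((p >= 0.5) != (y[!tr] == 1L))
  }
  err / n
}

#' Calibration intercept (calibration-in-the-large)
#'
#' Intercept of a logistic regression of the observed outcomes on the logit
#' of the predicted probabilities entered as a fixed offset (slope fixed at
#' 1). Zero means predictions are well calibrated on average; negative
#' values mean the predicted risks were too high (over-estimation), the
#' signature of models fitted to artificially balanced data.
#'
#' @param probs Predicted probabilities; values at the 0/1 boundary are
#'   clamped to `[1e-12, 1 - 1e-12]` and the clamp count reported.
#' @param y Binary outcomes (both classes required).
#' @param level Confidence level for the Wald interval.
#' @return List with `estimate`, `ci_low`, `ci_high`, `n_clamped`.
#' @export
calibration_intercept <- function(probs, y, level = 0.95) {
  if (length(unique(y)) < 2L)
    stop("calibration requires both outcome classes")
  n_clamped <- sum(probs <= 0 | probs >= 1)
  probs <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  off <- stats::qlogis(probs)
  fit <- stats::glm(y ~ 1, family = stats::binomial(), offset = off)
  est <- unname(stats::coef(fit)[1L])
  se <- sqrt(stats::vcov(fit)[1L, 1L])
  q <- stats::qnorm(1 - (1 - level) / 2)
  list(estimate = est, ci_low = est - q * se, ci_high = est + q * se,
       n_clamped = n_clamped)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen event
#' row receives a higher predicted risk than a randomly chosen non-event
#' row, ties counted 1/2 (computed via midranks).
#'
#' @param probs Predicted risks (any monotone score).
#' @param y Binary outcomes (both classes required).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(probs, y) {
  y <- as.integer(y == 1L)
  n1 <- sum(y); n0 <- length(y) - n1
  if (n1 == 0L || n0 == 0L) stop("AUC requires both outcome classes")
  r <- rank(probs, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' True- and false-positive rates at every distinct threshold, for plotting.
#'
#' @inheritParams roc_auc
#' @return Data frame with `threshold`, `tpr`, `fpr`, from (0,0) to (1,1).
#' @export
roc_points <- function(probs, y) {
  y <- as.integer(y == 1L)
  thr <- c(Inf, sort(unique(probs), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(probs[y == 1L] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(probs[y == 0L] >= t), numeric(1))
  data.frame(threshold = thr, tpr = tpr, fpr = fpr)
}

#' Run the full model-by-regime evaluation experiment
#'
#' One random 4:1 split of the trials; then, for each imbalance-correction
#' regime (uncorrected, SMOTE, under-sampling, over-sampling), the fitting
#' set alone is corrected and each requested model (standard GLM,
#' adaptive LASSO with cross-validated penalty) is fitted on it and scored
#' on the untouched test set: accuracy at the risk threshold, K-fold CV
#' error on the (corrected) fitting set, test-set AUC, and the calibration
#' intercept with its confidence interval. A leakage audit asserts that no
#' test row id ever enters a fitting set. Failures in a single cell are
#' recorded in the report and the run continues.
#'
#' @param trials A trial table with `Ht_z`, `Hs_z`, `Dm_z`, `collision` (and
#'   optionally ids), e.g. the truth table of [generate_dataset()].
#' @param threshold Risk threshold for [accuracy()].
#' @param models Character subset of `c("glm", "alasso")`.
#' @param regimes Character subset of
#'   `c("uncorrected", "smote", "under", "over")`.
#' @param k SMOTE neighbourhood size.
#' @param K Folds for both CV error and penalty tuning.
#' @param cv_cost Cost for [kfold_cv_error()].
#' @param seed Integer seed making the whole run reproducible.
#' @param stratified Passed to [split_trials()].
#' @return An `evaluation_report`: data frame with one row per model x
#'   regime (accuracy, cv_error, auc, calibration intercept and CI, sizes),
#'   with `roc`, `cv_paths` and `config` attributes.
#' @export
run_experiment <- function(trials, threshold = 0.10,
                           models = c("glm", "alasso"),
                           regimes = c("uncorrected", "smote", "under", "over"),
                           k = 5L, K = 5L, cv_cost = "brier", seed = 1L,
                           stratified = FALSE) {
  models <- match.arg(models, c("glm", "alasso"), several.ok = TRUE)
  regimes <- match.arg(regimes, c("uncorrected", "smote", "under", "over"),
                       several.ok = TRUE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  data <- labelled_features(trials)
  parts <- split_trials(data, stratified = stratified)
  X_test <- build_design(parts$test)
  y_test <- parts$test$collision
  test_ids <- parts$test$id
  two_class_test <- length(unique(y_test)) == 2L

  rows <- list(); roc_curves <- list(); cv_paths <- list()
  for (regime in regimes) {
    fit_set <- rebalance(parts$fit, method = regime, k = k)
    if (any(fit_set$id %in% test_ids & !fit_set$synthetic))
      stop("leakage audit failed: test rows present in the fitting set")
    X_fit <- build_design(fit_set)
    y_fit <- fit_set$collision
    for (model in models) {
      cell <- tryCatch({
        if (model == "glm") {
          fit <- fit_glm(X_fit, y_fit)
          fitter <- fit_glm
        } else {
          fit <- fit_alasso_cv(X_fit, y_fit, K = K)
          cv_paths[[paste(model, regime, sep = ".")]] <- attr(fit, "cv")$path
          w <- fit$weights; lam <- fit$lambda
          fitter <- function(X, y) fit_adaptive_lasso(X, y, lam, w)
        }
        p_test <- predict_prob(fit, X_test)
        cal <- if (two_class_test) calibration_intercept(p_test, y_test)
               else list(estimate = NA_real_, ci_low = NA_real_,
                         ci_high = NA_real_, n_clamped = 0L)
        roc_curves[[paste(model, regime, sep = ".")]] <-
          if (two_class_test) roc_points(p_test, y_test) else NULL
        data.frame(model = model, regime = regime,
                   accuracy = accuracy(p_test, y_test, threshold),
                   cv_error = kfold_cv_error(X_fit, y_fit, K = K,
                                             fitter = fitter, cost = cv_cost),
                   auc = if (two_class_test) roc_auc(p_test, y_test) else NA_real_,
                   calib_intercept = cal$estimate,
                   calib_ci_low = cal$ci_low, calib_ci_high = cal$ci_high,
                   lambda = fit$lambda, converged = fit$converged,
                   n_fit = nrow(X_fit), n_test = length(y_test),
                   error = NA_character_, stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(model = model, regime = regime, accuracy = NA_real_,
                   cv_error = NA_real_, auc = NA_real_,
                   calib_intercept = NA_real_, calib_ci_low = NA_real_,
                   calib_ci_high = NA_real_, lambda = NA_real_,
                   converged = FALSE, n_fit = nrow(X_fit),
                   n_test = length(y_test), error = conditionMessage(e),
                   stringsAsFactors = FALSE)
      })
      rows[[paste(model, regime, sep = ".")]] <- cell
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "roc") <- roc_curves
  attr(report, "cv_paths") <- cv_paths
  attr(report, "config") <- list(threshold = threshold, k = k, K = K,
                                 cv_cost = cv_cost, seed = seed,
                                 stratified = stratified,
                                 models = models, regimes = regimes)
  class(report) <- c("evaluation_report", "data.frame")
  report
}
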