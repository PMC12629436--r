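binomial_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Adaptive-LASSO penalty weights from a ridge logistic fit
#'
#' The adaptive LASSO penalises each coefficient in proportion to
#' `1 / |beta_tilde_j|`, where `beta_tilde` is an initial L2-penalised
#' (ridge) logistic estimate: coefficients the ridge fit finds large are
#' shrunk gently, near-zero ones heavily. Magnitudes are floored at 1e-8
#' before inversion so weights stay finite; the intercept gets weight 0
#' (never penalised).
#'
#' @param X Design matrix from [build_design()].
#' @param y Binary outcome vector.
#' @param ridge_penalty Positive L2 penalty on the mean-deviance scale
#'   (objective `deviance/n + ridge_penalty * sum(beta_j^2)` over
#'   non-intercept terms).
#' @return Non-negative weight vector, one per design column (0 for the
#'   intercept).
#' @export
adaptive_weights <- function(X, y, ridge_penalty = 0.01) {
  if (ridge_penalty <= 0) stop("ridge_penalty must be positive")
  n <- length(y)
  pen <- c(0, rep(1, ncol(X) - 1L))          # intercept unpenalised
  beta <- c(stats::qlogis(mean(y)), rep(0, ncol(X) - 1L))
  for (it in 1:100) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    g <- (2 / n) * crossprod(X, p - y) + 2 * ridge_penalty * pen * beta
    H <- (2 / n) * crossprod(X, X * (p * (1 - p))) +
      2 * ridge_penalty * diag(pen)
    step <- solve(H, g)
    beta <- beta - step
    if (max(abs(step)) < 1e-10) break
  }
  w <- ifelse(pen == 0, 0, 1 / pmax(abs(beta), 1e-8))
  stats::setNames(w, colnames(X))
}

#' Fit the adaptive-LASSO penalised logistic model
#'
#' Minimises `deviance(beta)/n + lambda * sum_j w_j |beta_j|` over the
#' non-intercept terms by accelerated proximal-gradient (FISTA)
#' soft-thresholding iterations with adaptive restart. At `lambda = 0` the
#' solution coincides with the maximum-likelihood fit; for large `lambda`
#' every penalised coefficient is exactly 0 and the intercept equals the
#' logit of the event fraction.
#'
#' @param X Design matrix from [build_design()].
#' @param y Binary outcome vector.
#' @param lambda Non-negative penalty strength.
#' @param weights Per-coefficient penalty weights (e.g. from
#'   [adaptive_weights()]); the intercept weight must be 0.
#' @param beta_init Optional warm start.
#' @param max_iter,tol Iteration cap and convergence tolerance on
#'   `max |delta beta|`.
#' @return A `collision_fit` with `lambda` and `weights` recorded and no
#'   covariance (standard errors are not meaningful for penalised
#'   estimates).
#' @export
fit_adaptive_lasso <- function(X, y, lambda, weights, beta_init = NULL,
                               max_iter = 10000L, tol = 1e-10) {
  if (lambda < 0) stop("lambda must be >= 0")
  if (length(weights) != ncol(X) || any(weights < 0))
    stop("weights must be non-negative, one per design column")
  n <- length(y)
  L <- max(eigen(crossprod(X), symmetric = TRUE, only.values = TRUE)$values) /
    (2 * n)
  step <- 1 / L
  thr <- step * lambda * weights
  obj <- function(b) {
    binomial_deviance(y, stats::plogis(drop(X %*% b))) / n +
      lambda * sum(weights * abs(b))
  }
  beta <- if (is.null(beta_init)) c(stats::qlogis(mean(y)), rep(0, ncol(X) - 1L))
          else beta_init
  zeta <- beta
  tk <- 1
  f_prev <- obj(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    p <- stats::plogis(drop(X %*% zeta))
    g <- (2 / n) * drop(crossprod(X, p - y))
    beta_new <- zeta - step * g
    beta_new <- sign(beta_new) * pmax(abs(beta_new) - thr, 0)
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    zeta <- beta_new + (tk - 1) / t_new * (beta_new - beta)
    f_new <- obj(beta_new)
    if (f_new > f_prev) {           # adaptive restart of the momentum
      zeta <- beta_new
      t_new <- 1
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    tk <- t_new
    f_prev <- min(f_prev, f_new)
    if (delta < tol) { converged <- TRUE; break }
  }
  p <- stats::plogis(drop(X %*% beta))
  new_fit(stats::setNames(beta, colnames(X)), vcov = NULL, lambda = lambda,
          weights = weights, converged = converged, n_obs = n,
          loglik = -binomial_deviance(y, p) / 2, fitted = p, y = y)
}

#' Default penalty grid for the adaptive LASSO
#'
#' 100 log-spaced values from `lambda_max` (the smallest penalty at which
#' every penalised coefficient is exactly zero, from the subgradient
#' condition at the intercept-only fit) down to `lambda_max * 1e-4`.
#'
#' @inheritParams fit_adaptive_lasso
#' @param n_lambda Grid length.
#' @param min_ratio Ratio of the smallest to the largest grid value.
#' @return Decreasing numeric vector.
#' @export
lambda_grid <- function(X, y, weights, n_lambda = 100L, min_ratio = 1e-4) {
  n <- length(y)
  p0 <- mean(y)
  g <- (2 / n) * drop(crossprod(X, y - p0))
  j <- weights > 0
  lmax <- max(abs(g[j]) / weights[j])
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

stratified_folds <- function(y, K) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(K), length(idx)))
  }
  fold
}

#' Select the penalty by K-fold cross-validated binomial deviance
#'
#' Stratified K-fold cross-validation over a decreasing penalty grid with
#' warm starts; the grid value minimising the mean held-out binomial
#' deviance (per observation) is chosen. The full deviance path is returned
#' for plotting.
#'
#' @inheritParams fit_adaptive_lasso
#' @param K Number of folds (default 5).
#' @param grid Penalty grid; defaults to [lambda_grid()].
#' @return List with `lambda` (the minimiser), `path` (data frame `lambda`,
#'   `cv_deviance`, `cv_se`) and `K`.
#' @export
tune_lambda <- function(X, y, weights, K = 5L, grid = NULL) {
  if (is.null(grid)) grid <- lambda_grid(X, y, weights)
  if (length(grid) < 1L) stop("penalty grid is empty")
  grid <- sort(grid, decreasing = TRUE)
  for (attempt in 1:10) {
    fold <- stratified_folds(y, K)
    ok <- all(vapply(seq_len(K), function(k)
      length(unique(y[fold != k])) == 2L && sum(fold == k) > 0L, logical(1)))
    if (ok) break
    if (attempt == 10) stop("could not form folds with both classes present")
  }
  dev_fold <- matrix(NA_real_, K, length(grid))
  n_fold <- integer(K)
  for (k in seq_len(K)) {
    tr <- fold != k
    bw <- NULL
    for (g in seq_along(grid)) {
      fit <- fit_adaptive_lasso(X[tr, , drop = FALSE], y[tr], grid[g],
                                weights, beta_init = bw, tol = 1e-8)
      bw <- fit$coefficients
      p_out <- stats::plogis(drop(X[!tr, , drop = FALSE] %*% bw))
      dev_fold[k, g] <- binomial_deviance(y[!tr], p_out) / sum(!tr)
    }
    n_fold[k] <- sum(!tr)
  }
  cv <- colMeans(dev_fold)
  cv_se <- apply(dev_fold, 2L, stats::sd) / sqrt(K)
  best <- which.min(cv)
  list(lambda = grid[best],
       path = data.frame(lambda = grid, cv_deviance = cv, cv_se = cv_se),
       K = K)
}

#' Adaptive LASSO with data-driven penalty
#'
#' Convenience wrapper: ridge-based adaptive weights, K-fold selection of
#' the penalty by binomial deviance, then the final penalised fit on the
#' full data. The cross-validation path is attached as the `cv` attribute.
#'
#' @inheritParams tune_lambda
#' @param ridge_penalty Passed to [adaptive_weights()].
#' @return A `collision_fit`.
#' @export
fit_alasso_cv <- function(X, y, K = 5L, ridge_penalty = 0.01, grid = NULL) {
  w <- adaptive_weights(X, y, ridge_penalty)
  tuned <- tune_lambda(X, y, w, K = K, grid = grid)
  fit <- fit_adaptive_lasso(X, y, tuned$lambda, w)
  attr(fit, "cv") <- tuned
  fit
}
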