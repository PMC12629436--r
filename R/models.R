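design_cols <- c("(Intercept)", "Ht", "Hs", "Dm",
                 "Ht:Hs", "Ht:Dm", "Hs:Dm", "Ht:Hs:Dm")

#' Build the collision-model design matrix
#'
#' Fixed column order: intercept, the three standardised features (gaze
#' transition entropy Ht, stationary gaze entropy Hs, mean pupil diameter
#' Dm), all pairwise interactions, and the three-way interaction. Row ids
#' and cluster (participant) ids travel as attributes; synthetic rows carry
#' singleton cluster ids assigned by the rebalancing step.
#'
#' @param trials A data frame with `Ht_z`, `Hs_z`, `Dm_z` (e.g. a
#'   `labelled_features` set or the truth table of [generate_dataset()]).
#' @return Numeric matrix with 8 named columns and attributes `ids`,
#'   `clusters`.
#' @export
build_design <- function(trials) {
  need <- c("Ht_z", "Hs_z", "Dm_z")
  if (!all(need %in% names(trials)))
    stop("missing standardised features (Ht_z, Hs_z, Dm_z)")
  if (any(is.na(trials[need]))) stop("features contain missing values")
  Ht <- trials$Ht_z; Hs <- trials$Hs_z; Dm <- trials$Dm_z
  X <- cbind(1, Ht, Hs, Dm, Ht * Hs, Ht * Dm, Hs * Dm, Ht * Hs * Dm)
  colnames(X) <- design_cols
  attr(X, "ids") <- if (!is.null(trials$id)) as.character(trials$id)
                    else as.character(seq_len(nrow(X)))
  attr(X, "clusters") <- if (!is.null(trials$cluster)) as.character(trials$cluster)
                         else if (!is.null(trials$participant_id)) as.character(trials$participant_id)
                         else as.character(seq_len(nrow(X)))
  X
}

new_fit <- function(coefficients, vcov = NULL, lambda = 0, weights = NULL,
                    converged = TRUE, separation = FALSE, n_obs, loglik = NA,
                    fitted = NULL, y = NULL) {
  structure(list(coefficients = coefficients, vcov = vcov,
                 vcov_clustered = NULL, lambda = lambda, weights = weights,
                 converged = converged, separation = separation,
                 n_obs = n_obs, loglik = loglik, fitted = fitted, y = y),
            class = "collision_fit")
}

#' @export
print.collision_fit <- function(x, ...) {
  kind <- if (x$lambda > 0) sprintf("adaptive-LASSO (lambda = %.4g)", x$lambda)
          else "maximum-likelihood"
  cat(sprintf("Logistic collision model (%s), n = %d%s\n", kind, x$n_obs,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Fit the logistic collision model by maximum likelihood
#'
#' Iteratively reweighted least squares (via `stats::glm.fit`, binomial
#' family, logit link) with a tight convergence tolerance and at most 100
#' iterations. Perfect or quasi-perfect separation (fitted probabilities at
#' the 0/1 boundary) is detected and flagged as non-convergence rather than
#' passing silently.
#'
#' @param X Design matrix from [build_design()].
#' @param y Binary outcome vector (1 = collision).
#' @return A `collision_fit` with coefficients, conventional covariance
#'   (inverse observed information), log-likelihood and convergence state.
#' @export
fit_glm <- function(X, y) {
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  p <- fit$fitted.values
  separation <- any(p < 1e-10 | p > 1 - 1e-10) ||
    any(abs(fit$coefficients) > 30)
  w <- p * (1 - p)
  info <- crossprod(X, X * w)
  vc <- tryCatch(solve(info), error = function(e) NULL)
  if (!is.null(vc)) dimnames(vc) <- list(colnames(X), colnames(X))
  ll <- sum(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300)))
  beta <- stats::setNames(fit$coefficients, colnames(X))
  out <- new_fit(beta, vcov = vc, lambda = 0,
                 converged = fit$converged && !separation,
                 separation = separation,
                 n_obs = length(y), loglik = ll, fitted = p, y = y)
  if (separation)
    attr(out, "diagnostic") <- "fitted probabilities at the 0/1 boundary: (quasi-)separation suspected"
  out
}

#' Cluster-robust (sandwich) covariance
#'
#' Liang-Zeger sandwich estimator for repeated-measures data: scores
#' `x_i (y_i - p_i)` are summed within clusters (participants), the bread is
#' the inverse observed information, and the small-sample factor
#' `G / (G - 1)` is applied. With every row its own cluster this reduces to
#' the HC0 heteroskedasticity-robust estimator times the factor.
#'
#' @param fit A converged `collision_fit` from [fit_glm()].
#' @param X The design matrix used for the fit.
#' @param clusters Cluster id per row (defaults to the design's `clusters`
#'   attribute); at least 2 distinct clusters.
#' @return Symmetric covariance matrix; also stored in the returned fit by
#'   [with_cluster_vcov()].
#' @export
cluster_robust_vcov <- function(fit, X, clusters = attr(X, "clusters")) {
  if (!fit$converged) stop("model did not converge; covariance unreliable")
  clusters <- as.character(clusters)
  G <- length(unique(clusters))
  if (G < 2L) stop("cluster-robust covariance requires >= 2 clusters")
  p <- fit$fitted
  scores <- X * (fit$y - p)
  meat <- crossprod(rowsum(scores, clusters))
  bread <- fit$vcov
  V <- G / (G - 1) * bread %*% meat %*% bread
  V <- (V + t(V)) / 2
  dimnames(V) <- dimnames(fit$vcov)
  V
}

#' Attach a cluster-robust covariance to a fit
#'
#' @inheritParams cluster_robust_vcov
#' @return The fit with `vcov_clustered` filled in.
#' @export
with_cluster_vcov <- function(fit, X, clusters = attr(X, "clusters")) {
  fit$vcov_clustered <- cluster_robust_vcov(fit, X, clusters)
  fit
}

#' Predicted collision probabilities
#'
#' Inverse-logit of the linear predictor, `plogis(X beta)`.
#'
#' @param fit A `collision_fit`.
#' @param X Design matrix with the same column order as the fit.
#' @return Probability vector in (0, 1).
#' @export
predict_prob <- function(fit, X) {
  if (!identical(colnames(X), names(fit$coefficients)))
    stop("design columns do not match the fitted coefficients")
  stats::plogis(drop(X %*% fit$coefficients))
}

#' Coefficient table with Wald inference
#'
#' Estimates, standard errors, z-values, two-sided p-values and 95% Wald
#' confidence intervals, using the clustered covariance when available
#' (repeated-measures correction), otherwise the conventional one.
#'
#' @param fit A `collision_fit` from [fit_glm()] (penalized fits carry no
#'   covariance and are rejected: standard errors are not meaningful for
#'   LASSO-type estimates).
#' @param level Confidence level.
#' @return Data frame with one row per coefficient.
#' @export
coef_table <- function(fit, level = 0.95) {
  if (fit$lambda > 0)
    stop("no standard errors for penalized fits")
  V <- if (!is.null(fit$vcov_clustered)) fit$vcov_clustered else fit$vcov
  se <- sqrt(diag(V))
  z <- fit$coefficients / se
  q <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(term = names(fit$coefficients), estimate = fit$coefficients,
             se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
             ci_low = fit$coefficients - q * se,
             ci_high = fit$coefficients + q * se,
             row.names = NULL)
}

#' Serialise a fitted model to JSON
#'
#' Writes coefficients, covariance(s), penalty, adaptive weights,
#' convergence metadata and the design column order.
#'
#' @param fit A `collision_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(fit, path) {
  obj <- list(coefficients = as.list(fit$coefficients),
              vcov = fit$vcov, vcov_clustered = fit$vcov_clustered,
              lambda = fit$lambda, adaptive_weights = fit$weights,
              converged = fit$converged, separation = fit$separation,
              n_obs = fit$n_obs, loglik = fit$loglik,
              columns = names(fit$coefficients),
              software = paste0("gazerisk ", utils::packageVersion("gazerisk")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
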