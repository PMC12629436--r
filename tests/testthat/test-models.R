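sim_truth <- function(..., seed = 1) {
  generate_dataset(sim_config(..., seed = seed), raw = FALSE)$truth
}

test_that("the design matrix has the fixed 8-column interaction structure", {
  d <- data.frame(Ht_z = 1, Hs_z = 2, Dm_z = 3)
  X <- build_design(d)
  expect_equal(colnames(X), c("(Intercept)", "Ht", "Hs", "Dm", "Ht:Hs",
                              "Ht:Dm", "Hs:Dm", "Ht:Hs:Dm"))
  expect_equal(unname(X[1, ]), c(1, 1, 2, 3, 2, 3, 6, 6))
  X0 <- build_design(data.frame(Ht_z = 0, Hs_z = 0, Dm_z = 0))
  expect_equal(unname(X0[1, ]), c(1, 0, 0, 0, 0, 0, 0, 0))
  expect_error(build_design(data.frame(Ht_z = 1, Hs_z = 2)), "missing")
  # interaction columns are elementwise products of the main effects
  d2 <- sim_truth(n_participants = 5)
  X2 <- build_design(d2)
  expect_equal(X2[, "Ht:Hs:Dm"], X2[, "Ht"] * X2[, "Hs"] * X2[, "Dm"])
})

test_that("maximum-likelihood fit matches closed forms and stats::glm", {
  # intercept-only on 29 events / 265 non-events: logit of the prevalence
  y <- rep(c(1L, 0L), c(29, 265))
  f <- fit_glm(matrix(1, 294, 1, dimnames = list(NULL, "(Intercept)")), y)
  expect_equal(unname(f$coefficients), log(29 / 265), tolerance = 1e-8)
  # full model agrees with stats::glm on coefficients and covariance
  d <- sim_truth(seed = 14)
  X <- build_design(d)
  f2 <- fit_glm(X, d$collision)
  ref <- glm(d$collision ~ X[, -1], family = binomial())
  expect_equal(unname(f2$coefficients), unname(coef(ref)), tolerance = 1e-7)
  expect_equal(unname(sqrt(diag(f2$vcov))),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  expect_true(f2$converged)
  expect_error(fit_glm(X, rep(0L, nrow(X))), "both outcome classes")
})

test_that("independent outcomes leave non-intercept coefficients near zero", {
  set.seed(31)
  d <- sim_truth(n_participants = 500, cluster_sd = 0, seed = 31)
  y <- rbinom(nrow(d), 1, 0.1)           # independent of the features
  f <- fit_glm(build_design(d), y)
  tab <- coef_table(f)
  expect_true(all(abs(tab$z[-1]) < 3))
})

test_that("perfect separation is flagged, never silent", {
  set.seed(12)
  d <- data.frame(Ht_z = c(-2, -1, -0.5, 0.5, 1, 2),
                  Hs_z = rnorm(6), Dm_z = rnorm(6))
  y <- c(0L, 0L, 0L, 1L, 1L, 1L)
  f <- fit_glm(build_design(d), y)
  expect_false(f$converged)
  expect_true(f$separation)
  expect_match(attr(f, "diagnostic"), "separation")
})

test_that("adaptive weights invert the ridge magnitudes with a floor", {
  d <- sim_truth(seed = 8)
  X <- build_design(d)
  w <- adaptive_weights(X, d$collision)
  expect_equal(unname(w[1]), 0)                 # intercept unpenalised
  expect_true(all(w[-1] > 0) && all(is.finite(w)))
  # sign invariance: flipping a feature flips the ridge estimate, not the weight
  d2 <- d; d2$Dm_z <- -d2$Dm_z
  w2 <- adaptive_weights(build_design(d2), d2$collision)
  expect_equal(unname(w2["Dm"]), unname(w["Dm"]), tolerance = 1e-6)
  # a feature with a near-zero ridge coefficient gets the floored weight
  set.seed(40)
  n <- 4000
  dn <- data.frame(Ht_z = rnorm(n), Hs_z = rnorm(n), Dm_z = rnorm(n))
  yn <- rbinom(n, 1, 0.3)
  wn <- adaptive_weights(build_design(dn), yn, ridge_penalty = 10)
  expect_true(any(wn[-1] > 1e3))                # heavy shrinkage, tiny betas
  expect_true(all(wn[-1] <= 1e8 + 1e-6))        # floor bounds the weight
  expect_error(adaptive_weights(X, d$collision, ridge_penalty = 0),
               "positive")
})

test_that("the penalised fit reproduces the MLE at lambda 0 and collapses at large lambda", {
  d <- sim_truth(seed = 16)
  X <- build_design(d); y <- d$collision
  w <- adaptive_weights(X, y)
  f0 <- fit_adaptive_lasso(X, y, 0, w)
  fg <- fit_glm(X, y)
  expect_lt(max(abs(f0$coefficients - fg$coefficients)), 1e-4)
  fb <- fit_adaptive_lasso(X, y, 1e6, w)
  expect_equal(unname(fb$coefficients[-1]), rep(0, 7))
  expect_equal(unname(fb$coefficients[1]), qlogis(mean(y)), tolerance = 1e-8)
  expect_error(fit_adaptive_lasso(X, y, -1, w), ">= 0")
})

test_that("the proximal-gradient solution matches the glmnet coordinate-descent oracle", {
  skip_if_not_installed("glmnet")
  d <- sim_truth(seed = 3)
  X <- build_design(d); y <- d$collision
  w <- adaptive_weights(X, y)
  p <- ncol(X) - 1L
  for (lam in c(0.002, 0.02, 0.1)) {
    mine <- fit_adaptive_lasso(X, y, lam, w)
    # objective deviance/n + lam * sum(w |b|) equals glmnet's -loglik/n +
    # lam_g * sum(pf_scaled |b|) with pf rescaled to sum to nvars
    lam_g <- lam / 2 * sum(w[-1]) / p
    gn <- glmnet::glmnet(X[, -1], y, family = "binomial", alpha = 1,
                         penalty.factor = w[-1], standardize = FALSE,
                         lambda = c(lam_g * 4, lam_g), thresh = 1e-14,
                         maxit = 1e6)
    oracle <- c(gn$a0[2], as.numeric(gn$beta[, 2]))
    expect_lt(max(abs(unname(mine$coefficients) - oracle)), 1e-6)
  }
  # one-dimensional toy with a hand-checkable soft-threshold structure
  set.seed(50)
  x1 <- rnorm(400)
  y1 <- rbinom(400, 1, plogis(-1 + x1))
  X1 <- cbind("(Intercept)" = 1, Ht = x1)
  m1 <- fit_adaptive_lasso(X1, y1, 0.05, c(0, 1))
  g1 <- glmnet::glmnet(cbind(x1, 0), y1, family = "binomial",
                       penalty.factor = c(1, 1), standardize = FALSE,
                       lambda = c(0.1, 0.025), thresh = 1e-14, maxit = 1e6)
  expect_lt(abs(unname(m1$coefficients["Ht"]) - g1$beta[1, 2]), 1e-6)
})

test_that("coefficient magnitudes shrink monotonically in lambda on an orthogonal design", {
  set.seed(60)
  n <- 512
  # orthogonal +-1 contrasts
  a <- rep(c(-1, 1), each = n / 2)
  b <- rep(rep(c(-1, 1), each = n / 4), 2)
  cc <- rep(c(-1, 1), n / 2)
  d <- data.frame(Ht_z = a, Hs_z = b, Dm_z = cc)
  X <- build_design(d)[, 1:4]
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * a - 0.4 * b + 0.2 * cc))
  w <- c(0, 1, 1, 1)
  lams <- seq(0, 0.3, length.out = 13)
  path <- t(sapply(lams, function(l)
    abs(fit_adaptive_lasso(X, y, l, w)$coefficients[-1])))
  expect_true(all(diff(path) <= 1e-6))
})

test_that("cross-validated penalty selection behaves at the grid edges", {
  d <- sim_truth(seed = 22)
  X <- build_design(d); y <- d$collision
  w <- adaptive_weights(X, y)
  set.seed(1)
  single <- tune_lambda(X, y, w, K = 5, grid = 0.05)
  expect_equal(single$lambda, 0.05)
  # pure noise: full shrinkage preferred in most replicates
  set.seed(70)
  top <- replicate(20, {
    n <- 200
    dn <- data.frame(Ht_z = rnorm(n), Hs_z = rnorm(n), Dm_z = rnorm(n))
    Xn <- build_design(dn)
    yn <- rbinom(n, 1, 0.25)
    wn <- adaptive_weights(Xn, yn)
    g <- lambda_grid(Xn, yn, wn, n_lambda = 40)
    tune_lambda(Xn, yn, wn, K = 5, grid = g)$lambda >= g[8]  # top 20% of grid
  })
  expect_gt(mean(top), 0.5)
  # strong signal at large n: the chosen penalty sits strictly inside the grid
  set.seed(71)
  ds <- sim_truth(n_participants = 250, cluster_sd = 0, seed = 71)
  Xs <- build_design(ds); ys <- ds$collision
  ws <- adaptive_weights(Xs, ys)
  gs <- lambda_grid(Xs, ys, ws)
  ts <- tune_lambda(Xs, ys, ws, K = 5, grid = gs)
  expect_lt(ts$lambda, max(gs))
  expect_equal(nrow(ts$path), 100)
})

test_that("cluster-robust covariance reduces to HC0 under singleton clusters", {
  d <- sim_truth(seed = 19)
  X <- build_design(d); y <- d$collision
  f <- fit_glm(X, y)
  n <- nrow(X)
  V1 <- cluster_robust_vcov(f, X, clusters = seq_len(n))
  p <- f$fitted
  meat_hc0 <- crossprod(X * (y - p))
  V_hc0 <- f$vcov %*% meat_hc0 %*% f$vcov
  expect_equal(V1, n / (n - 1) * V_hc0, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(cluster_robust_vcov(f, X, clusters = rep(1, n)), ">= 2")
})

test_that("cluster-robust covariance matches the sandwich package", {
  skip_if_not_installed("sandwich")
  d <- sim_truth(seed = 23)
  X <- build_design(d); y <- d$collision
  f <- fit_glm(X, y)
  V <- cluster_robust_vcov(f, X, clusters = d$participant_id)
  ref <- glm(y ~ X[, -1], family = binomial(),
             control = glm.control(epsilon = 1e-12))
  Vref <- sandwich::vcovCL(ref, cluster = d$participant_id, type = "HC0",
                           cadjust = TRUE)
  expect_equal(unname(V), unname(Vref), tolerance = 1e-4)
})

test_that("duplicating every row leaves clustered SEs stable but shrinks conventional ones", {
  d <- sim_truth(seed = 27)
  X <- build_design(d); y <- d$collision
  cl <- d$participant_id
  f1 <- fit_glm(X, y)
  X2 <- rbind(X, X); y2 <- c(y, y); cl2 <- c(cl, cl)
  f2 <- fit_glm(X2, y2)
  expect_equal(sqrt(diag(f2$vcov)), sqrt(diag(f1$vcov)) / sqrt(2),
               tolerance = 1e-6)
  V1 <- cluster_robust_vcov(f1, X, cl)
  V2 <- cluster_robust_vcov(f2, X2, cl2)
  expect_equal(sqrt(diag(V2)), sqrt(diag(V1)), tolerance = 1e-6)
})

test_that("clustered and conventional SEs agree when there is no clustering", {
  d <- sim_truth(n_participants = 600, cluster_sd = 0, seed = 44)
  X <- build_design(d); y <- d$collision
  f <- fit_glm(X, y)
  V <- cluster_robust_vcov(f, X, clusters = d$participant_id)
  ratio <- sqrt(diag(V)) / sqrt(diag(f$vcov))
  expect_true(all(abs(ratio - 1) < 0.15))
})

test_that("predicted probabilities follow the inverse logit", {
  X <- build_design(data.frame(Ht_z = 0, Hs_z = 0, Dm_z = 0))
  f <- gazerisk:::new_fit(setNames(default_beta(), colnames(X)), n_obs = 1)
  expect_equal(predict_prob(f, X), plogis(-2.664), tolerance = 1e-12)
  f0 <- gazerisk:::new_fit(setNames(rep(0, 8), colnames(X)), n_obs = 1)
  d <- data.frame(Ht_z = rnorm(5), Hs_z = rnorm(5), Dm_z = rnorm(5))
  expect_equal(predict_prob(f0, build_design(d)), rep(0.5, 5))
  # monotone in Ht when only the Ht coefficient is positive
  dh <- data.frame(Ht_z = seq(-2, 2, 0.5), Hs_z = 0, Dm_z = 0)
  fh <- gazerisk:::new_fit(setNames(c(-1, 1, rep(0, 6)), colnames(X)),
                           n_obs = 1)
  expect_true(all(diff(predict_prob(fh, build_design(dh))) > 0))
})

test_that("penalised fits refuse Wald inference and serialise to JSON", {
  d <- sim_truth(seed = 2)
  X <- build_design(d); y <- d$collision
  w <- adaptive_weights(X, y)
  fa <- fit_adaptive_lasso(X, y, 0.05, w)
  expect_error(coef_table(fa), "penalized")
  path <- tempfile(fileext = ".json")
  write_model_json(fa, path)
  obj <- jsonlite::read_json(path)
  expect_equal(obj$lambda, 0.05)
  expect_equal(unlist(obj$columns), colnames(X))
  fg <- with_cluster_vcov(fit_glm(X, y), X, d$participant_id)
  expect_equal(dim(fg$vcov_clustered), c(8, 8))
})
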