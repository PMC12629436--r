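sim_truth2 <- function(..., seed = 1) {
  generate_dataset(sim_config(..., seed = seed), raw = FALSE)$truth
}

test_that("the 4:1 split sizes, marking and reproducibility are correct", {
  data <- labelled_features(data.frame(
    Ht_z = rnorm(294), Hs_z = rnorm(294), Dm_z = rnorm(294),
    collision = rep(c(1L, 0L), c(29, 265))))
  set.seed(1)
  parts <- split_trials(data)
  expect_equal(nrow(parts$fit), 235)      # floor(0.8 * 294)
  expect_equal(nrow(parts$test), 59)
  expect_true(isTRUE(attr(parts$test, "no_rebalance")))
  expect_setequal(c(parts$fit$id, parts$test$id), data$id)
  expect_length(intersect(parts$fit$id, parts$test$id), 0)
  set.seed(1); a <- split_trials(data)
  set.seed(1); b <- split_trials(data)
  expect_identical(a, b)
  small <- labelled_features(data.frame(
    Ht_z = rnorm(10), Hs_z = rnorm(10), Dm_z = rnorm(10),
    collision = rep(c(1L, 0L), 5)))
  set.seed(2)
  ps <- split_trials(small)
  expect_equal(nrow(ps$fit), 8)
  expect_equal(nrow(ps$test), 2)
  expect_error(split_trials(small[1:5, ]), "at least 10")
})

test_that("a stratified split preserves the class balance in both parts", {
  data <- labelled_features(data.frame(
    Ht_z = rnorm(294), Hs_z = rnorm(294), Dm_z = rnorm(294),
    collision = rep(c(1L, 0L), c(29, 265))))
  set.seed(3)
  parts <- split_trials(data, stratified = TRUE)
  expect_equal(sum(parts$test$collision), 6)   # round(0.2 * 29)
  expect_equal(sum(parts$fit$collision), 23)
})

test_that("accuracy classifies the threshold boundary as positive", {
  expect_equal(accuracy(c(0.2, 0.05), c(1, 0)), 1)
  expect_equal(accuracy(c(0.2, 0.05), c(0, 1)), 0)
  expect_equal(accuracy(rep(0.10, 5), rep(1, 5)), 1)
  expect_error(accuracy(c(1.2, 0.5), c(1, 0)), "\\[0, 1\\]")
})

test_that("cross-validation error matches its closed forms and the LOO oracle", {
  # a perfect predictor has zero cost under either loss
  set.seed(4)
  y <- rep(c(0L, 1L), each = 15)
  Xp <- cbind("(Intercept)" = 1, sig = (2 * y - 1) * 30)
  perfect <- function(X, y) list(coefficients = c(0, 1))
  expect_lt(kfold_cv_error(Xp, y, K = 5, fitter = perfect), 1e-8)
  expect_equal(kfold_cv_error(Xp, y, K = 5, fitter = perfect,
                              cost = "misclass"), 0)
  # constant forecast at the event rate: Brier ~ q(1 - q)
  set.seed(5)
  n <- 4000; q <- 0.1
  yc <- rbinom(n, 1, q)
  Xc <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  qhat <- mean(yc)
  expect_lt(abs(kfold_cv_error(Xc, yc, K = 5) - qhat * (1 - qhat)), 0.005)
  # leave-one-out equals the brute-force oracle on 10 rows
  set.seed(6)
  d10 <- data.frame(Ht_z = rnorm(10), Hs_z = rnorm(10), Dm_z = rnorm(10))
  y10 <- rep(c(0L, 1L), c(6, 4))
  X10 <- build_design(d10)[, 1:2]
  expect_equal(kfold_cv_error(X10, y10, K = 10), brute_loo_brier(X10, y10),
               tolerance = 1e-8)
  expect_error(kfold_cv_error(X10, y10, K = 11), "cannot exceed")
})

test_that("the calibration intercept recovers known logit shifts", {
  set.seed(7)
  n <- 10000
  p_true <- plogis(rnorm(n, -2, 1))
  y <- rbinom(n, 1, p_true)
  well <- calibration_intercept(p_true, y)
  expect_true(well$ci_low < 0 && 0 < well$ci_high)
  over <- calibration_intercept(plogis(qlogis(p_true) + 2), y)
  expect_lt(abs(over$estimate - (-2)), 0.1)
  under <- calibration_intercept(plogis(qlogis(p_true) - 1), y)
  expect_lt(abs(under$estimate - 1), 0.1)
  expect_error(calibration_intercept(p_true, rep(1, n)), "both outcome")
  clamped <- calibration_intercept(c(0, 1, p_true), c(0, 1, y))
  expect_equal(clamped$n_clamped, 2L)
})

test_that("AUC equals the Mann-Whitney pair count, with ties at one half", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3), c(1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.9, 0.1, 0.8), c(0, 1, 0)), 0)
  expect_equal(roc_auc(rep(0.4, 6), rep(c(0, 1), 3)), 0.5)
  set.seed(8)
  for (rep in 1:25) {
    n <- sample(4:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    p <- round(runif(n), 1)              # coarse grid forces ties
    expect_equal(roc_auc(p, y), brute_auc(p, y))
  }
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both outcome")
})

test_that("AUC agrees with pROC on continuous scores", {
  skip_if_not_installed("pROC")
  set.seed(9)
  y <- rbinom(100, 1, 0.3)
  p <- plogis(rnorm(100) + y)
  expect_equal(roc_auc(p, y),
               as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                              direction = "<"))))
})

test_that("ROC points run from (0,0) to (1,1) and reproduce the AUC by trapezoid", {
  set.seed(10)
  y <- rbinom(60, 1, 0.3)
  p <- runif(60)
  pts <- roc_points(p, y)
  expect_equal(c(pts$fpr[1], pts$tpr[1]), c(0, 0))
  expect_equal(c(pts$fpr[nrow(pts)], pts$tpr[nrow(pts)]), c(1, 1))
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  trap <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  expect_equal(trap, roc_auc(p, y), tolerance = 1e-10)
})

test_that("the experiment grid is complete, leak-free and byte-reproducible", {
  d <- sim_truth2(seed = 90)
  r1 <- run_experiment(d, seed = 5)
  expect_s3_class(r1, "evaluation_report")
  expect_equal(nrow(r1), 8)              # 2 models x 4 regimes
  expect_setequal(unique(r1$model), c("glm", "alasso"))
  expect_setequal(unique(r1$regime), c("uncorrected", "smote", "under", "over"))
  expect_true(all(is.na(r1$error)))
  expect_true(all(r1$accuracy >= 0 & r1$accuracy <= 1, na.rm = TRUE))
  expect_true(all(r1$auc >= 0 & r1$auc <= 1, na.rm = TRUE))
  expect_true(all(r1$lambda[r1$model == "alasso"] > 0))
  # penalty paths and ROC curves exported for every adaptive-LASSO cell
  expect_length(attr(r1, "cv_paths"), 4)
  expect_length(attr(r1, "roc"), 8)
  r2 <- run_experiment(d, seed = 5)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
})

test_that("rebalancing never touches the test rows", {
  d <- sim_truth2(seed = 91)
  data <- labelled_features(d)
  set.seed(17)
  parts <- split_trials(data)
  for (m in c("smote", "under", "over")) {
    set.seed(18)
    fit_set <- rebalance(parts$fit, m)
    expect_length(intersect(fit_set$id[!fit_set$synthetic], parts$test$id), 0)
    expect_error(rebalance(parts$test, m), "no-rebalance")
  }
})
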