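# shared synthetic regression design: 2 informative of 500 columns
make_lasso_sim <- function(n = 200, p = 500, seed = 42) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("i%03d", 1:n), sprintf("f%03d", 1:p)))
  # lifespans around 18 d driven by two informative features
  y <- 18 + 3 * x[, 1] - 2 * x[, 2] + rnorm(n, 0, 0.5)
  list(x = x, y = y)
}

test_that("feature building follows the column grammar and survival bounds", {
  t <- seq(0, 29.5, by = 0.5)
  mk <- function(id, metric, label, v)
    data.frame(individual_id = id, metric = metric, time_days = t,
               value = v, clip_label = label)
  metrics <- c("raw_movement", "centroid_speed", "body_amplitude",
               "swim_frequency")
  traces <- do.call(rbind, lapply(c("w1", "w2"), function(id)
    do.call(rbind, lapply(metrics, function(m)
      do.call(rbind, lapply(c("constant", "pulsed"), function(l)
        mk(id, m, l, pmax(1 - t / 30, 0))))))))
  rec <- data.frame(individual_id = c("w1", "w2"),
                    death_time_days = c(29.9, 12.2), censored = FALSE)
  fm <- build_features(traces, rec, day_grid = 0:29)
  # 4 metrics x 2 labels x 30 days x 2 stats + 8 slopes = 488 columns
  expect_equal(ncol(fm$x), 4 * 2 * 30 * 2 + 8)
  expect_true(all(grepl("^[a-z_]+\\.(max|mean|slope)(\\.day\\d{2})?\\.",
                        colnames(fm$x))))
  # features beyond an individual's death are missing, not zero
  expect_true(is.na(fm$x["w2", "raw_movement.mean.day20.constant"]))
  expect_false(is.na(fm$x["w1", "raw_movement.mean.day20.constant"]))
  # constant trace: daily max equals daily mean
  flat <- mk("w3", "raw_movement", "constant", 0.7)
  rec3 <- data.frame(individual_id = "w3", death_time_days = 29.9,
                     censored = FALSE)
  fm3 <- build_features(flat, rec3, day_grid = 0:29)
  mx <- fm3$x[1, grepl("\\.max\\.", colnames(fm3$x))]
  mn <- fm3$x[1, grepl("\\.mean\\.", colnames(fm3$x))]
  expect_equal(unname(mx), unname(mn))
  # decline slope of an exact line a*t + b recovers a
  lin <- mk("w4", "raw_movement", "constant", 2 - 0.05 * t)
  rec4 <- data.frame(individual_id = "w4", death_time_days = 29.9,
                     censored = FALSE)
  fm4 <- build_features(lin, rec4, day_grid = 0:29,
                        early_window = c(1, 10))
  expect_equal(unname(fm4$x[1, "raw_movement.slope.constant"]), -0.05,
               tolerance = 1e-10)
})

test_that("sparse columns are censored and the rest median-imputed, idempotently", {
  x <- cbind(a = c(1, NA, 3, 4, 5), b = c(NA, NA, NA, 4, 5),
             c = c(1, NA, 3, NA, 10))
  fm <- structure(list(x = x, lifespans = 1:5, imputation_medians = NULL),
                  class = "feature_matrix")
  out <- censor_and_impute(fm, sparsity_threshold = 0.5)
  expect_false("b" %in% colnames(out$x))    # 60% missing -> removed
  expect_equal(unname(out$x[2, "a"]), median(c(1, 3, 4, 5)))
  expect_equal(unname(out$x[c(2, 4), "c"]), rep(median(c(1, 3, 10)), 2))
  # column {1, missing, 3}: missing -> 2
  fm2 <- structure(list(x = cbind(z = c(1, NA, 3)), lifespans = 1:3,
                        imputation_medians = NULL), class = "feature_matrix")
  expect_equal(unname(censor_and_impute(fm2)$x[2, "z"]), 2)
  # idempotence
  out2 <- censor_and_impute(out, sparsity_threshold = 0.5)
  expect_equal(out2$x, out$x)
  fm3 <- structure(list(x = cbind(q = c(NA, NA, 1)), lifespans = 1:3,
                        imputation_medians = NULL), class = "feature_matrix")
  expect_error(censor_and_impute(fm3, 0.5), "all feature columns")
})

test_that("LASSO recovers the true support with high out-of-fold R2", {
  sim <- make_lasso_sim()
  fit <- fit_lasso_cv(sim$x, sim$y, n_folds = 10, seed = 5)
  expect_true(all(c("f001", "f002") %in% fit$selected))
  expect_lte(length(setdiff(fit$selected, c("f001", "f002"))), 5)
  expect_gt(fit$coefficients["f001"], 0)
  expect_lt(fit$coefficients["f002"], 0)
  expect_gte(fit$oof_r2, 0.8)
  # deterministic given the seed
  fit2 <- fit_lasso_cv(sim$x, sim$y, n_folds = 10, seed = 5)
  expect_identical(fit$oof_predictions, fit2$oof_predictions)
  expect_identical(fit$coefficients, fit2$coefficients)
})

test_that("the penalty path is monotone in sparsity and ends intercept-only", {
  sim <- make_lasso_sim(n = 100, p = 50)
  fit <- fit_lasso_cv(sim$x, sim$y, seed = 3)
  path <- fit$cv[order(fit$cv$lambda, decreasing = TRUE), ]
  expect_true(all(diff(path$nzero) >= 0))
  # at the top of the path (penalty -> infinity) nothing is selected
  expect_equal(path$nzero[1], 0)
  big <- coef(fit$glmnet_cv, s = max(fit$cv$lambda) * 10)
  expect_true(all(as.numeric(big)[-1] == 0))
})

test_that("standardization makes fits invariant to feature rescaling", {
  sim <- make_lasso_sim(n = 120, p = 40)
  fit1 <- fit_lasso_cv(sim$x, sim$y, seed = 7)
  x2 <- sim$x
  x2[, 1] <- x2[, 1] * 1000
  x2[, 2] <- x2[, 2] / 50 + 3
  fit2 <- fit_lasso_cv(x2, sim$y, seed = 7)
  expect_equal(fit1$oof_predictions, fit2$oof_predictions, tolerance = 1e-4)
  # coefficient on a column scaled by 1000 shrinks by 1000
  expect_equal(fit1$coefficients["f001"],
               fit2$coefficients["f001"] * 1000, tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("transfer residuals detect systematic lifespan shifts", {
  sim <- make_lasso_sim()
  fit <- fit_lasso_cv(sim$x, sim$y, seed = 5)
  # B = A: median residual near zero, no significant sign bias
  same <- transfer_residuals(fit, sim$x, sim$y, alternative = "two.sided")
  expect_lt(abs(same$median_residual), 0.2)
  expect_gt(same$p_value, 0.01)
  # lifespans uniformly shortened by 30% (same behavior): overestimation
  short <- transfer_residuals(fit, sim$x, 0.7 * sim$y,
                              alternative = "greater")
  expect_gt(short$median_residual, 0)
  expect_lt(short$p_value, 0.01)
  # lengthened lifespans: mirror image
  long <- transfer_residuals(fit, sim$x, 1.3 * sim$y,
                             alternative = "less")
  expect_lt(long$median_residual, 0)
  expect_lt(long$p_value, 0.01)
  # schema alignment: a matrix with extra/missing columns still predicts
  xb <- sim$x[, 1:300]
  colnames(xb) <- colnames(sim$x)[1:300]
  pred <- predict(fit, xb)
  expect_equal(length(pred), nrow(xb))
  expect_error(predict(fit, matrix(1, 2, 2)), "named feature columns")
})
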