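# Validation metrics and the NDVI-benchmark comparison arithmetic.

metrics <- function(r2, rmse, n = 20) {
  structure(list(r2 = r2, p_value = 0.01, rmse = rmse, n = n, slope = 1,
                 intercept_ov = 0, constant_predictions = FALSE),
            class = "validation_metrics")
}

test_that("pearson_r2 matches hand-computed values", {
  x <- 1:10
  pr <- pearson_r2(x, 2 * x + 1)
  expect_equal(pr$r2, 1)
  expect_lte(pr$p_value, 1e-15) # floored, never zero
  expect_gt(pr$p_value, 0)
  expect_equal(pearson_r2(c(1, 2, 3), c(1, 3, 2))$r2, 0.25)
  expect_error(pearson_r2(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_r2(1:2, 1:2), "at least 3")
  expect_error(pearson_r2(1:3, 1:4), "equal length")
})

test_that("the correlation test p-value is uniform under the null", {
  set.seed(101)
  frac <- mean(replicate(500, {
    pearson_r2(rnorm(1000), rnorm(1000))$p_value < 0.05
  }))
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("evaluate_model reports r2, rmse and the observed-on-predicted line", {
  tt <- tiny_table(6)
  # a model that predicts gy exactly from ndvi (gy is affine in ndvi here);
  # the perfect fit may warn that its BIC is undefined
  m <- suppressWarnings(
    fit_ridge(as.matrix(as.data.frame(tt)[, "ndvi", drop = FALSE]),
              tt$gy, lambda = 0, combo = "ndvi"))
  v <- evaluate_model(m, tt)
  expect_equal(v$r2, 1, tolerance = 1e-10)
  expect_equal(v$rmse, 0, tolerance = 1e-7)
  expect_equal(v$slope, 1, tolerance = 1e-7)
  expect_equal(v$n, 6)
})

test_that("rmse and r2 behave correctly under offsets and hand examples", {
  # uniform offset: obs = (2,4,6), pred = (3,5,7)
  expect_equal(sqrt(mean((c(2, 4, 6) - c(3, 5, 7))^2)), 1)
  expect_equal(pearson_r2(c(2, 4, 6), c(3, 5, 7))$r2, 1)
  # hand example: obs = (1,2,4), pred = (1,3,3)
  obs <- c(1, 2, 4); pred <- c(1, 3, 3)
  expect_equal(sqrt(mean((obs - pred)^2)), sqrt(2 / 3))
  expect_equal(pearson_r2(obs, pred)$r2, 4 / 7, tolerance = 1e-10)
})

test_that("r2 is affine-invariant in the predictions while rmse is not", {
  set.seed(5)
  obs <- rnorm(30, 8, 2)
  pred <- obs + rnorm(30, 0, 1)
  r2_raw <- pearson_r2(obs, pred)$r2
  expect_equal(pearson_r2(obs, 3 * pred - 2)$r2, r2_raw, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(sqrt(mean((obs - pred)^2)),
                                sqrt(mean((obs - (3 * pred - 2))^2)))))
  # rmse = 0 iff elementwise equality
  expect_identical(sqrt(mean((obs - obs)^2)), 0)
  expect_gt(sqrt(mean((obs - pred)^2)), 0)
})

test_that("constant predictions are flagged, with rmse still reported", {
  tt <- tiny_table(6)
  m <- fit_ridge(as.matrix(as.data.frame(tt)[, "ndvi", drop = FALSE]),
                 tt$gy, lambda = 1e12, combo = "ndvi")
  v <- evaluate_model(m, tt)
  expect_true(v$constant_predictions)
  expect_true(is.na(v$r2))
  expect_gt(v$rmse, 0)
})

test_that("comparison deltas follow the relative reporting convention", {
  rep0 <- compare_metrics(metrics(0.5, 1.0), metrics(0.5, 1.0))
  expect_equal(rep0$delta_r2_relative, 0)
  expect_equal(rep0$delta_rmse_relative, 0)
  rep1 <- compare_metrics(metrics(0.60, 0.9), metrics(0.40, 1.0))
  expect_equal(rep1$delta_r2_relative, 50)
  expect_equal(rep1$delta_rmse_relative, -10)
  # zero benchmark r2: relative delta undefined, absolute fallback engaged
  rep2 <- compare_metrics(metrics(0.30, 0.9), metrics(0, 1.0))
  expect_true(is.na(rep2$delta_r2_relative))
  expect_equal(rep2$delta_r2_absolute, 0.30)
  expect_equal(rep2$delta_rmse_relative, -10)
})

test_that("compare_to_benchmark requires an NDVI-only benchmark", {
  tt <- signal_table(6)
  df <- as.data.frame(tt)
  best <- fit_ridge(as.matrix(df[, c("ndvi", "dh")]), df$gy, 1,
                    combo = c("ndvi", "dh"))
  bench <- fit_ridge(as.matrix(df[, "ndvi", drop = FALSE]), df$gy, 1,
                     combo = "ndvi")
  rep <- compare_to_benchmark(best, bench, tt)
  expect_s3_class(rep, "comparison_report")
  expect_gte(rep$best_model_metrics$r2, rep$benchmark_metrics$r2 - 1e-6)
  not_ndvi <- fit_ridge(as.matrix(df[, "ph", drop = FALSE]), df$gy, 1,
                        combo = "ph")
  expect_error(compare_to_benchmark(best, not_ndvi, tt), "NDVI-only")
})

test_that("an unpenalized fit attains the best training r2 among linear models", {
  set.seed(9)
  tt <- signal_table(7)
  df <- as.data.frame(tt)[1:60, ]
  x <- as.matrix(df[, c("ndvi", "dh")])
  m <- fit_ridge(x, df$gy, lambda = 0, combo = c("ndvi", "dh"))
  r2_ols <- pearson_r2(df$gy, predict(m, x))$r2
  for (i in 1:10) {
    beta <- m$coefficients + rnorm(2, 0, 0.5 * abs(m$coefficients) + 0.01)
    pred <- drop(x %*% beta) + m$intercept
    expect_gte(r2_ols + 1e-10, pearson_r2(df$gy, pred)$r2)
  }
})

test_that("observed-vs-predicted pairs are exported for plotting", {
  tt <- signal_table(8)
  df <- as.data.frame(tt)
  m <- fit_ridge(as.matrix(df[, "ndvi", drop = FALSE]), df$gy, 1, combo = "ndvi")
  path <- withr::local_tempfile(fileext = ".csv")
  out <- observed_vs_predicted(m, tt, path)
  expect_equal(nrow(out), n_plots(tt))
  expect_true(file.exists(path))
  expect_equal(out$predicted_gy, unname(predict(m, tt)))
})
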