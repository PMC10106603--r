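# Held-out validation: R2, RMSE, observed-vs-predicted regression, and the
# comparison against the NDVI-only benchmark.

P_FLOOR <- 1e-15

#' Squared Pearson correlation with its test probability
#'
#' @param x,y numeric vectors of equal length, n >= 3, both non-constant.
#' @return `list(r2, p_value)`: the squared Pearson correlation and the
#'   two-sided t-test p-value on n - 2 degrees of freedom. p-values below
#'   1e-15 are floored at 1e-15.
#' @export
pearson_r2 <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r2 = unname(ct$estimate)^2, p_value = max(ct$p.value, P_FLOOR))
}

#' Evaluate a fitted model on held-out validation plots
#'
#' Predicts grain yield for the validation plots with complete values for
#' the model's traits and compares against observed yield: squared Pearson
#' correlation (with p-value), root mean square error, and the
#' observed-on-predicted OLS line (slope, intercept).
#'
#' @param model a `ridge_model`.
#' @param validation a [trial_table] with at least 3 complete cases for the
#'   model's traits and `gy`.
#' @return an object of class `validation_metrics`: `r2`, `p_value`, `rmse`
#'   (t/ha), `n`, `slope`, `intercept_ov`, `constant_predictions`. When the
#'   predictions are constant, `r2`/`p_value`/`slope` are `NA` (flagged) and
#'   the RMSE is still reported.
#' @export
evaluate_model <- function(model, validation) {
  stopifnot(inherits(model, "ridge_model"), inherits(validation, "trial_table"))
  df <- as.data.frame(validation)
  keep <- stats::complete.cases(df[, c(model$combo, "gy"), drop = FALSE])
  df <- df[keep, , drop = FALSE]
  if (nrow(df) < 3) {
    stop("validation requires >= 3 complete cases for ",
         combo_label(model$combo), " (have ", nrow(df), ")")
  }
  obs <- df$gy
  pred <- predict(model, df)
  rmse <- sqrt(mean((obs - pred)^2))
  if (stats::sd(pred) < SCALE_TOL || stats::sd(obs) < SCALE_TOL) {
    return(structure(list(r2 = NA_real_, p_value = NA_real_, rmse = rmse,
                          n = nrow(df), slope = NA_real_,
                          intercept_ov = if (stats::sd(pred) < SCALE_TOL)
                            mean(obs) else NA_real_,
                          constant_predictions = TRUE),
                     class = "validation_metrics"))
  }
  pr <- pearson_r2(obs, pred)
  ols <- stats::lm.fit(cbind(1, pred), obs)$coefficients
  structure(list(r2 = pr$r2, p_value = pr$p_value, rmse = rmse, n = nrow(df),
                 slope = unname(ols[2]), intercept_ov = unname(ols[1]),
                 constant_predictions = FALSE),
            class = "validation_metrics")
}

#' @export
print.validation_metrics <- function(x, ...) {
  cat(sprintf("validation_metrics: n=%d  R2=%.3f  RMSE=%.3f t/ha  p=%.3g\n",
              x$n, x$r2, x$rmse, x$p_value))
  cat(sprintf("  observed ~ predicted: slope=%.3f intercept=%.3f\n",
              x$slope, x$intercept_ov))
  invisible(x)
}

#' Compare two sets of validation metrics (best model vs NDVI benchmark)
#'
#' Relative differences follow the reporting convention
#' `100 * (best - benchmark) / benchmark` for both R2 ("prediction
#' accuracy") and RMSE; e.g. R2 0.60 vs 0.40 is a +50% accuracy change and
#' RMSE 0.9 vs 1.0 a -10% RMSE change. When the benchmark R2 is zero or
#' undefined, absolute deltas are reported instead and the relative R2 delta
#' is `NA`.
#'
#' @param best_metrics,benchmark_metrics `validation_metrics` computed on
#'   the same validation plots.
#' @return an object of class `comparison_report`: `best_model_metrics`,
#'   `benchmark_metrics`, `delta_r2_relative`, `delta_rmse_relative`
#'   (percent), `delta_r2_absolute`, `delta_rmse_absolute`.
#' @export
compare_metrics <- function(best_metrics, benchmark_metrics) {
  stopifnot(inherits(best_metrics, "validation_metrics"),
            inherits(benchmark_metrics, "validation_metrics"))
  b <- best_metrics; k <- benchmark_metrics
  d_r2_abs <- b$r2 - k$r2
  d_rmse_abs <- b$rmse - k$rmse
  d_r2_rel <- if (!is.na(k$r2) && k$r2 > 0) 100 * d_r2_abs / k$r2 else NA_real_
  d_rmse_rel <- if (k$rmse > 0) 100 * d_rmse_abs / k$rmse else NA_real_
  structure(list(best_model_metrics = b, benchmark_metrics = k,
                 delta_r2_relative = d_r2_rel,
                 delta_rmse_relative = d_rmse_rel,
                 delta_r2_absolute = d_r2_abs,
                 delta_rmse_absolute = d_rmse_abs),
            class = "comparison_report")
}

#' Validate a model against the NDVI-only benchmark on shared plots
#'
#' @param best a fitted `ridge_model` (any combination).
#' @param benchmark the NDVI-only `ridge_model` (combo must be `"ndvi"`).
#' @param validation the shared validation [trial_table].
#' @return a `comparison_report`, see [compare_metrics()].
#' @export
compare_to_benchmark <- function(best, benchmark, validation) {
  stopifnot(inherits(best, "ridge_model"), inherits(benchmark, "ridge_model"))
  if (!identical(benchmark$combo, "ndvi")) {
    stop("benchmark model must be the NDVI-only combination")
  }
  compare_metrics(evaluate_model(best, validation),
                  evaluate_model(benchmark, validation))
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison_report: best R2=%.3f RMSE=%.3f | benchmark R2=%.3f RMSE=%.3f\n",
              x$best_model_metrics$r2, x$best_model_metrics$rmse,
              x$benchmark_metrics$r2, x$benchmark_metrics$rmse))
  cat(sprintf("  accuracy %+.1f%%  RMSE %+.1f%%\n",
              x$delta_r2_relative, x$delta_rmse_relative))
  invisible(x)
}

#' Export observed-vs-predicted pairs for plotting
#'
#' @param model a `ridge_model`.
#' @param validation a [trial_table].
#' @param path optional CSV path.
#' @return data.frame with `plot_id`, `observed_gy`, `predicted_gy`.
#' @export
observed_vs_predicted <- function(model, validation, path = NULL) {
  df <- as.data.frame(validation)
  keep <- stats::complete.cases(df[, c(model$combo, "gy"), drop = FALSE])
  df <- df[keep, , drop = FALSE]
  out <- data.frame(plot_id = df$plot_id, observed_gy = df$gy,
                    predicted_gy = predict(model, df),
                    stringsAsFactors = FALSE)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
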