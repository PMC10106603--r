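# Penalized linear regression engine: standardization, closed-form ridge
# fit, cross-validated penalty selection, effective degrees of freedom and
# BIC. All fits standardize predictors to zero mean and unit population
# standard deviation (1/n convention), leave the intercept unpenalized, and
# report coefficients back on the original trait scale.

SCALE_TOL <- 1e-10

# centers/scales with the population (1/n) variance convention; errors on
# zero-variance columns because ridge standardization is then undefined.
standardize_columns <- function(x, context = "design") {
  centers <- colMeans(x)
  xc <- sweep(x, 2, centers)
  scales <- sqrt(colMeans(xc^2))
  if (any(scales < SCALE_TOL)) {
    bad <- colnames(x)[scales < SCALE_TOL] %||% which(scales < SCALE_TOL)
    stop("zero-variance predictor in ", context, ": ",
         paste(bad, collapse = ", "))
  }
  list(z = sweep(xc, 2, scales, "/"), centers = centers, scales = scales)
}

as_design_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (anyNA(x) || !all(is.finite(x))) stop("design matrix contains missing or non-finite values")
  x
}

#' Fit a ridge regression model in closed form
#'
#' Minimizes `||y - b0 - Z b||^2 + lambda * ||b||^2` over the standardized
#' design `Z` (zero mean, unit population SD per column) with an unpenalized
#' intercept, via the singular value decomposition. Coefficients and
#' intercept are returned on the original trait scale, together with the
#' residual sum of squares, the effective degrees of freedom
#' `edf = sum(d_i^2 / (d_i^2 + lambda))`, and the BIC
#' `n*log(rss/n) + (edf + 1)*log(n)`.
#'
#' @param x numeric matrix (n x p) of predictors, `n >= p + 2`; column names
#'   identify the trait combination.
#' @param y numeric response vector (grain yield, t/ha).
#' @param lambda ridge penalty, `>= 0`.
#' @param combo optional character vector naming the trait combination;
#'   defaults to `colnames(x)`.
#' @return an object of class `ridge_model` with elements `combo`,
#'   `coefficients`, `intercept`, `lambda`, `centers`, `scales`, `n_train`,
#'   `rss`, `edf`, `bic`, `r2_train`, `rmse_train`.
#' @seealso [select_lambda_cv()], [predict.ridge_model()], [bic_of()]
#' @export
fit_ridge <- function(x, y, lambda, combo = NULL) {
  x <- as_design_matrix(x)
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  stopifnot(length(y) == n)
  if (anyNA(y) || !all(is.finite(y))) stop("response contains missing or non-finite values")
  if (n < p + 2) stop("need at least p + 2 observations to fit (n = ", n, ", p = ", p, ")")
  if (!is.finite(lambda) || lambda < 0) stop("lambda must be a finite number >= 0")
  std <- standardize_columns(x)
  ybar <- mean(y)
  yc <- y - ybar
  sv <- svd(std$z)
  d2 <- sv$d^2
  uty <- drop(crossprod(sv$u, yc))
  # at lambda = 0, d/(d^2 + 0) = 1/d on the non-null space only
  shrink <- if (lambda == 0) {
    ifelse(sv$d > SCALE_TOL, 1 / sv$d, 0)
  } else {
    sv$d / (d2 + lambda)
  }
  beta_std <- drop(sv$v %*% (shrink * uty))
  fitted <- drop(std$z %*% beta_std) + ybar
  rss <- sum((y - fitted)^2)
  edf <- if (lambda == 0) sum(sv$d > SCALE_TOL) else sum(d2 / (d2 + lambda))
  tss <- sum(yc^2)
  coefficients <- beta_std / std$scales
  names(coefficients) <- colnames(x)
  bic <- if (rss > 0) n * log(rss / n) + (edf + 1) * log(n) else NA_real_
  if (rss == 0) warning("perfect fit (rss = 0): BIC undefined, set to NA")
  structure(list(
    combo = combo %||% colnames(x),
    coefficients = coefficients,
    intercept = ybar - sum(coefficients * std$centers),
    lambda = lambda,
    centers = std$centers, scales = std$scales,
    n_train = n, rss = rss, edf = edf, bic = bic,
    r2_train = if (tss > 0) 1 - rss / tss else NA_real_,
    rmse_train = sqrt(rss / n)
  ), class = "ridge_model")
}

#' Predict grain yield from a fitted ridge model
#'
#' @param object a `ridge_model`.
#' @param newdata matrix with columns in the model's trait order, or a
#'   data.frame containing the model's trait columns (e.g. a
#'   [trial_table]).
#' @param ... unused.
#' @return numeric vector of predicted yields (t/ha).
#' @export
predict.ridge_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    miss <- setdiff(object$combo, names(newdata))
    if (length(miss) > 0) stop("newdata lacks column(s): ", paste(miss, collapse = ", "))
    newdata <- as.matrix(as.data.frame(newdata)[, object$combo, drop = FALSE])
  }
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients)) {
    stop("column-count mismatch: model has ", length(object$coefficients),
         " predictors, newdata has ", ncol(newdata))
  }
  drop(newdata %*% object$coefficients) + object$intercept
}

#' Effective degrees of freedom of a ridge fit
#'
#' The trace of the ridge hat matrix `Z (Z'Z + lambda I)^-1 Z'` on the
#' standardized design, equal to `sum(d_i^2 / (d_i^2 + lambda))` over the
#' singular values `d_i`. Equals `rank(Z)` at `lambda = 0` and decreases to 0
#' as `lambda` grows.
#'
#' @inheritParams fit_ridge
#' @return effective degrees of freedom (dimensionless, in `[0, p]`).
#' @export
effective_df <- function(x, lambda) {
  x <- as_design_matrix(x)
  if (!is.finite(lambda) || lambda < 0) stop("lambda must be a finite number >= 0")
  d <- svd(standardize_columns(x)$z, nu = 0, nv = 0)$d
  if (lambda == 0) return(sum(d > SCALE_TOL))
  sum(d^2 / (d^2 + lambda))
}

#' BIC of a fitted ridge model
#'
#' Gaussian-likelihood BIC omitting additive constants,
#' `n*log(rss/n) + (edf + 1)*log(n)`; the `+1` counts the unpenalized
#' intercept. Lower is better. At `lambda = 0` on a full-rank design this
#' reduces to the textbook BIC with `p + 1` parameters.
#'
#' @param model a fitted `ridge_model`.
#' @return the BIC (dimensionless).
#' @export
bic_of <- function(model) {
  stopifnot(inherits(model, "ridge_model"))
  if (model$rss <= 0) stop("degenerate perfect fit (rss = 0): BIC undefined")
  model$n_train * log(model$rss / model$n_train) +
    (model$edf + 1) * log(model$n_train)
}

#' Default penalty grid for cross-validation
#'
#' 100 log-spaced penalties, descending, spanning
#' `[1e-6 * d_max^2, 100 * d_max^2]` where `d_max` is the largest singular
#' value of the standardized design. The grid endpoints correspond to
#' shrinkage factors from essentially 1 (no shrinkage) down to about 0.01
#' (slopes nearly annihilated), so cross-validation can express anything
#' between an OLS-like fit and an intercept-only fit.
#'
#' @inheritParams fit_ridge
#' @param n_grid number of grid points (default 100).
#' @return numeric vector of penalties, strictly positive, descending.
#' @export
default_lambda_grid <- function(x, y = NULL, n_grid = 100) {
  x <- as_design_matrix(x)
  dmax2 <- max(svd(standardize_columns(x)$z, nu = 0, nv = 0)$d^2)
  if (!is.finite(dmax2) || dmax2 <= 0) dmax2 <- 1
  exp(seq(log(100 * dmax2), log(1e-6 * dmax2), length.out = n_grid))
}

#' Select the ridge penalty by k-fold cross-validation
#'
#' Fold membership comes from a seeded permutation (fold sizes differ by at
#' most one). For each grid penalty the mean held-out squared prediction
#' error is computed, standardizing within each fold's training rows; the
#' selected penalty minimizes this error, with ties broken toward the larger
#' penalty (more regularization). Deterministic given the seed.
#'
#' @inheritParams fit_ridge
#' @param k_folds number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param grid optional descending positive penalty grid; defaults to
#'   [default_lambda_grid()].
#' @param n_grid grid length when `grid` is NULL.
#' @return `list(lambda, grid, cv_mse, k_folds, seed)` where `lambda` is the
#'   selected penalty.
#' @export
select_lambda_cv <- function(x, y, k_folds = 10, seed = 1L, grid = NULL,
                             n_grid = 100) {
  x <- as_design_matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  stopifnot(length(y) == n)
  if (k_folds < 2 || k_folds > n) stop("k_folds must lie in [2, n]")
  if (n < 2 * k_folds) stop("fold with < 2 observations: reduce k_folds")
  if (is.null(grid)) grid <- default_lambda_grid(x, y, n_grid = n_grid)
  if (length(grid) == 0) stop("empty penalty grid")
  if (any(grid <= 0)) stop("penalty grid must be strictly positive")
  grid <- sort(grid, decreasing = TRUE)
  fold <- integer(n)
  fold[with_seed(seed, sample.int(n))] <- rep_len(seq_len(k_folds), n)
  sse <- numeric(length(grid))
  for (k in seq_len(k_folds)) {
    tr <- fold != k
    std <- standardize_columns(x[tr, , drop = FALSE], context = "CV fold")
    ytr <- y[tr]
    ybar <- mean(ytr)
    # ridge path via the p x p eigen-system: (Z'Z + lambda I)^-1 Z'y for the
    # whole grid in one small matrix product
    ev <- eigen(crossprod(std$z), symmetric = TRUE)
    w <- drop(crossprod(ev$vectors, crossprod(std$z, ytr - ybar)))
    bmat <- ev$vectors %*% (w / outer(pmax(ev$values, 0), grid, "+"))
    zva <- sweep(sweep(x[!tr, , drop = FALSE], 2, std$centers), 2, std$scales, "/")
    pred <- zva %*% bmat + ybar
    sse <- sse + colSums((y[!tr] - pred)^2)
  }
  cv_mse <- sse / n
  list(lambda = grid[which.min(cv_mse)], grid = grid, cv_mse = cv_mse,
       k_folds = k_folds, seed = as.integer(seed))
}

#' Fit a ridge model with a cross-validated penalty
#'
#' Convenience wrapper: [select_lambda_cv()] followed by [fit_ridge()] at
#' the selected penalty.
#'
#' @inheritParams select_lambda_cv
#' @param combo optional trait-combination label passed to [fit_ridge()].
#' @return a `ridge_model` with an extra element `cv` holding the search.
#' @export
ridge_cv_fit <- function(x, y, k_folds = 10, seed = 1L, grid = NULL,
                         n_grid = 100, combo = NULL) {
  cv <- select_lambda_cv(x, y, k_folds = k_folds, seed = seed, grid = grid,
                         n_grid = n_grid)
  model <- fit_ridge(x, y, lambda = cv$lambda, combo = combo)
  model$cv <- cv
  model
}

#' @export
print.ridge_model <- function(x, ...) {
  cat(sprintf("ridge_model: gy ~ %s  (n = %d, lambda = %.4g)\n",
              paste(x$combo, collapse = " + "), x$n_train, x$lambda))
  cat(sprintf("  intercept %.4f | %s\n", x$intercept,
              paste(sprintf("%s %.4f", names(x$coefficients), x$coefficients),
                    collapse = " | ")))
  cat(sprintf("  rss %.4f  edf %.3f  BIC %.3f  train R2 %.3f  train RMSE %.3f\n",
              x$rss, x$edf, x$bic, x$r2_train, x$rmse_train))
  invisible(x)
}

#' Serialize a fitted ridge model to JSON
#'
#' @param model a `ridge_model`.
#' @param path optional file path; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
ridge_model_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "ridge_model"))
  doc <- model[c("combo", "coefficients", "intercept", "lambda", "centers",
                 "scales", "n_train", "rss", "edf", "bic")]
  js <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
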