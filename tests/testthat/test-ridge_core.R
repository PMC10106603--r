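# The ridge engine: closed-form fit, penalty selection, effective df, BIC.

random_design <- function(n, p, seed, noise = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("t", seq_len(p))))
  beta <- rnorm(p)
  y <- drop(x %*% beta) + rnorm(n, 0, noise)
  list(x = x, y = y)
}

test_that("lambda = 0 reproduces ordinary least squares", {
  d <- random_design(30, 3, seed = 1)
  m <- fit_ridge(d$x, d$y, lambda = 0)
  ols <- stats::lm(d$y ~ d$x)
  expect_equal(unname(m$coefficients), unname(coef(ols)[-1]), tolerance = 1e-8)
  expect_equal(m$intercept, unname(coef(ols)[1]), tolerance = 1e-8)
  expect_equal(unname(predict(m, d$x)), unname(fitted(ols)), tolerance = 1e-8)
  expect_equal(m$edf, 3)
})

test_that("an overwhelming penalty shrinks all slopes to the intercept-only fit", {
  d <- random_design(40, 4, seed = 2)
  m <- fit_ridge(d$x, d$y, lambda = 1e12)
  expect_true(all(abs(m$coefficients) < 1e-6))
  expect_equal(m$intercept, mean(d$y), tolerance = 1e-4)
  expect_equal(unname(predict(m, d$x[1:3, ])), rep(m$intercept, 3),
               tolerance = 1e-4)
  expect_lt(m$edf, 1e-6)
})

test_that("the 3-point worked fit matches the brute-force normal-equation oracle", {
  x <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(NULL, "t1"))
  y <- c(1, 2, 3)
  m <- fit_ridge(x, y, lambda = 1)
  o <- ridge_oracle(x, y, lambda = 1)
  expect_equal(unname(m$coefficients), unname(o$coefficients), tolerance = 1e-12)
  expect_equal(m$intercept, o$intercept, tolerance = 1e-12)
  # hand check: standardized z = (-1.2247, 0, 1.2247), z'z = 3, z'y = 2.4495,
  # beta_std = 2.4495/4, back-transformed by sd = 0.8165
  expect_equal(unname(m$coefficients), (2 * sqrt(1.5) / 4) / sqrt(2 / 3),
               tolerance = 1e-10)
  expect_equal(predict(m, matrix(2, 1, 1)),
               unname(o$intercept + 2 * o$coefficients), tolerance = 1e-12)
})

test_that("closed-form ridge equals the independent solver on random instances", {
  set.seed(33)
  for (i in 1:30) {
    n <- sample(8:30, 1)
    p <- sample(1:4, 1)
    d <- random_design(n, p, seed = 1000 + i)
    lambda <- runif(1, 0, 50)
    m <- fit_ridge(d$x, d$y, lambda)
    o <- ridge_oracle(d$x, d$y, lambda)
    expect_lt(max(abs(m$coefficients - o$coefficients)), 1e-8)
    expect_lt(abs(m$intercept - o$intercept), 1e-8)
  }
})

test_that("fit preconditions are enforced", {
  d <- random_design(10, 2, seed = 3)
  expect_error(fit_ridge(d$x[1:3, ], d$y[1:3], 1), "p \\+ 2")
  xz <- cbind(d$x, const = 1)
  expect_error(fit_ridge(xz, d$y, 1), "zero-variance")
  expect_error(fit_ridge(d$x, d$y, -1), "lambda")
  expect_error(predict(fit_ridge(d$x, d$y, 1), d$x[, 1, drop = FALSE]),
               "column-count mismatch")
})

test_that("effective df matches the dense hat-matrix trace and is monotone", {
  d <- random_design(20, 2, seed = 4)
  expect_equal(effective_df(d$x, 5), edf_oracle(d$x, 5), tolerance = 1e-10)
  expect_equal(effective_df(d$x, 0), 2)
  lams <- c(0.01, 0.1, 1, 10, 100, 1e4)
  edfs <- vapply(lams, function(l) effective_df(d$x, l), numeric(1))
  expect_true(all(diff(edfs) < 0))
  expect_lt(effective_df(d$x, 1e12), 1e-6)
  for (i in 1:10) {
    dd <- random_design(sample(10:40, 1), sample(1:4, 1), seed = 2000 + i)
    l <- runif(1, 0.01, 100)
    expect_equal(effective_df(dd$x, l), edf_oracle(dd$x, l), tolerance = 1e-10)
  }
})

test_that("BIC follows n*log(rss/n) + (edf + 1)*log(n)", {
  m <- structure(list(n_train = 10, rss = 10, edf = 2), class = "ridge_model")
  expect_equal(bic_of(m), 10 * log(1) + 3 * log(10))
  expect_equal(bic_of(m), 6.907755, tolerance = 1e-6)
  # monotone in edf at identical rss and n
  m2 <- structure(list(n_train = 10, rss = 10, edf = 1.5), class = "ridge_model")
  expect_lt(bic_of(m2), bic_of(m))
  m0 <- structure(list(n_train = 10, rss = 0, edf = 2), class = "ridge_model")
  expect_error(bic_of(m0), "perfect fit")
})

test_that("adding a pure-noise predictor raises BIC on average", {
  set.seed(55)
  diffs <- replicate(200, {
    n <- 50
    x1 <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "s"))
    y <- 3 * x1[, 1] + rnorm(n, 0, 0.5)
    x2 <- cbind(x1, noise = rnorm(n))
    fit_ridge(x2, y, lambda = 1)$bic - fit_ridge(x1, y, lambda = 1)$bic
  })
  expect_gt(mean(diffs), 0)
})

test_that("CV penalty selection is deterministic and lands on sane extremes", {
  d <- random_design(50, 3, seed = 6)
  cv1 <- select_lambda_cv(d$x, d$y, seed = 42)
  cv2 <- select_lambda_cv(d$x, d$y, seed = 42)
  expect_identical(cv1$lambda, cv2$lambda)
  expect_identical(cv1$cv_mse, cv2$cv_mse)
  expect_length(cv1$cv_mse, 100)
  expect_true(all(diff(cv1$grid) < 0))
  # exact noiseless linear signal: any shrinkage hurts
  set.seed(7)
  x <- matrix(rnorm(50), 50, 1, dimnames = list(NULL, "t"))
  y <- 2 * x[, 1]
  cv <- select_lambda_cv(x, y, seed = 3)
  expect_equal(cv$lambda, min(cv$grid))
  expect_error(select_lambda_cv(d$x, d$y, k_folds = 30), "fold")
  expect_error(select_lambda_cv(d$x, d$y, grid = numeric(0)), "grid")
})

test_that("pure-noise responses select the largest penalty in most seeds", {
  hits <- vapply(1:60, function(s) {
    set.seed(s)
    x <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, paste0("t", 1:4)))
    y <- rnorm(50)
    cv <- select_lambda_cv(x, y, seed = derive_seed(s, 1))
    cv$lambda == max(cv$grid)
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("coefficient norms shrink and predictions are shift/scale invariant", {
  d <- random_design(40, 3, seed = 8)
  lams <- c(0.1, 1, 10, 100, 1000)
  norms <- vapply(lams, function(l) {
    m <- fit_ridge(d$x, d$y, l)
    sqrt(sum((m$coefficients * m$scales)^2)) # back to standardized scale
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
  # affine changes of the predictor columns leave fitted values unchanged
  m1 <- fit_ridge(d$x, d$y, 3)
  x2 <- sweep(sweep(d$x, 2, c(10, -5, 100), "+"), 2, c(2, 0.5, 30), "*")
  m2 <- fit_ridge(x2, d$y, 3)
  expect_equal(predict(m1, d$x), predict(m2, x2), tolerance = 1e-8)
})

test_that("ridge models serialize to JSON with all fit constants", {
  d <- random_design(30, 2, seed = 9)
  m <- ridge_cv_fit(d$x, d$y, seed = 1)
  js <- jsonlite::fromJSON(ridge_model_json(m))
  expect_equal(unlist(js$coefficients), m$coefficients, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(js$lambda, m$lambda)
  expect_equal(js$n_train, 30)
})
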