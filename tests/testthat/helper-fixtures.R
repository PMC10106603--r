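# Shared fixtures and independent oracles, built in code at test time.

# A small hand-written valid table.
tiny_table <- function(n = 6) {
  trial_table(data.frame(
    plot_id = sprintf("p%02d", seq_len(n)),
    genotype_id = rep(c("g1", "g2"), length.out = n),
    germplasm_class = rep(c("landrace", "modern"), length.out = n),
    experiment_id = "E1",
    water_regime = "rainfed",
    sowing_date = "2016-11-21",
    replicate = rep(1:2, length.out = n),
    gy = seq(4, 10, length.out = n),
    ndvi = seq(0.5, 0.85, length.out = n),
    dh = seq(130, 150, length.out = n),
    ph = seq(70, 110, length.out = n),
    ears = seq(350, 550, length.out = n),
    stringsAsFactors = FALSE
  ), provenance = "fixture")
}

# A random valid table with some absent trait values (for round-trip props).
random_table <- function(n, seed, na_frac = 0.1) {
  set.seed(seed)
  df <- data.frame(
    plot_id = sprintf("r%04d", seq_len(n)),
    genotype_id = sprintf("g%03d", sample(60, n, replace = TRUE)),
    germplasm_class = sample(c("landrace", "modern"), n, replace = TRUE),
    experiment_id = sample(paste0("E", 1:3), n, replace = TRUE),
    water_regime = sample(c("rainfed", "irrigated"), n, replace = TRUE),
    sowing_date = as.Date("2020-12-03") + sample(0:20, n, replace = TRUE),
    replicate = sample(1:3, n, replace = TRUE),
    gy = runif(n, 1, 14),
    ndvi = runif(n, 0.2, 0.95),
    dh = runif(n, 120, 160),
    ph = runif(n, 50, 120),
    ears = runif(n, 200, 700),
    stringsAsFactors = FALSE
  )
  for (tr in c("ndvi", "dh", "ph", "ears")) {
    df[[tr]][sample(n, ceiling(na_frac * n))] <- NA
  }
  trial_table(df, provenance = "random fixture")
}

# Independent brute-force ridge oracle: normal equations via solve() on the
# population-standardized system, back-transformed. Shares no code with the
# package's SVD path.
ridge_oracle <- function(x, y, lambda) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  scl <- sqrt(colMeans(xc^2))
  z <- sweep(xc, 2, scl, "/")
  yc <- y - mean(y)
  beta_std <- solve(crossprod(z) + diag(lambda, p), crossprod(z, yc))
  beta <- drop(beta_std) / scl
  list(coefficients = beta, intercept = mean(y) - sum(beta * ctr),
       fitted = drop(x %*% beta) + mean(y) - sum(beta * ctr))
}

# Independent effective-df oracle: explicit dense hat-matrix trace.
edf_oracle <- function(x, lambda) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  z <- sweep(xc, 2, sqrt(colMeans(xc^2)), "/")
  h <- z %*% solve(crossprod(z) + diag(lambda, ncol(z)), t(z))
  sum(diag(h))
}

# Trait table whose yield truly depends only on NDVI and DH (strong signal):
# agronomic traits come from the generator, then yield is rebuilt from the
# realized NDVI and DH plus small noise.
signal_table <- function(seed, noise_sd = 0.25) {
  cf <- default_configs()$case2_2021
  cf$seed <- derive_seed(seed, 5)
  df <- as.data.frame(generate_trial(cf))
  set.seed(derive_seed(seed, 6))
  df$gy <- pmax(2 + 8 * df$ndvi - 0.08 * (df$dh - 140) +
                  rnorm(nrow(df), 0, noise_sd), 0.1)
  trial_table(df, provenance = "signal fixture")
}

# Balanced replicated trial drawn straight from the variance-component model.
vc_trial <- function(n_genotypes, r, sigma2_g, sigma2_e, seed, mu = 8) {
  set.seed(seed)
  g <- rnorm(n_genotypes, 0, sqrt(sigma2_g))
  gidx <- rep(seq_len(n_genotypes), each = r)
  trial_table(data.frame(
    plot_id = sprintf("v%04d", seq_along(gidx)),
    genotype_id = sprintf("g%03d", gidx),
    replicate = rep(seq_len(r), n_genotypes),
    gy = pmax(mu + g[gidx] + rnorm(length(gidx), 0, sqrt(sigma2_e)), 0.1),
    stringsAsFactors = FALSE
  ))
}
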