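# Synthetic wheat trial generator. Emulates the statistical structure the
# analysis assumes: genotype effects plus replicate error for grain yield,
# landrace/modern harvest-index classes, correlated agronomic traits via a
# Gaussian copula, and an NDVI that saturates with canopy biomass.

GEN_TRAITS <- c("gy", "dh", "ph", "ears")

#' Default trait correlation structure (GY, DH, PH, EARS)
#'
#' Latent Gaussian correlations: yield correlates negatively with days to
#' heading (later-heading material yields less in this Mediterranean
#' environment) and positively with plant height and ear density within
#' modern germplasm. Symmetric positive definite with unit diagonal.
#'
#' @return 4x4 correlation matrix with dimnames `gy, dh, ph, ears`.
#' @export
default_trait_corr <- function() {
  m <- matrix(c(
     1.00, -0.60,  0.70,  0.70,
    -0.60,  1.00, -0.40, -0.40,
     0.70, -0.40,  1.00,  0.45,
     0.70, -0.40,  0.45,  1.00
  ), 4, 4, dimnames = list(GEN_TRAITS, GEN_TRAITS))
  m
}

#' Parameterize the synthetic trial generator
#'
#' @param cells data.frame with one row per experiment-by-class cell and
#'   columns `experiment_id`, `water_regime`, `sowing_date`,
#'   `germplasm_class`, `n_genotypes`, `n_reps`, `gy_mean`, `gy_sd`
#'   (phenotypic plot-level mean and SD, t/ha) and `h2` (target broad-sense
#'   heritability; `NA` for non-replicated cells). Genotypic and error
#'   variances are derived per cell: for a replicated cell with target `h2`,
#'   `sigma2_g = h2 * sd^2 / (r * (1 - h2) + h2)` (so the heritability of a
#'   balanced trial with `r` replicates equals `h2` and the plot-level
#'   variance equals `sd^2`); non-replicated cells split the variance evenly.
#' @param harvest_index named vector, grain mass / above-ground biomass per
#'   germplasm class (landraces partition much less biomass to grain).
#' @param ndvi_soil NDVI of bare soil (asymptote at zero biomass).
#' @param ndvi_max canopy NDVI asymptote at large biomass.
#' @param sat_rate exponential saturation rate per t/ha of biomass; with the
#'   defaults, canopies above ~8 t/ha grain (modern harvest index) sit on
#'   the flat part of the curve.
#' @param lin_rate NDVI per t/ha biomass for the non-saturating (affine)
#'   alternative used when `saturation_enabled = FALSE`.
#' @param ndvi_noise_sd SD of plot-level NDVI measurement/canopy noise.
#' @param saturation_enabled logical; FALSE replaces the saturating response
#'   with the affine one.
#' @param trait_means,trait_sds named vectors for `dh` (days), `ph` (cm),
#'   `ears` (ears/m2).
#' @param class_shifts per-class additive shifts of the trait means
#'   (landraces head later, are taller, tiller less densely).
#' @param trait_corr 4x4 latent correlation matrix, see
#'   [default_trait_corr()].
#' @param gy_floor lower bound applied to simulated yields (t/ha).
#' @param seed integer seed; generation is deterministic given the config.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(cells,
                             harvest_index = c(landrace = 0.33, modern = 0.48),
                             ndvi_soil = 0.15, ndvi_max = 0.92,
                             sat_rate = 0.15, lin_rate = 0.025,
                             ndvi_noise_sd = 0.04,
                             saturation_enabled = TRUE,
                             trait_means = c(dh = 140, ph = 85, ears = 450),
                             trait_sds = c(dh = 6, ph = 12, ears = 80),
                             class_shifts = list(
                               landrace = c(dh = 5, ph = 25, ears = -60),
                               modern = c(dh = 0, ph = 0, ears = 0)),
                             trait_corr = default_trait_corr(),
                             gy_floor = 0.1, seed = 1L) {
  stopifnot(is.data.frame(cells), nrow(cells) >= 1)
  need <- c("experiment_id", "water_regime", "sowing_date", "germplasm_class",
            "n_genotypes", "n_reps", "gy_mean", "gy_sd", "h2")
  miss <- setdiff(need, names(cells))
  if (length(miss) > 0) stop("cells lacks column(s): ", paste(miss, collapse = ", "))
  stopifnot(all(cells$n_genotypes >= 1), all(cells$n_reps >= 1),
            all(cells$gy_mean > 0), all(cells$gy_sd > 0),
            all(is.na(cells$h2) | (cells$h2 > 0 & cells$h2 < 1)),
            all(cells$germplasm_class %in% GERMPLASM_CLASSES),
            all(cells$water_regime %in% WATER_REGIMES))
  stopifnot(all(harvest_index > 0), all(harvest_index <= 1),
            ndvi_max > 0, ndvi_max <= 1, ndvi_soil >= 0, ndvi_soil < ndvi_max,
            sat_rate > 0, lin_rate > 0, ndvi_noise_sd >= 0,
            all(trait_sds > 0), gy_floor > 0)
  if (!isTRUE(all.equal(trait_corr, t(trait_corr))) ||
      !isTRUE(all.equal(unname(diag(trait_corr)), rep(1, 4)))) {
    stop("trait_corr must be symmetric with unit diagonal")
  }
  if (min(eigen(trait_corr, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("trait_corr is not positive semi-definite")
  }
  # per-cell variance components hitting the target H2 at the cell's r
  var_tot <- cells$gy_sd^2
  sg <- ifelse(!is.na(cells$h2) & cells$n_reps >= 2,
               cells$h2 * var_tot / (cells$n_reps * (1 - cells$h2) + cells$h2),
               0.5 * var_tot)
  cells$sigma2_g <- sg
  cells$sigma2_e <- var_tot - sg
  structure(list(cells = cells, harvest_index = harvest_index,
                 ndvi_soil = ndvi_soil, ndvi_max = ndvi_max,
                 sat_rate = sat_rate, lin_rate = lin_rate,
                 ndvi_noise_sd = ndvi_noise_sd,
                 saturation_enabled = isTRUE(saturation_enabled),
                 trait_means = trait_means, trait_sds = trait_sds,
                 class_shifts = class_shifts, trait_corr = trait_corr,
                 gy_floor = gy_floor, seed = as.integer(seed)),
            class = "generator_config")
}

#' Noiseless saturating NDVI response to canopy biomass
#'
#' `ndvi_soil + (ndvi_max - ndvi_soil) * (1 - exp(-sat_rate * biomass))`: a
#' Beer-Lambert-like exponential approach from the bare-soil NDVI to the
#' dense-canopy asymptote, monotone non-decreasing in biomass. Measurement
#' noise and clipping to `[0, 1]` are applied by [generate_trial()].
#'
#' @param biomass above-ground biomass, t/ha, `>= 0`.
#' @param config a [generator_config()].
#' @return NDVI values (dimensionless).
#' @export
saturating_ndvi <- function(biomass, config) {
  stopifnot(inherits(config, "generator_config"))
  if (any(biomass < 0)) stop("biomass must be >= 0")
  config$ndvi_soil +
    (config$ndvi_max - config$ndvi_soil) * (1 - exp(-config$sat_rate * biomass))
}

#' Generate a synthetic plot-level trial table
#'
#' Per cell, genotype effects are drawn `N(0, sigma2_g)` and plot yields are
#' `gy_mean + genotype effect + N(0, sigma2_e)`, floored at `gy_floor`. Days
#' to heading, plant height and ear density are drawn jointly with yield
#' from the Gaussian copula implied by `trait_corr` and mapped to the
#' configured means/SDs (plus per-class shifts); DH and EARS are rounded to
#' whole units. Biomass is `gy / harvest_index(class)` and NDVI is the
#' saturating (or affine, when saturation is disabled) response plus
#' Gaussian noise, clipped to `[0, 1]`. Deterministic given the config.
#'
#' @param config a [generator_config()].
#' @return a [trial_table].
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  corr <- config$trait_corr
  rho <- corr["gy", c("dh", "ph", "ears")]
  cond_cov <- corr[c("dh", "ph", "ears"), c("dh", "ph", "ears")] - tcrossprod(rho)
  ev <- eigen(cond_cov, symmetric = TRUE)
  chol_like <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)))

  with_seed(config$seed, {
    parts <- lapply(seq_len(nrow(config$cells)), function(ci) {
      cell <- config$cells[ci, ]
      ng <- cell$n_genotypes; r <- cell$n_reps; n <- ng * r
      g_eff <- stats::rnorm(ng, 0, sqrt(cell$sigma2_g))
      gidx <- rep(seq_len(ng), each = r)
      gy <- cell$gy_mean + g_eff[gidx] + stats::rnorm(n, 0, sqrt(cell$sigma2_e))
      gy <- pmax(gy, config$gy_floor)
      z_gy <- (gy - cell$gy_mean) / cell$gy_sd
      eps <- matrix(stats::rnorm(n * 3), n, 3) %*% t(chol_like)
      z_traits <- outer(z_gy, rho) + eps
      shift <- config$class_shifts[[cell$germplasm_class]] %||% c(dh = 0, ph = 0, ears = 0)
      dh <- round(config$trait_means["dh"] + shift["dh"] +
                    config$trait_sds["dh"] * z_traits[, 1])
      ph <- config$trait_means["ph"] + shift["ph"] +
        config$trait_sds["ph"] * z_traits[, 2]
      ears <- round(config$trait_means["ears"] + shift["ears"] +
                      config$trait_sds["ears"] * z_traits[, 3])
      biomass <- gy / config$harvest_index[[cell$germplasm_class]]
      ndvi_clean <- if (config$saturation_enabled) {
        saturating_ndvi(biomass, config)
      } else {
        config$ndvi_soil + config$lin_rate * biomass
      }
      ndvi <- pmin(1, pmax(0, ndvi_clean + stats::rnorm(n, 0, config$ndvi_noise_sd)))
      data.frame(
        plot_id = sprintf("%s_C%d_P%03d", cell$experiment_id, ci, seq_len(n)),
        genotype_id = sprintf("%s_C%d_G%03d", cell$experiment_id, ci, gidx),
        germplasm_class = cell$germplasm_class,
        experiment_id = cell$experiment_id,
        water_regime = cell$water_regime,
        sowing_date = cell$sowing_date,
        replicate = rep(seq_len(r), times = ng),
        gy = gy, ndvi = ndvi,
        dh = pmax(dh, 1), ph = pmax(ph, 1), ears = pmax(ears, 1),
        stringsAsFactors = FALSE
      )
    })
    trial_table(do.call(rbind, parts), provenance = "synthetic")
  })
}

#' Preset generator configurations for the two case-study structures
#'
#' Three presets emulating the published trial structures:
#' \describe{
#'   \item{`case1_2017`, `case1_2018`}{one non-replicated rainfed experiment
#'     per season with 170 landrace and 184 modern-variety plots; landraces
#'     yield ~5 t/ha with harvest index ~0.33, modern varieties ~9.5 t/ha
#'     with harvest index ~0.48, so both classes carry similar canopy
#'     biomass and NDVI.}
#'   \item{`case2_2021`}{seven replicated alpha-lattice experiments of
#'     modern varieties under rainfed/irrigated regimes and two sowing
#'     dates, spanning cell means 4.1-11.9 t/ha with target heritabilities
#'     0.664-0.903, so both saturation strata (below/above 8 t/ha) are
#'     populated.}
#' }
#'
#' @return named list of [generator_config()] objects.
#' @export
default_configs <- function() {
  case1_cells <- function(sowing, lr_mean, lr_sd, mo_mean, mo_sd) {
    data.frame(
      experiment_id = "E1", water_regime = "rainfed", sowing_date = sowing,
      germplasm_class = c("landrace", "modern"),
      n_genotypes = c(170L, 184L), n_reps = 1L,
      gy_mean = c(lr_mean, mo_mean), gy_sd = c(lr_sd, mo_sd), h2 = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  case2_cells <- data.frame(
    experiment_id = paste0("E", 1:7),
    water_regime = c("rainfed", "irrigated", "rainfed", "irrigated",
                     "irrigated", "irrigated", "rainfed"),
    sowing_date = c("2020-12-27", "2020-12-27", "2020-12-03", "2020-12-03",
                    "2020-12-03", "2020-12-03", "2020-12-03"),
    germplasm_class = "modern",
    n_genotypes = c(10L, 10L, 10L, 10L, 22L, 22L, 16L),
    n_reps = c(3L, 3L, 3L, 3L, 3L, 3L, 6L),
    gy_mean = c(5.33, 8.87, 7.86, 10.32, 11.87, 10.55, 4.14),
    gy_sd = c(1.61, 1.77, 2.17, 1.90, 1.54, 1.02, 1.09),
    h2 = c(0.688, 0.885, 0.776, 0.903, 0.678, 0.664, 0.697),
    stringsAsFactors = FALSE
  )
  list(
    case1_2017 = generator_config(
      case1_cells("2016-11-21", 5.10, 0.91, 9.48, 1.01), seed = 2017L),
    case1_2018 = generator_config(
      case1_cells("2017-11-15", 5.63, 0.82, 9.94, 0.98), seed = 2018L),
    case2_2021 = generator_config(case2_cells, seed = 2021L)
  )
}

#' Empirical checks of a generated trial against its configuration
#'
#' Computes, from the emitted table only: per-cell yield means and SDs with
#' pass flags (mean within 3 standard errors of the target), empirical
#' within-cell trait correlations vs the configured latent targets (flagged
#' at `+/- 0.1` when n >= 1000, informational below), empirical broad-sense
#' heritability per replicated experiment, and the stratified NDVI-yield
#' r-squared below/above a yield threshold with the plateau SD ratio.
#'
#' @param table a table emitted by [generate_trial()].
#' @param config the [generator_config()] that produced it.
#' @param threshold saturation threshold for the stratified check (t/ha).
#' @return an object of class `generator_report`.
#' @export
verify_generator <- function(table, config, threshold = 8) {
  stopifnot(inherits(table, "trial_table"), inherits(config, "generator_config"))
  df <- as.data.frame(table)
  cells <- config$cells
  cell_rows <- lapply(seq_len(nrow(cells)), function(ci) {
    cell <- cells[ci, ]
    sub <- df[df$experiment_id == cell$experiment_id &
                df$germplasm_class == cell$germplasm_class, , drop = FALSE]
    n <- nrow(sub)
    # SE of the cell mean under the genotype-effect design (genotype effects
    # are shared within a genotype, so the design effect matters at small n_g)
    se <- sqrt(cell$sigma2_g / cell$n_genotypes + cell$sigma2_e / n)
    data.frame(experiment_id = cell$experiment_id,
               germplasm_class = cell$germplasm_class, n = n,
               gy_mean_target = cell$gy_mean, gy_mean = mean(sub$gy),
               gy_sd_target = cell$gy_sd, gy_sd = stats::sd(sub$gy),
               mean_pass = abs(mean(sub$gy) - cell$gy_mean) <= 3 * se,
               stringsAsFactors = FALSE)
  })
  cell_summary <- do.call(rbind, cell_rows)

  # pooled within-cell correlations on the pre-NDVI latent traits
  zs <- lapply(seq_len(nrow(cells)), function(ci) {
    cell <- cells[ci, ]
    sub <- df[df$experiment_id == cell$experiment_id &
                df$germplasm_class == cell$germplasm_class, GEN_TRAITS]
    scale(as.matrix(sub))
  })
  z <- do.call(rbind, zs)
  emp_corr <- stats::cor(z)
  corr_ok <- abs(emp_corr - config$trait_corr) <= 0.1
  diag(corr_ok) <- TRUE

  h2_rows <- lapply(unique(cells$experiment_id[cells$n_reps >= 2]), function(e) {
    sub <- new_trial_subset(df[df$experiment_id == e, , drop = FALSE])
    vc <- variance_components(sub, "gy")
    data.frame(experiment_id = e,
               h2_target = cells$h2[match(e, cells$experiment_id)],
               h2 = broad_sense_h2(vc), stringsAsFactors = FALSE)
  })
  h2_summary <- if (length(h2_rows) > 0) do.call(rbind, h2_rows) else NULL

  sat <- saturation_scan(table, threshold)
  nd <- df[!is.na(df$ndvi), ]
  sd_below <- stats::sd(nd$ndvi[nd$gy < threshold])
  sd_above <- stats::sd(nd$ndvi[nd$gy >= threshold])

  structure(list(cell_summary = cell_summary, emp_corr = emp_corr,
                 corr_pass = corr_ok, corr_n = nrow(z),
                 h2_summary = h2_summary, saturation = sat,
                 ndvi_sd_below = sd_below, ndvi_sd_above = sd_above,
                 all_moment_checks_pass = all(cell_summary$mean_pass)),
            class = "generator_report")
}

#' @export
print.generator_report <- function(x, ...) {
  cat("generator_report\n")
  print(x$cell_summary, row.names = FALSE, digits = 4)
  if (!is.null(x$h2_summary)) {
    cat("heritability (gy):\n")
    print(x$h2_summary, row.names = FALSE, digits = 3)
  }
  cat(sprintf("stratified NDVI-GY r2: below %.3f / above %.3f (threshold %g)\n",
              x$saturation$r2_below[1], x$saturation$r2_above[1],
              x$saturation$threshold[1]))
  cat(sprintf("NDVI SD below/above: %.4f / %.4f\n",
              x$ndvi_sd_below, x$ndvi_sd_above))
  invisible(x)
}
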