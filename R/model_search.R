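# Exhaustive trait-combination search over repeated random training subsets,
# with selection by BIC.

CANDIDATE_TRAITS <- c("ndvi", "ph", "dh", "ears")

combo_label <- function(combo) paste(combo, collapse = "+")

#' Enumerate all non-empty trait combinations
#'
#' Produces the `2^p - 1` candidate models in a fixed deterministic order:
#' multi-trait combinations grouped by their leading trait (in the canonical
#' order of `traits`), within a group by decreasing size then
#' lexicographically, and the single-trait models last in canonical order.
#' For the four canonical traits this is the conventional listing
#' NDVI+PH+DH+EARS, NDVI+PH+DH, ..., NDVI, PH, DH, EARS.
#'
#' @param traits ordered character vector of candidate traits (1 to 10).
#' @return list of character vectors, each a trait combination.
#' @examples
#' length(enumerate_models(c("ndvi", "ph", "dh", "ears"))) # 15
#' @export
enumerate_models <- function(traits = CANDIDATE_TRAITS) {
  p <- length(traits)
  if (p < 1) stop("candidate trait set must be non-empty")
  if (p > 10) stop("exhaustive search guarded at 10 traits (got ", p, ")")
  if (anyDuplicated(traits)) stop("duplicate traits in candidate set")
  combos <- lapply(seq_len(2^p - 1), function(mask) {
    which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
  })
  keys <- vapply(combos, function(idx) {
    size <- length(idx)
    sprintf("%d_%02d_%02d_%s",
            as.integer(size == 1), idx[1], 99 - size,
            paste(sprintf("%02d", idx), collapse = ""))
  }, character(1))
  lapply(combos[order(keys)], function(idx) traits[idx])
}

# Draw a training subset of `size` complete-case rows, redrawing (derived
# seeds, max 10 retries) if any requested combo is degenerate on the subset.
draw_training_subset <- function(m, pool_idx, size, seed, combos,
                                 max_retries = 10) {
  for (try in 0:max_retries) {
    s <- if (try == 0) seed else derive_seed(seed, 1000 + try)
    idx <- with_seed(s, pool_idx[sample.int(length(pool_idx), size)])
    degenerate <- FALSE
    for (combo in combos) {
      sub <- m[idx, combo, drop = FALSE]
      sds <- sqrt(colMeans(sweep(sub, 2, colMeans(sub))^2))
      if (any(sds < SCALE_TOL)) { degenerate <- TRUE; break }
    }
    if (!degenerate) return(idx)
  }
  NULL
}

#' Calibrate one model on one random training subset
#'
#' Draws `size` plots without replacement (seeded) from the pool of plots
#' with complete values for the combination's traits and grain yield, selects
#' the ridge penalty by k-fold cross-validation, and fits the model.
#'
#' @param train_pool a [trial_table] to draw training plots from.
#' @param combo character vector of trait names (a model).
#' @param size training-set size.
#' @param iteration_seed integer seed for the draw (the CV fold seed is
#'   derived from it).
#' @param k_folds CV folds for the penalty search (default 10).
#' @param grid optional penalty grid (default data-adaptive, see
#'   [default_lambda_grid()]).
#' @return an object of class `calibration_run`: `iteration`, `combo`,
#'   `train_plot_ids`, `model` (a `ridge_model`) and `bic`.
#' @export
calibrate_once <- function(train_pool, combo, size, iteration_seed,
                           k_folds = 10, grid = NULL) {
  stopifnot(inherits(train_pool, "trial_table"))
  df <- as.data.frame(train_pool)
  complete <- stats::complete.cases(df[, c(combo, "gy"), drop = FALSE])
  pool_idx <- which(complete)
  if (length(pool_idx) < size) {
    stop("insufficient complete cases for ", combo_label(combo), ": need ",
         size, ", have ", length(pool_idx))
  }
  m <- as.matrix(df[, combo, drop = FALSE])
  idx <- draw_training_subset(m, pool_idx, size, iteration_seed, list(combo))
  if (is.null(idx)) {
    stop("degenerate training subset (zero-variance predictor) for ",
         combo_label(combo), " after retry policy")
  }
  model <- ridge_cv_fit(m[idx, , drop = FALSE], df$gy[idx], k_folds = k_folds,
                        seed = derive_seed(iteration_seed, 7), grid = grid,
                        combo = combo)
  structure(list(iteration = NA_integer_, combo = combo,
                 train_plot_ids = df$plot_id[idx], model = model,
                 bic = model$bic),
            class = "calibration_run")
}

# lower-middle order statistic index: the median for odd n, the lower of the
# two middle values for even n, so the representative is an actual run.
lower_median_index <- function(n) floor((n + 1) / 2)

#' Run the repeated-random-subset calibration over a set of models
#'
#' For each of `n_iter` iterations a training subset of `size` plots is
#' drawn (seeded, derived from `master_seed`) from the plots with complete
#' values for all candidate traits; every combination is fitted on the SAME
#' subset within an iteration, making BIC comparisons paired. Each fit uses
#' a cross-validated ridge penalty. The best combination is the one with the
#' lowest median BIC across iterations (ties broken toward fewer traits,
#' then canonical order), and the representative model is the best
#' combination's run at the lower-middle BIC order statistic.
#'
#' @param train_pool a [trial_table] of candidate training plots.
#' @param combos list of trait combinations, e.g. from [enumerate_models()].
#' @param size training-subset size (e.g. 20, 50 or 100).
#' @param n_iter number of random subsets per combination (default 100).
#' @param master_seed integer seed; iteration and CV seeds are derived from it.
#' @param k_folds CV folds (default 10).
#' @param grid optional shared penalty grid.
#' @return an object of class `calibration_ensemble`: `runs` (data.frame of
#'   iteration, combo, bic, lambda, r2_train, rmse_train), `models` (list of
#'   fitted runs), `combo_summary`, `best_combo`, `representative_model`,
#'   `training_size`, `n_iter`, `master_seed`, `n_skipped`.
#' @export
run_calibration <- function(train_pool, combos, size, n_iter = 100,
                            master_seed = 1L, k_folds = 10, grid = NULL) {
  stopifnot(inherits(train_pool, "trial_table"), length(combos) >= 1)
  df <- as.data.frame(train_pool)
  traits <- unique(unlist(combos))
  complete <- stats::complete.cases(df[, c(traits, "gy"), drop = FALSE])
  pool_idx <- which(complete)
  n_excluded <- nrow(df) - length(pool_idx)
  if (length(pool_idx) < size) {
    stop("insufficient complete cases: need ", size, ", have ", length(pool_idx))
  }
  m <- as.matrix(df[, traits, drop = FALSE])
  y <- df$gy
  labels <- vapply(combos, combo_label, character(1))

  runs <- vector("list", length(combos) * n_iter)
  rec <- vector("list", length(runs))
  skipped <- integer(length(combos))
  r <- 0L
  for (it in seq_len(n_iter)) {
    it_seed <- derive_seed(master_seed, it)
    idx <- draw_training_subset(m, pool_idx, size, it_seed, combos)
    for (ci in seq_along(combos)) {
      r <- r + 1L
      if (is.null(idx)) { skipped[ci] <- skipped[ci] + 1L; next }
      combo <- combos[[ci]]
      model <- ridge_cv_fit(m[idx, combo, drop = FALSE], y[idx],
                            k_folds = k_folds,
                            seed = derive_seed(master_seed, it, ci),
                            grid = grid, combo = combo)
      runs[[r]] <- structure(list(iteration = it, combo = combo,
                                  train_plot_ids = df$plot_id[idx],
                                  model = model, bic = model$bic),
                             class = "calibration_run")
      rec[[r]] <- data.frame(iteration = it, combo = labels[ci],
                             bic = model$bic, lambda = model$lambda,
                             r2_train = model$r2_train,
                             rmse_train = model$rmse_train,
                             stringsAsFactors = FALSE)
    }
  }
  if (any(skipped > 0.2 * n_iter)) {
    stop("combo(s) with > 20% skipped (degenerate) iterations: ",
         paste(labels[skipped > 0.2 * n_iter], collapse = ", "))
  }
  runs <- runs[!vapply(runs, is.null, logical(1))]
  run_df <- do.call(rbind, rec[!vapply(rec, is.null, logical(1))])
  rownames(run_df) <- NULL

  combo_summary <- do.call(rbind, lapply(seq_along(combos), function(ci) {
    b <- run_df$bic[run_df$combo == labels[ci]]
    data.frame(combo = labels[ci], n_traits = length(combos[[ci]]),
               n_runs = length(b),
               median_bic = sort(b)[lower_median_index(length(b))],
               mean_bic = mean(b),
               mean_r2_train = mean(run_df$r2_train[run_df$combo == labels[ci]]),
               mean_rmse_train = mean(run_df$rmse_train[run_df$combo == labels[ci]]),
               stringsAsFactors = FALSE)
  }))
  rownames(combo_summary) <- NULL
  ord <- order(combo_summary$median_bic, combo_summary$n_traits,
               seq_along(combos))
  best_ci <- ord[1]
  best_combo <- combos[[best_ci]]
  best_runs <- runs[vapply(runs, function(rn) identical(rn$combo, best_combo),
                           logical(1))]
  bics <- vapply(best_runs, function(rn) rn$bic, numeric(1))
  rep_run <- best_runs[[order(bics)[lower_median_index(length(bics))]]]

  structure(list(runs = run_df, models = runs, combo_summary = combo_summary,
                 best_combo = best_combo, representative_model = rep_run$model,
                 representative_run = rep_run, training_size = size,
                 n_iter = n_iter, master_seed = as.integer(master_seed),
                 n_skipped = stats::setNames(skipped, labels),
                 n_excluded_incomplete = n_excluded),
            class = "calibration_ensemble")
}

#' Extract a combination's representative (median-BIC) run from an ensemble
#'
#' @param ensemble a `calibration_ensemble`.
#' @param combo trait combination to extract (default the ensemble's best).
#' @return the `calibration_run` at that combination's lower-middle BIC.
#' @export
representative_run <- function(ensemble, combo = NULL) {
  stopifnot(inherits(ensemble, "calibration_ensemble"))
  if (is.null(combo)) return(ensemble$representative_run)
  hits <- ensemble$models[vapply(ensemble$models,
                                 function(rn) identical(rn$combo, combo),
                                 logical(1))]
  if (length(hits) == 0) stop("no runs for combo ", combo_label(combo))
  bics <- vapply(hits, function(rn) rn$bic, numeric(1))
  hits[[order(bics)[lower_median_index(length(bics))]]]
}

#' @export
print.calibration_ensemble <- function(x, ...) {
  cat(sprintf("calibration_ensemble: %d combos x %d iterations, size %d\n",
              nrow(x$combo_summary), x$n_iter, x$training_size))
  cs <- x$combo_summary[order(x$combo_summary$median_bic), ]
  print(utils::head(cs[, c("combo", "median_bic", "mean_bic", "mean_r2_train")], 5),
        row.names = FALSE)
  cat("best combo:", combo_label(x$best_combo), "\n")
  invisible(x)
}
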