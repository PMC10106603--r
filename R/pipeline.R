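# End-to-end case-study workflow: generate/ingest -> split -> calibrate ->
# select -> validate -> report.

#' Configure an end-to-end case-study run
#'
#' @param source either the name of a generator preset (see
#'   [default_configs()]) or a [trial_table].
#' @param split optional [split_scheme]; when NULL a preset-appropriate
#'   default is used (the replicated multi-experiment preset holds out the
#'   low-yielding experiment E1 and the high-yielding E5 as validation; the
#'   landrace/modern presets hold out a stratified 20 + 20 validation set).
#' @param candidate_traits traits searched over (default NDVI, PH, DH, EARS).
#' @param training_sizes training-subset sizes (default 20, 50, 100).
#' @param n_iter random subsets per combination and size (default 100).
#' @param k_folds CV folds for the ridge penalty (default 10).
#' @param saturation_threshold yield threshold, t/ha (default 8).
#' @param stratified_mode fit separate model ensembles below/above the
#'   threshold (default TRUE); otherwise one ensemble on all plots.
#' @param master_seed single master seed; all stochastic stages derive their
#'   seeds from it.
#' @param out_dir optional directory to write reports into.
#' @return an object of class `run_config`.
#' @export
run_config <- function(source = "case2_2021", split = NULL,
                       candidate_traits = CANDIDATE_TRAITS,
                       training_sizes = c(20, 50, 100), n_iter = 100,
                       k_folds = 10, saturation_threshold = 8,
                       stratified_mode = TRUE, master_seed = 1L,
                       out_dir = NULL) {
  if (!inherits(source, "trial_table") && !is.character(source)) {
    stop("source must be a trial_table or a preset name")
  }
  if (is.character(source) && !source %in% names(default_configs())) {
    stop("unknown preset '", source, "'; available: ",
         paste(names(default_configs()), collapse = ", "))
  }
  if (!is.null(split)) stopifnot(inherits(split, "split_scheme"))
  stopifnot(length(candidate_traits) >= 1,
            all(candidate_traits %in% TRAIT_COLUMNS),
            all(training_sizes >= 5), n_iter >= 1,
            saturation_threshold > 0)
  structure(list(source = source, split = split,
                 candidate_traits = candidate_traits,
                 training_sizes = sort(unique(training_sizes)),
                 n_iter = n_iter, k_folds = k_folds,
                 saturation_threshold = saturation_threshold,
                 stratified_mode = isTRUE(stratified_mode),
                 master_seed = as.integer(master_seed), out_dir = out_dir),
            class = "run_config")
}

default_split_for <- function(table, source_name, seed) {
  exps <- unique(table$experiment_id[!is.na(table$experiment_id)])
  if (length(exps) > 2 && all(c("E1", "E5") %in% exps)) {
    split_scheme("by_experiment",
                 train_experiments = setdiff(exps, c("E1", "E5")),
                 validation_experiments = c("E1", "E5"), seed = seed)
  } else if (all(c("landrace", "modern") %in% table$germplasm_class)) {
    split_scheme("stratified_random",
                 strata_sizes = c(landrace = 20, modern = 20), seed = seed)
  } else {
    split_scheme("random_n",
                 train_size = max(5, floor(0.8 * nrow(table))), seed = seed)
  }
}

#' Run a full case study: calibrate, select, validate, report
#'
#' The workflow: obtain the plot table (generating it from a preset when
#' `source` names one), split into a training pool and validation set(s),
#' run the repeated-random-subset calibration of every trait combination at
#' every training size (separately below/above the saturation threshold when
#' `stratified_mode`), select the best combination and a representative
#' median-BIC model per ensemble, validate it against the NDVI-only
#' benchmark on the matching validation plots, and report the stratified
#' NDVI-yield correlations plus per-experiment heritability where trials are
#' replicated. All randomness derives from `master_seed`; identical configs
#' give identical results.
#'
#' @param config a [run_config()].
#' @return an object of class `case_study_result`: `table_summary`,
#'   `split_sizes`, `saturation`, `heritability`, and `ensembles` (one entry
#'   per stratum x size with `combo_summary`, `best_combo`,
#'   `representative_model`, `best_metrics`, `benchmark_metrics`,
#'   `comparison`). When `config$out_dir` is set the reports are also
#'   written there as JSON/CSV.
#' @export
run_case_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$master_seed

  table <- if (is.character(config$source)) {
    gc <- default_configs()[[config$source]]
    gc$seed <- derive_seed(seed, 101)
    generate_trial(gc)
  } else {
    config$source
  }

  scheme <- config$split %||% default_split_for(
    table, if (is.character(config$source)) config$source else "",
    seed = derive_seed(seed, 102))
  sp <- split_train_validation(table, scheme)

  sat <- saturation_scan(table, config$saturation_threshold)

  herit <- tryCatch({
    reps <- vapply(split(as.data.frame(table), table$experiment_id),
                   function(s) length(unique(table(s$genotype_id))) == 1 &&
                     min(table(s$genotype_id)) >= 2, logical(1))
    if (!any(reps)) NULL else do.call(rbind, lapply(names(reps)[reps], function(e) {
      sub <- new_trial_subset(as.data.frame(table)[table$experiment_id == e, ])
      # truncation of a negative genotypic variance is visible as sigma2_g = 0
      cbind(experiment_id = e, suppressWarnings(heritability_summary(sub, "gy")))
    }))
  }, error = function(e) NULL)

  strata <- if (config$stratified_mode) {
    tr <- stratify_by_yield(sp$train, config$saturation_threshold)
    va <- stratify_by_yield(sp$validation, config$saturation_threshold)
    list(below = list(train = tr$below, validation = va$below),
         above = list(train = tr$above, validation = va$above))
  } else {
    list(all = list(train = sp$train, validation = sp$validation))
  }

  combos <- enumerate_models(config$candidate_traits)
  benchmark_combo <- "ndvi"
  ensembles <- list()
  si <- 0L
  for (stratum in names(strata)) {
    si <- si + 1L
    pool <- strata[[stratum]]$train
    valid <- strata[[stratum]]$validation
    for (size in config$training_sizes) {
      key <- sprintf("%s_size%d", stratum, size)
      n_complete <- sum(stats::complete.cases(
        as.data.frame(pool)[, c(config$candidate_traits, "gy"), drop = FALSE]))
      if (n_complete < size) {
        ensembles[[key]] <- list(stratum = stratum, size = size,
                                 skipped = TRUE,
                                 reason = sprintf("pool has %d complete plots < size %d",
                                                  n_complete, size))
        next
      }
      ens <- run_calibration(pool, combos, size = size, n_iter = config$n_iter,
                             master_seed = derive_seed(seed, si, size),
                             k_folds = config$k_folds)
      best_model <- ens$representative_model
      bench_model <- representative_run(ens, benchmark_combo)$model
      entry <- list(stratum = stratum, size = size, skipped = FALSE,
                    combo_summary = ens$combo_summary,
                    best_combo = ens$best_combo,
                    representative_model = best_model,
                    benchmark_model = bench_model,
                    runs = ens$runs)
      n_val_ok <- sum(stats::complete.cases(
        as.data.frame(valid)[, c(config$candidate_traits, "gy"), drop = FALSE]))
      if (n_val_ok >= 3) {
        entry$best_metrics <- evaluate_model(best_model, valid)
        entry$benchmark_metrics <- evaluate_model(bench_model, valid)
        entry$comparison <- compare_metrics(entry$best_metrics,
                                            entry$benchmark_metrics)
      } else {
        entry$validation_note <- sprintf(
          "only %d complete validation plots; metrics skipped", n_val_ok)
      }
      ensembles[[key]] <- entry
    }
  }

  result <- structure(list(
    config = config[setdiff(names(config), "source")],
    source = if (is.character(config$source)) config$source else "user table",
    table_summary = list(
      n_plots = nrow(table),
      gy_mean = mean(table$gy), gy_sd = stats::sd(table$gy),
      experiments = sort(unique(table$experiment_id))),
    split_sizes = c(train = nrow(sp$train),
                    validation = nrow(sp$validation)),
    saturation = sat, heritability = herit, ensembles = ensembles,
    master_seed = seed
  ), class = "case_study_result")

  if (!is.null(config$out_dir)) write_result_bundle(result, config$out_dir)
  result
}

#' Serialize a case-study result to a canonical JSON string
#'
#' Used both for reporting and for verifying end-to-end reproducibility
#' (identical seeds give byte-identical strings). Full run tables are
#' omitted; combination summaries, selected models and metrics are kept.
#'
#' @param result a `case_study_result`.
#' @return a JSON string.
#' @export
result_to_json <- function(result) {
  stopifnot(inherits(result, "case_study_result"))
  slim <- result
  slim$ensembles <- lapply(result$ensembles, function(e) {
    if (isTRUE(e$skipped)) return(e[c("stratum", "size", "skipped", "reason")])
    list(stratum = e$stratum, size = e$size,
         best_combo = e$best_combo,
         combo_summary = e$combo_summary,
         representative_model = e$representative_model[
           c("combo", "coefficients", "intercept", "lambda", "n_train",
             "rss", "edf", "bic")],
         best_metrics = unclass(e$best_metrics %||% NULL),
         benchmark_metrics = unclass(e$benchmark_metrics %||% NULL),
         delta_r2_relative = e$comparison$delta_r2_relative %||% NULL,
         delta_rmse_relative = e$comparison$delta_rmse_relative %||% NULL)
  })
  slim$config <- unclass(slim$config)
  slim$config$split <- if (is.null(slim$config$split)) NULL else unclass(slim$config$split)
  slim$saturation <- as.data.frame(slim$saturation)
  as.character(jsonlite::toJSON(unclass(slim), digits = 10, auto_unbox = TRUE,
                                pretty = TRUE, null = "null"))
}

#' Write a case-study result bundle to disk
#'
#' Writes `result.json` (the canonical summary), `saturation.csv`,
#' `heritability.csv` (when available) and one `runs_<stratum>_<size>.csv`
#' per ensemble.
#'
#' @param result a `case_study_result`.
#' @param out_dir output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_result_bundle <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(result_to_json(result), file.path(out_dir, "result.json"))
  utils::write.csv(as.data.frame(result$saturation),
                   file.path(out_dir, "saturation.csv"), row.names = FALSE)
  if (!is.null(result$heritability)) {
    utils::write.csv(result$heritability,
                     file.path(out_dir, "heritability.csv"), row.names = FALSE)
  }
  for (key in names(result$ensembles)) {
    e <- result$ensembles[[key]]
    if (!isTRUE(e$skipped)) {
      utils::write.csv(e$runs, file.path(out_dir, sprintf("runs_%s.csv", key)),
                       row.names = FALSE)
    }
  }
  invisible(out_dir)
}

#' @export
print.case_study_result <- function(x, ...) {
  cat(sprintf("case_study_result: %s, %d plots (train %d / validation %d), seed %d\n",
              x$source, x$table_summary$n_plots, x$split_sizes["train"],
              x$split_sizes["validation"], x$master_seed))
  cat(sprintf("saturation at %g t/ha: r2 below %.3f, above %.3f\n",
              x$saturation$threshold[1], x$saturation$r2_below[1],
              x$saturation$r2_above[1]))
  for (key in names(x$ensembles)) {
    e <- x$ensembles[[key]]
    if (isTRUE(e$skipped)) {
      cat(sprintf("  %s: skipped (%s)\n", key, e$reason))
    } else if (!is.null(e$best_metrics)) {
      cat(sprintf("  %s: best %s | val R2 %.3f RMSE %.3f vs NDVI R2 %.3f RMSE %.3f\n",
                  key, combo_label(e$best_combo), e$best_metrics$r2,
                  e$best_metrics$rmse, e$benchmark_metrics$r2,
                  e$benchmark_metrics$rmse))
    } else {
      cat(sprintf("  %s: best %s (validation metrics unavailable)\n",
                  key, combo_label(e$best_combo)))
    }
  }
  invisible(x)
}
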