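# NDVI saturation analysis: stratify plots at a yield threshold and compare
# the NDVI-yield relationship below vs above it.

#' Stratify a trial table at a yield threshold
#'
#' Plots with `gy < threshold` go to the "below" stratum, plots with
#' `gy >= threshold` to "above" (boundary plots are assigned above, a pinned
#' convention). The two strata partition the input.
#'
#' @param table a [trial_table].
#' @param threshold yield threshold in t/ha (default 8).
#' @return `list(below = trial_table, above = trial_table)`.
#' @export
stratify_by_yield <- function(table, threshold = 8) {
  stopifnot(inherits(table, "trial_table"), threshold > 0)
  df <- as.data.frame(table)
  prov <- attr(table, "provenance") %||% ""
  mk <- function(idx, tag) {
    new_trial_subset(df[idx, , drop = FALSE],
                     provenance = if (nzchar(prov)) paste0(prov, ":", tag) else tag)
  }
  list(below = mk(which(df$gy < threshold), sprintf("gy<%g", threshold)),
       above = mk(which(df$gy >= threshold), sprintf("gy>=%g", threshold)))
}

#' Quantify the NDVI-yield relationship below and above yield thresholds
#'
#' For each threshold, plots with both NDVI and grain yield present are
#' stratified and the squared Pearson correlation between NDVI and yield is
#' computed within each stratum. Strata with fewer than 3 plots (or with a
#' constant trait) are flagged insufficient rather than failing.
#'
#' @param table a [trial_table] with NDVI values.
#' @param thresholds numeric vector of yield thresholds in t/ha (default 8).
#' @return a data.frame of class `saturation_report` with columns
#'   `threshold`, `n_below`, `n_above`, `r2_below`, `p_below`, `r2_above`,
#'   `p_above`, `sufficient_below`, `sufficient_above`.
#' @export
saturation_scan <- function(table, thresholds = 8) {
  stopifnot(inherits(table, "trial_table"), length(thresholds) >= 1,
            all(thresholds > 0))
  df <- as.data.frame(table)
  df <- df[!is.na(df$ndvi) & !is.na(df$gy), , drop = FALSE]
  if (nrow(df) == 0) stop("no plots with both ndvi and gy present")
  one <- function(thr) {
    below <- df$gy < thr
    stratum <- function(sel) {
      sub <- df[sel, , drop = FALSE]
      ok <- nrow(sub) >= 3 && stats::sd(sub$ndvi) > 0 && stats::sd(sub$gy) > 0
      if (!ok) return(list(n = nrow(sub), r2 = NA_real_, p = NA_real_, ok = FALSE))
      pr <- pearson_r2(sub$ndvi, sub$gy)
      list(n = nrow(sub), r2 = pr$r2, p = pr$p_value, ok = TRUE)
    }
    lo <- stratum(below); hi <- stratum(!below)
    data.frame(threshold = thr, n_below = lo$n, n_above = hi$n,
               r2_below = lo$r2, p_below = lo$p,
               r2_above = hi$r2, p_above = hi$p,
               sufficient_below = lo$ok, sufficient_above = hi$ok)
  }
  out <- do.call(rbind, lapply(thresholds, one))
  rownames(out) <- NULL
  class(out) <- c("saturation_report", "data.frame")
  out
}
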