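# Plot-level trial table: the central data container of the package.

TRIAL_COLUMNS <- c(
  "plot_id", "genotype_id", "germplasm_class", "experiment_id",
  "water_regime", "sowing_date", "replicate", "gy", "ndvi", "dh", "ph", "ears"
)
TRAIT_COLUMNS <- c("gy", "ndvi", "dh", "ph", "ears")
GERMPLASM_CLASSES <- c("landrace", "modern")
WATER_REGIMES <- c("rainfed", "irrigated")

#' Construct a validated plot-level trial table
#'
#' One row per experimental plot: identifiers, design factors and measured
#' traits. Mandatory columns are `plot_id` and `gy` (grain yield, t/ha at 12%
#' moisture); optional traits are `ndvi` (dimensionless, in `[0, 1]`), `dh`
#' (days from sowing to 50% spike emergence), `ph` (plant height, cm) and
#' `ears` (ears per square metre). Missing values are `NA` ("absent").
#'
#' @param df data.frame with at least `plot_id` and `gy` columns; any of the
#'   canonical columns `genotype_id`, `germplasm_class`, `experiment_id`,
#'   `water_regime`, `sowing_date`, `replicate`, `ndvi`, `dh`, `ph`, `ears`
#'   are used when present, all others are dropped.
#' @param provenance free-text source tag stored as an attribute.
#' @return an object of class `trial_table` (a data.frame with the canonical
#'   columns in canonical order).
#' @examples
#' tt <- trial_table(data.frame(plot_id = c("p1", "p2"), gy = c(5.2, 8.1),
#'                              ndvi = c(0.61, 0.78)))
#' n_plots(tt)
#' @export
trial_table <- function(df, provenance = "") {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_mand <- setdiff(c("plot_id", "gy"), names(df))
  if (length(missing_mand) > 0) {
    stop("missing mandatory column(s): ", paste(missing_mand, collapse = ", "))
  }
  out <- data.frame(row.names = seq_len(nrow(df)))
  for (col in TRIAL_COLUMNS) {
    out[[col]] <- if (col %in% names(df)) df[[col]] else rep(NA, nrow(df))
  }
  out$plot_id <- as.character(out$plot_id)
  out$genotype_id <- as.character(out$genotype_id)
  out$germplasm_class <- as.character(out$germplasm_class)
  out$experiment_id <- as.character(out$experiment_id)
  out$water_regime <- as.character(out$water_regime)
  out$sowing_date <- parse_trial_date(out$sowing_date)
  out$replicate <- suppressWarnings(as.integer(out$replicate))
  for (tr in TRAIT_COLUMNS) out[[tr]] <- as.numeric(out[[tr]])
  validate_trial_records(out)
  structure(out,
    class = c("trial_table", "data.frame"),
    provenance = as.character(provenance)
  )
}

# Row-indexed invariant checks shared by the constructor and the reader.
validate_trial_records <- function(df, allow_empty = FALSE) {
  if (nrow(df) == 0) {
    if (allow_empty) return(invisible(TRUE))
    stop("trial table must contain at least one plot")
  }
  bad_row <- function(ok, col, rule) {
    bad <- which(!ok)
    if (length(bad) > 0) {
      stop(sprintf(
        "invalid %s in row(s) %s: %s", col,
        paste(utils::head(bad, 5), collapse = ", "), rule
      ))
    }
  }
  if (anyNA(df$plot_id) || any(df$plot_id == "")) {
    bad_row(!is.na(df$plot_id) & df$plot_id != "", "plot_id", "must be non-empty")
  }
  dup <- duplicated(df$plot_id)
  if (any(dup)) {
    stop("duplicated plot_id in row(s) ",
         paste(which(dup), collapse = ", "), ": plot_id must be unique")
  }
  bad_row(!is.na(df$gy) & is.finite(df$gy) & df$gy >= 0, "gy",
          "grain yield must be a finite number >= 0")
  ok_opt <- function(x, test) is.na(x) | test(x)
  bad_row(ok_opt(df$ndvi, function(x) is.finite(x) & x >= 0 & x <= 1),
          "ndvi", "must lie in [0, 1]")
  bad_row(ok_opt(df$dh, function(x) is.finite(x) & x > 0), "dh", "must be > 0")
  bad_row(ok_opt(df$ph, function(x) is.finite(x) & x > 0), "ph", "must be > 0")
  bad_row(ok_opt(df$ears, function(x) is.finite(x) & x > 0), "ears", "must be > 0")
  bad_row(ok_opt(df$replicate, function(x) x >= 1), "replicate",
          "must be a positive integer")
  cls <- df$germplasm_class
  bad_row(is.na(cls) | cls %in% GERMPLASM_CLASSES, "germplasm_class",
          paste("must be one of:", paste(GERMPLASM_CLASSES, collapse = ", ")))
  wr <- df$water_regime
  bad_row(is.na(wr) | wr %in% WATER_REGIMES, "water_regime",
          paste("must be one of:", paste(WATER_REGIMES, collapse = ", ")))
  invisible(TRUE)
}

# Internal constructor for subsets that may legitimately be empty
# (e.g. the validation half of a boundary split).
new_trial_subset <- function(df, provenance = "") {
  validate_trial_records(df, allow_empty = TRUE)
  rownames(df) <- NULL
  structure(as.data.frame(df),
    class = c("trial_table", "data.frame"),
    provenance = as.character(provenance)
  )
}

parse_trial_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  out <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  nz <- !is.na(x) & x != ""
  if (!any(nz)) return(out)
  iso <- as.Date(x[nz], format = "%Y-%m-%d")
  dmy <- as.Date(x[nz], format = "%d/%m/%Y")
  got <- ifelse(!is.na(iso), as.numeric(iso), as.numeric(dmy))
  if (anyNA(got)) {
    stop("unparseable sowing_date in row(s) ",
         paste(utils::head(which(nz)[is.na(got)], 5), collapse = ", "),
         ": use ISO-8601 (yyyy-mm-dd) or dd/mm/yyyy")
  }
  out[nz] <- as.Date(got, origin = "1970-01-01")
  out
}

#' Number of plots in a trial table
#' @param table a `trial_table`.
#' @return integer plot count.
#' @export
n_plots <- function(table) nrow(table)

#' Count present (non-missing) values of a trait
#'
#' @param table a `trial_table`.
#' @param trait one of `"gy"`, `"ndvi"`, `"dh"`, `"ph"`, `"ears"`.
#' @return integer count of plots where the trait is present.
#' @export
trait_completeness <- function(table, trait) {
  trait <- match.arg(trait, TRAIT_COLUMNS)
  sum(!is.na(table[[trait]]))
}

#' @export
print.trial_table <- function(x, ...) {
  cat(sprintf("trial_table: %d plots", nrow(x)))
  prov <- attr(x, "provenance")
  if (!is.null(prov) && nzchar(prov)) cat(sprintf(" [%s]", prov))
  cat("\n")
  for (tr in TRAIT_COLUMNS) {
    n <- sum(!is.na(x[[tr]]))
    if (n > 0) {
      cat(sprintf("  %-5s n=%d  mean=%.3f  range=[%.3f, %.3f]\n",
                  tr, n, mean(x[[tr]], na.rm = TRUE),
                  min(x[[tr]], na.rm = TRUE), max(x[[tr]], na.rm = TRUE)))
    }
  }
  invisible(x)
}
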