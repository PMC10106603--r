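# CSV ingestion and export of plot-level trial tables.
#
# Canonical dialect: comma-separated, header row, UTF-8, period decimal
# separator, empty cell <=> absent value. A column-name mapping absorbs
# other headers.

#' Read a plot-level trial table from CSV
#'
#' @param path path to a CSV file with one row per plot.
#' @param dialect optional named character vector mapping canonical column
#'   names to the file's header names, e.g.
#'   `c(gy = "GY", ndvi = "NDVI_anthesis")`. Unmapped canonical names are
#'   matched case-insensitively against the file header.
#' @return a validated [trial_table]. Rows violating trait invariants abort
#'   the read with a row-indexed diagnostic; empty cells become `NA`.
#' @export
read_trial_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  hdr <- names(raw)
  resolve <- function(canon) {
    if (!is.null(dialect) && canon %in% names(dialect)) {
      nm <- dialect[[canon]]
      if (!nm %in% hdr) stop("dialect maps '", canon, "' to missing column '", nm, "'")
      return(nm)
    }
    hit <- hdr[tolower(hdr) == canon]
    if (length(hit) >= 1) hit[1] else NA_character_
  }
  cols <- vapply(TRIAL_COLUMNS, resolve, character(1))
  for (mand in c("plot_id", "gy")) {
    if (is.na(cols[[mand]])) stop("missing mandatory column: ", mand)
  }
  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (canon in TRIAL_COLUMNS) {
    src <- cols[[canon]]
    x <- if (is.na(src)) rep(NA_character_, nrow(raw)) else raw[[src]]
    x[!is.na(x) & trimws(x) == ""] <- NA_character_
    if (canon %in% c(TRAIT_COLUMNS, "replicate")) {
      num <- suppressWarnings(as.numeric(x))
      bad <- which(!is.na(x) & is.na(num))
      if (length(bad) > 0) {
        stop(sprintf("unparseable numeric cell in column '%s', row(s) %s",
                     canon, paste(utils::head(bad, 5), collapse = ", ")))
      }
      df[[canon]] <- num
    } else {
      df[[canon]] <- x
    }
  }
  trial_table(df, provenance = path)
}

#' Write a trial table to CSV
#'
#' Values round-trip exactly: numerics are printed with 17 significant
#' digits, absent values as empty cells (never sentinel numbers), dates as
#' ISO-8601. `read_trial_table(write_trial_table(t))` reproduces `t`.
#'
#' @param table a `trial_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(table, path) {
  stopifnot(inherits(table, "trial_table"))
  out <- as.data.frame(table)
  for (col in c(TRAIT_COLUMNS)) {
    out[[col]] <- ifelse(is.na(out[[col]]), "", sprintf("%.17g", out[[col]]))
  }
  out$replicate <- ifelse(is.na(out$replicate), "", as.character(out$replicate))
  out$sowing_date <- ifelse(is.na(out$sowing_date), "",
                            format(out$sowing_date, "%Y-%m-%d"))
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) stop("cannot write to '", path, "': ", conditionMessage(e)))
  invisible(path)
}
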