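# Deterministic train/validation splitting schemes.

#' Define a train/validation splitting scheme
#'
#' Three designs are supported:
#' \describe{
#'   \item{`random_n`}{draw `train_size` plots at random for the training
#'     set; the remainder is the validation set.}
#'   \item{`stratified_random`}{draw `strata_sizes[class]` plots per
#'     germplasm class at random for the \emph{validation} set; the remainder
#'     is the training pool. This is the case-study-1 convention (40
#'     validation plots: 20 landraces and 20 modern varieties).}
#'   \item{`by_experiment`}{assign whole experiments to train and validation
#'     by id; the two sets must be disjoint.}
#' }
#'
#' @param kind one of `"random_n"`, `"stratified_random"`, `"by_experiment"`.
#' @param train_size training-set size (for `random_n`).
#' @param strata_sizes named integer vector, germplasm class -> validation
#'   count (for `stratified_random`).
#' @param train_experiments,validation_experiments experiment-id sets (for
#'   `by_experiment`).
#' @param seed integer seed; identical seed gives an identical split.
#' @return an object of class `split_scheme`.
#' @export
split_scheme <- function(kind = c("random_n", "stratified_random", "by_experiment"),
                         train_size = NULL, strata_sizes = NULL,
                         train_experiments = NULL, validation_experiments = NULL,
                         seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "random_n") {
    stopifnot(is.numeric(train_size), length(train_size) == 1, train_size >= 1)
  } else if (kind == "stratified_random") {
    stopifnot(is.numeric(strata_sizes), length(strata_sizes) >= 1,
              !is.null(names(strata_sizes)), all(strata_sizes >= 1))
  } else {
    stopifnot(length(train_experiments) >= 1, length(validation_experiments) >= 1)
    if (length(intersect(train_experiments, validation_experiments)) > 0) {
      stop("train and validation experiment sets must be disjoint")
    }
  }
  structure(list(kind = kind, train_size = train_size,
                 strata_sizes = strata_sizes,
                 train_experiments = train_experiments,
                 validation_experiments = validation_experiments,
                 seed = as.integer(seed)),
            class = "split_scheme")
}

#' Split a trial table into training and validation sets
#'
#' The two sets are disjoint and (for the random schemes) partition the
#' table. Splits are deterministic given `(table, scheme)`; the input table
#' is never modified.
#'
#' @param table a [trial_table].
#' @param scheme a [split_scheme].
#' @return `list(train = trial_table, validation = trial_table)`.
#' @export
split_train_validation <- function(table, scheme) {
  stopifnot(inherits(table, "trial_table"), inherits(scheme, "split_scheme"))
  n <- nrow(table)
  prov <- attr(table, "provenance") %||% ""
  take <- function(idx, tag) {
    new_trial_subset(as.data.frame(table)[idx, , drop = FALSE],
                     provenance = if (nzchar(prov)) paste0(prov, ":", tag) else tag)
  }
  if (scheme$kind == "random_n") {
    if (scheme$train_size > n) {
      stop("requested train_size (", scheme$train_size,
           ") exceeds available plots (", n, ")")
    }
    idx <- with_seed(scheme$seed, sort(sample.int(n, scheme$train_size)))
    return(list(train = take(idx, "train"),
                validation = take(setdiff(seq_len(n), idx), "validation")))
  }
  if (scheme$kind == "stratified_random") {
    cls <- table$germplasm_class
    val_idx <- integer(0)
    with_seed(scheme$seed, {
      for (k in names(scheme$strata_sizes)) {
        pool <- which(!is.na(cls) & cls == k)
        need <- scheme$strata_sizes[[k]]
        if (need > length(pool)) {
          stop("stratum '", k, "' requests ", need, " plots but only ",
               length(pool), " available")
        }
        val_idx <- c(val_idx, sample(pool, need))
      }
    })
    val_idx <- sort(val_idx)
    return(list(train = take(setdiff(seq_len(n), val_idx), "train_pool"),
                validation = take(val_idx, "validation")))
  }
  # by_experiment
  exps <- unique(table$experiment_id[!is.na(table$experiment_id)])
  unknown <- setdiff(c(scheme$train_experiments, scheme$validation_experiments), exps)
  if (length(unknown) > 0) {
    stop("unknown experiment id(s): ", paste(unknown, collapse = ", "))
  }
  tr <- which(table$experiment_id %in% scheme$train_experiments)
  va <- which(table$experiment_id %in% scheme$validation_experiments)
  list(train = take(tr, "train"), validation = take(va, "validation"))
}

#' Export a split as a single CSV with a `set` column
#'
#' @param split a list as returned by [split_train_validation].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_split <- function(split, path) {
  a <- as.data.frame(split$train); a$set <- "train_pool"
  b <- as.data.frame(split$validation); b$set <- "validation"
  out <- rbind(a, b)
  out$sowing_date <- ifelse(is.na(out$sowing_date), "",
                            format(out$sowing_date, "%Y-%m-%d"))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
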