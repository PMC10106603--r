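# Broad-sense heritability from balanced replicated trials, by one-way
# ANOVA method of moments.

#' Estimate genotypic and error variance components
#'
#' One-way ANOVA method of moments on a balanced replicated trial: the error
#' variance is the within-genotype mean square, and the genotypic variance is
#' `(MS_genotype - MS_error) / r`, truncated at zero (with a warning) when
#' negative. Unbalanced replication is an error, not an approximation: the
#' heritability formula presumes a single replicate count `r`.
#'
#' @param trial a [trial_table] with `genotype_id` and the trait present for
#'   every plot used; at least 2 genotypes, each with the same number
#'   `r >= 2` of replicates.
#' @param trait trait column to analyse (default `"gy"`).
#' @return an object of class `variance_components`: `sigma2_g`, `sigma2_e`
#'   ((t/ha)^2 for yield), `r`, `n_genotypes`, `trait`.
#' @export
variance_components <- function(trial, trait = "gy") {
  stopifnot(inherits(trial, "trial_table"))
  trait <- match.arg(trait, TRAIT_COLUMNS)
  df <- as.data.frame(trial)
  df <- df[!is.na(df[[trait]]) & !is.na(df$genotype_id), , drop = FALSE]
  counts <- table(df$genotype_id)
  if (length(counts) < 2) stop("need at least 2 genotypes")
  if (length(unique(counts)) != 1) {
    stop("unbalanced replication: genotypes have differing replicate counts (",
         paste(range(counts), collapse = "-"), ")")
  }
  r <- unname(counts[1])
  if (r < 2) stop("heritability requires replicated trials (r >= 2), got r = ", r)
  fit <- stats::lm(df[[trait]] ~ factor(df$genotype_id))
  an <- suppressWarnings(stats::anova(fit)) # perfect fits warn about F-tests
  msg <- an[["Mean Sq"]][1]
  mse <- an[["Mean Sq"]][2]
  # snap floating-point residue of exact fits to zero
  tol <- 1e-12 * (1 + mean(df[[trait]])^2)
  if (msg < tol) msg <- 0
  if (mse < tol) mse <- 0
  sigma2_g <- (msg - mse) / r
  if (sigma2_g < 0) {
    warning("negative genotypic variance estimate truncated to 0")
    sigma2_g <- 0
  }
  structure(list(sigma2_g = sigma2_g, sigma2_e = mse, r = as.integer(r),
                 n_genotypes = length(counts), trait = trait),
            class = "variance_components")
}

#' Broad-sense heritability from variance components
#'
#' `H^2 = sigma2_g / (sigma2_g + sigma2_e / r)`: the fraction of the
#' variance of genotype means attributable to genotype.
#'
#' @param vc a `variance_components` object (or a list with `sigma2_g`,
#'   `sigma2_e`, `r`).
#' @return heritability in `[0, 1]`.
#' @export
broad_sense_h2 <- function(vc) {
  stopifnot(is.list(vc), all(c("sigma2_g", "sigma2_e", "r") %in% names(vc)))
  if (vc$sigma2_g < 0 || vc$sigma2_e < 0 || vc$r < 1) {
    stop("invalid variance components")
  }
  if (vc$sigma2_g == 0 && vc$sigma2_e == 0) {
    stop("H2 undefined: both variance components are zero")
  }
  vc$sigma2_g / (vc$sigma2_g + vc$sigma2_e / vc$r)
}

#' Per-trait heritability summary of a replicated trial
#'
#' @param trial a [trial_table] with balanced genotype replication.
#' @param traits trait columns to summarize (those present are used).
#' @return data.frame with columns `trait`, `sigma2_g`, `sigma2_e`, `r`,
#'   `n_genotypes`, `h2`.
#' @export
heritability_summary <- function(trial, traits = TRAIT_COLUMNS) {
  rows <- lapply(traits, function(tr) {
    if (trait_completeness(trial, tr) == 0) return(NULL)
    vc <- variance_components(trial, tr)
    data.frame(trait = tr, sigma2_g = vc$sigma2_g, sigma2_e = vc$sigma2_e,
               r = vc$r, n_genotypes = vc$n_genotypes,
               h2 = if (vc$sigma2_g == 0 && vc$sigma2_e == 0) NA_real_
                    else broad_sense_h2(vc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
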