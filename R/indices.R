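# NDVI from plot-aggregated band reflectances.

#' Compute NDVI from red and near-infrared reflectances
#'
#' NDVI = (NIR - red) / (NIR + red), the normalized difference vegetation
#' index, computed elementwise from plot-mean band reflectances (nominal
#' band centres 660/668 nm red, 790/840 nm NIR; band-centre differences
#' between cameras are ignored). Output lies in `[-1, 1]`.
#'
#' @param r_red,r_nir non-negative reflectance vectors of equal length.
#' @return numeric vector of NDVI values.
#' @examples
#' compute_ndvi(0.05, 0.79) # 0.74 / 0.84
#' @export
compute_ndvi <- function(r_red, r_nir) {
  if (length(r_red) != length(r_nir)) {
    stop("r_red and r_nir must have equal length")
  }
  if (anyNA(r_red) || anyNA(r_nir) || !all(is.finite(r_red), is.finite(r_nir))) {
    stop("reflectances must be finite and non-missing")
  }
  if (any(r_red < 0) || any(r_nir < 0)) {
    stop("reflectances must be >= 0 (element ",
         paste(utils::head(which(r_red < 0 | r_nir < 0), 5), collapse = ", "), ")")
  }
  denom <- r_nir + r_red
  if (any(denom == 0)) {
    stop("NDVI undefined where both bands are zero (element ",
         paste(utils::head(which(denom == 0), 5), collapse = ", "), ")")
  }
  (r_nir - r_red) / denom
}

#' Compute per-plot NDVI from a reflectance CSV
#'
#' Reads a CSV with columns `plot_id`, `r_red`, `r_nir` (plot-mean band
#' reflectances) and returns (optionally writes) a `plot_id`, `ndvi` table.
#'
#' @param path input CSV path.
#' @param out optional output CSV path.
#' @return data.frame with columns `plot_id` and `ndvi`, invisibly when
#'   `out` is given.
#' @export
ndvi_from_reflectance_csv <- function(path, out = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "r_red", "r_nir")
  miss <- setdiff(need, tolower(names(df)))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  names(df) <- tolower(names(df))
  res <- data.frame(plot_id = as.character(df$plot_id),
                    ndvi = compute_ndvi(as.numeric(df$r_red), as.numeric(df$r_nir)),
                    stringsAsFactors = FALSE)
  if (!is.null(out)) {
    utils::write.csv(res, out, row.names = FALSE)
    return(invisible(res))
  }
  res
}
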