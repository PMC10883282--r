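#' Remove decoy and contaminant features
#'
#' Drops rows flagged as reverse-database hits or contaminants; the relative
#' order of the remaining rows is preserved.
#'
#' @param x an `abundance_matrix`.
#' @param is_reverse,is_contaminant logical vectors aligned to the feature
#'   rows of `x`.
#' @return a filtered `abundance_matrix`.
#' @export
filter_decoys_contaminants <- function(x, is_reverse, is_contaminant) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (length(is_reverse) != nrow(x$values) ||
      length(is_contaminant) != nrow(x$values))
    stop("flag vectors must align with the feature rows")
  keep <- !(is_reverse | is_contaminant)
  if (!any(keep)) warning("all features flagged; returning an empty matrix")
  abundance_matrix(x$values[keep, , drop = FALSE], scale = x$scale)
}

#' Median-centre samples to the grand median
#'
#' Each sample (column) is shifted additively on the log10 scale so that its
#' median over observed values equals the grand median of all observed values
#' of the input matrix. This corrects for different loading amounts while
#' leaving within-sample structure untouched. The operation is idempotent.
#'
#' @param x an `abundance_matrix` on the log10 scale.
#' @return a median-centred `abundance_matrix`.
#' @export
median_center <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (x$scale != "log10")
    stop("median_center expects a log10-scale matrix")
  vals <- x$values
  n_obs <- colSums(!is.na(vals))
  if (any(n_obs == 0L))
    stop("sample(s) with no observed values: ",
         paste(colnames(vals)[n_obs == 0L], collapse = ", "))
  grand <- stats::median(vals, na.rm = TRUE)
  med <- apply(vals, 2L, stats::median, na.rm = TRUE)
  shifted <- sweep(vals, 2L, med - grand, `-`)
  abundance_matrix(shifted, scale = "log10")
}

#' Row-wise half-minimum imputation
#'
#' Each missing cell of a feature row is set to the log10 of half the lowest
#' observed *linear* intensity of that row (halving is a linear-scale notion;
#' on the log10 scale the imputed value is `min(row) - log10(2)`). Observed
#' values are never altered. Rows with no observed value are left missing and
#' listed in the `fully_missing` attribute.
#'
#' @param x an `abundance_matrix` on the log10 scale.
#' @return an imputed `abundance_matrix`; attribute `fully_missing` holds the
#'   ids of rows that could not be imputed.
#' @export
impute_half_min_rowwise <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (x$scale != "log10")
    stop("impute_half_min_rowwise expects a log10-scale matrix")
  vals <- x$values
  row_min <- suppressWarnings(apply(vals, 1L, min, na.rm = TRUE))
  fully_missing <- !is.finite(row_min)
  fill <- row_min - log10(2)
  idx <- which(is.na(vals) & !fully_missing, arr.ind = TRUE)
  if (nrow(idx)) vals[idx] <- fill[idx[, 1L]]
  out <- abundance_matrix(vals, scale = "log10")
  attr(out, "fully_missing") <- rownames(x$values)[fully_missing]
  out
}

#' Standard post-processing chain
#'
#' Convenience wrapper: log10-transform (if needed), median-centre, and
#' optionally impute by the row-wise half-minimum rule.
#'
#' @param x an `abundance_matrix` (linear or log10).
#' @param impute impute missing values after centring? (default `TRUE`)
#' @return a processed log10-scale `abundance_matrix`.
#' @export
preprocess_matrix <- function(x, impute = TRUE) {
  x <- median_center(to_log10(x))
  if (impute) x <- impute_half_min_rowwise(x)
  x
}
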