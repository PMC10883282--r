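#' Abundance matrix container
#'
#' A thin S3 wrapper around a numeric features x samples matrix with an
#' explicit scale tag. Missing measurements are `NA`; on the linear scale a
#' raw intensity of 0 is treated as "not detected" and therefore stored as
#' `NA` (search-engine output tables use 0 for non-detection, and downstream
#' half-minimum imputation must not treat 0 as an observation).
#'
#' @param values numeric matrix (features in rows, samples in columns) with
#'   rownames and colnames set.
#' @param scale one of `"linear"` or `"log10"`.
#' @return an object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, scale = c("linear", "log10")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values))))
    stop("`values` must carry feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids in abundance matrix")
  if (scale == "linear" && any(values <= 0, na.rm = TRUE))
    stop("linear-scale intensities must be positive (zeros are missing)")
  structure(list(values = values, scale = scale), class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d features x %d samples [%s scale], %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$scale,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' Feature and sample identifiers
#' @param x an `abundance_matrix`.
#' @return character vector of ids.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Convert between linear and log10 intensity scales
#'
#' Missing cells stay missing; the scale tag is updated.
#'
#' @param x an `abundance_matrix`.
#' @return an `abundance_matrix` on the requested scale.
#' @export
to_log10 <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (x$scale == "log10") return(x)
  abundance_matrix(log10(x$values), scale = "log10")
}

#' @rdname to_log10
#' @export
to_linear <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (x$scale == "linear") return(x)
  abundance_matrix(10^x$values, scale = "linear")
}

# Build an abundance_matrix from a list of parsed records (records carry a
# named `intensities` vector; zeros were already mapped to NA by the reader).
records_to_matrix <- function(records, scale = "linear") {
  ids <- vapply(records, `[[`, character(1), 1L)
  samples <- unique(unlist(lapply(records, function(r) names(r$intensities))))
  m <- matrix(NA_real_, length(records), length(samples),
              dimnames = list(ids, samples))
  for (i in seq_along(records)) {
    v <- records[[i]]$intensities
    m[i, names(v)] <- unname(v)
  }
  abundance_matrix(m, scale = scale)
}
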