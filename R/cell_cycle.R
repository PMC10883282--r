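#' Cell-cycle phase proportions from periodic-protein clusters
#'
#' The bulk proteome of each cell line is summarised into five cluster sums
#' over annotated periodic proteins (proteins whose abundance oscillates over
#' the cell cycle). Each cluster sum is min-max rescaled across cell lines to
#' remove the bias of clusters with more members, and the five rescaled values
#' of a line are normalised to proportions summing to 1. Cluster labels map to
#' phases as metadata carried on the annotation (1: G1, 2: S, 3: G2,
#' 4: early M, 5: M); the labels are annotations, not computed.
#'
#' @param proteome linear-scale `abundance_matrix` of protein intensities.
#' @param periodic_clusters named list (`"1"`..`"5"`) of protein-id vectors,
#'   e.g. `annotations$periodic_clusters`.
#' @return object of class `cell_cycle_proportions`: `proportions` (cell
#'   lines x 5), plus intermediates `sums` and `rescaled`; lines whose five
#'   rescaled values are all 0 have undefined proportions and are listed in
#'   `undefined_lines`.
#' @export
cluster_proportions <- function(proteome, periodic_clusters) {
  stopifnot(inherits(proteome, "abundance_matrix"),
            proteome$scale == "linear")
  if (length(periodic_clusters) != 5L)
    stop("expected 5 periodic clusters")
  vals <- proteome$values
  sums <- sapply(names(periodic_clusters), function(cl) {
    members <- intersect(periodic_clusters[[cl]], rownames(vals))
    if (length(members) == 0L)
      stop("cluster ", cl, " has no mapped proteins")
    colSums(vals[members, , drop = FALSE], na.rm = TRUE)
  })  # cell lines x clusters
  # min-max rescale each cluster across cell lines; a cluster constant over
  # all lines carries no contrast and is set to the uninformative 0.5
  rescaled <- apply(sums, 2L, function(s) {
    rng <- range(s)
    if (rng[2L] == rng[1L]) return(rep(0.5, length(s)))
    (s - rng[1L]) / (rng[2L] - rng[1L])
  })
  dimnames(rescaled) <- dimnames(sums)
  tot <- rowSums(rescaled)
  undefined <- tot == 0
  props <- rescaled / ifelse(tot == 0, NA_real_, tot)
  structure(list(proportions = props, sums = sums, rescaled = rescaled,
                 undefined_lines = rownames(sums)[undefined]),
            class = "cell_cycle_proportions")
}

#' @export
print.cell_cycle_proportions <- function(x, ...) {
  cat(sprintf("cell_cycle_proportions: %d cell lines x %d clusters\n",
              nrow(x$proportions), ncol(x$proportions)))
  invisible(x)
}

#' Correlate cluster proportions with drug response
#'
#' For every drug whose minimum AUC across the panel is below `min_auc`
#' (drugs with very small effects are excluded to avoid spurious
#' correlations), the Pearson correlation between each cluster proportion and
#' the drug's AUC profile across shared cell lines is computed. Strong
#' negative correlations (r below `flag_threshold`) flag the cluster's phase
#' as a sensitivity marker; the positive mirror (r above `-flag_threshold`)
#' marks resistance-side associations.
#'
#' @param proportions a `cell_cycle_proportions`.
#' @param response a `drug_response`.
#' @param min_auc eligibility: a drug is screened only if its minimum AUC is
#'   below this (default 0.8).
#' @param flag_threshold sensitivity flag threshold on Pearson r
#'   (default -0.5).
#' @return data.frame with columns `drug`, `cluster`, `r`, `n`,
#'   `flag` (one of `"sensitivity"`, `"resistance"`, `"none"`). Pairs with
#'   fewer than 3 shared lines are reported with `r = NA`.
#' @export
correlate_with_response <- function(proportions, response, min_auc = 0.8,
                                    flag_threshold = -0.5) {
  stopifnot(inherits(proportions, "cell_cycle_proportions"),
            inherits(response, "drug_response"))
  props <- proportions$proportions
  shared <- intersect(rownames(props), colnames(response$auc))
  if (length(shared) == 0L) stop("no shared cell lines")
  auc <- response$auc[, shared, drop = FALSE]
  eligible <- rownames(auc)[apply(auc, 1L, min, na.rm = TRUE) < min_auc]
  out <- list()
  for (dg in eligible) for (cl in colnames(props)) {
    x <- props[shared, cl]
    y <- auc[dg, shared]
    ok <- !is.na(x) & !is.na(y)
    r <- if (sum(ok) >= 3L) stats::cor(x[ok], y[ok]) else NA_real_
    flag <- "none"
    if (!is.na(r) && r < flag_threshold) flag <- "sensitivity"
    if (!is.na(r) && r > -flag_threshold) flag <- "resistance"
    out[[length(out) + 1L]] <- data.frame(
      drug = dg, cluster = cl, r = r, n = sum(ok), flag = flag,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
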