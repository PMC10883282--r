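#' Kinase activity landscape
#'
#' Kinase activity across a cell-line panel is summarised from four evidence
#' layers: (a) kinase protein abundance (log10 full proteome), (b) summed
#' phosphorylation of the kinase's own p-sites, (c) activation-loop
#' phosphorylation, and (d) summed phosphorylation of the kinase's annotated
#' substrate sites. Each layer is standardised per kinase across cell lines
#' (z-score, sample SD) and the layers are added. Kinase protein abundance is
#' a hard requirement: without layer (a) no score is produced. In addition, at
#' least one phosphorylation-derived layer (b, c or d) must be present;
#' kinases with abundance only are reported separately for transparency.
#'
#' @name activity_landscape
NULL

# per-row z-score across samples: sample SD (n-1); rows with < 2 observed
# values stay missing (SD undefined); constant rows map to 0 so layer
# availability remains meaningful
row_zscore <- function(m) {
  t(apply(m, 1L, function(r) {
    obs <- !is.na(r)
    if (sum(obs) < 2L) return(rep(NA_real_, length(r)))
    s <- stats::sd(r[obs])
    if (s == 0) {
      r[obs] <- 0
      return(r)
    }
    (r - mean(r[obs])) / s
  }))
}

# sum linear-scale site intensities per kinase and sample; a missing site
# counts as 0 when at least one of the kinase's sites is observed in that
# sample, and the sum is missing when none are (additive evidence)
sum_sites_log10 <- function(phospho_linear, site_sets, kinases) {
  vals <- phospho_linear$values
  out <- matrix(NA_real_, length(kinases), ncol(vals),
                dimnames = list(kinases, colnames(vals)))
  for (k in kinases) {
    sites <- intersect(site_sets[[k]], rownames(vals))
    if (length(sites) == 0L) next
    sub <- vals[sites, , drop = FALSE]
    any_obs <- colSums(!is.na(sub)) > 0L
    s <- colSums(sub, na.rm = TRUE)
    s[!any_obs] <- NA_real_
    out[k, ] <- log10(s)
  }
  out
}

# gene part of a GENE_RESPOS site id
site_gene <- function(site_ids) sub("_[STY][0-9]+$", "", site_ids)

#' Layer (a): kinase abundance z-scores
#'
#' @param proteome log10-scale, median-centred `abundance_matrix` with
#'   protein/gene ids as rownames.
#' @param annotations an `annotation_set`.
#' @return kinases x cell lines z-score matrix (all annotated kinases as
#'   rows; missing where the kinase protein was not quantified in at least 2
#'   lines).
#' @export
layer_a_kinase_abundance <- function(proteome, annotations) {
  stopifnot(inherits(proteome, "abundance_matrix"),
            proteome$scale == "log10")
  kinases <- annotations$kinase_ids
  m <- matrix(NA_real_, length(kinases), ncol(proteome$values),
              dimnames = list(kinases, colnames(proteome$values)))
  present <- intersect(kinases, rownames(proteome$values))
  m[present, ] <- proteome$values[present, , drop = FALSE]
  row_zscore(m)
}

#' Layer (b): kinase phosphorylation z-scores
#'
#' Linear intensities of all p-sites on the kinase itself are summed per cell
#' line, log10-transformed and row-standardised.
#'
#' @param phospho linear-scale `abundance_matrix` of p-site intensities with
#'   `GENE_RESPOS` site ids as rownames.
#' @inheritParams layer_a_kinase_abundance
#' @return kinases x cell lines z-score matrix.
#' @export
layer_b_kinase_phospho <- function(phospho, annotations) {
  stopifnot(inherits(phospho, "abundance_matrix"),
            phospho$scale == "linear")
  genes <- site_gene(rownames(phospho$values))
  site_sets <- split(rownames(phospho$values), genes)
  row_zscore(sum_sites_log10(phospho, site_sets, annotations$kinase_ids))
}

#' Layer (c): activation-loop phosphorylation z-scores
#'
#' As layer (b) but restricted to annotated activation-loop sites.
#'
#' @inheritParams layer_b_kinase_phospho
#' @return kinases x cell lines z-score matrix.
#' @export
layer_c_activation_loop <- function(phospho, annotations) {
  stopifnot(inherits(phospho, "abundance_matrix"),
            phospho$scale == "linear")
  row_zscore(sum_sites_log10(phospho, annotations$activation_loop_sites,
                             annotations$kinase_ids))
}

#' Layer (d): substrate phosphorylation z-scores
#'
#' Linear intensities of the kinase's annotated substrate sites are summed,
#' log10-transformed and row-standardised. A substrate site shared by two
#' kinases contributes to both.
#'
#' @inheritParams layer_b_kinase_phospho
#' @return kinases x cell lines z-score matrix.
#' @export
layer_d_substrates <- function(phospho, annotations) {
  stopifnot(inherits(phospho, "abundance_matrix"),
            phospho$scale == "linear")
  row_zscore(sum_sites_log10(phospho, annotations$substrate_sites,
                             annotations$kinase_ids))
}

#' Combine the four activity layers into a landscape
#'
#' The combined score is `z_a` plus every available phosphorylation layer.
#' It is missing where layer (a) is missing, and also where none of layers
#' (b), (c), (d) is available; those abundance-only kinases are listed in
#' `a_only` rather than scored.
#'
#' @param a,b,c,d aligned kinases x cell lines z-score matrices.
#' @return object of class `activity_landscape`: `score`, `n_layers`,
#'   `layer_mask` (strings like `"abd"`), and `a_only` (kinase, cell_line
#'   pairs with abundance but no phosphorylation evidence).
#' @export
combine_activity_layers <- function(a, b, c, d) {
  stopifnot(identical(dim(a), dim(b)), identical(dim(a), dim(c)),
            identical(dim(a), dim(d)),
            identical(dimnames(a), dimnames(b)))
  has <- list(a = !is.na(a), b = !is.na(b), c = !is.na(c), d = !is.na(d))
  score <- ifelse(has$a, a, NA_real_) +
    ifelse(has$b, b, 0) + ifelse(has$c, c, 0) + ifelse(has$d, d, 0)
  any_bcd <- has$b | has$c | has$d
  a_only_idx <- which(has$a & !any_bcd, arr.ind = TRUE)
  score[!any_bcd] <- NA_real_
  mask <- matrix("", nrow(a), ncol(a), dimnames = dimnames(a))
  for (layer in names(has))
    mask[has[[layer]]] <- paste0(mask[has[[layer]]], layer)
  valid <- has$a & any_bcd
  n_layers <- matrix(NA_integer_, nrow(a), ncol(a), dimnames = dimnames(a))
  n_layers[valid] <- nchar(mask[valid])
  a_only <- data.frame(
    kinase = rownames(a)[a_only_idx[, 1L]],
    cell_line = colnames(a)[a_only_idx[, 2L]],
    stringsAsFactors = FALSE)
  structure(list(score = score, n_layers = n_layers, layer_mask = mask,
                 a_only = a_only),
            class = "activity_landscape")
}

#' @export
print.activity_landscape <- function(x, ...) {
  cat(sprintf("activity_landscape: %d kinases x %d cell lines, %d scores\n",
              nrow(x$score), ncol(x$score), sum(!is.na(x$score))))
  invisible(x)
}

#' Compute the full activity landscape
#'
#' Convenience wrapper running layers (a)-(d) and combining them.
#'
#' @param proteome log10-scale, median-centred proteome `abundance_matrix`.
#' @param phospho linear-scale phosphoproteome `abundance_matrix`.
#' @param annotations an `annotation_set`.
#' @return an `activity_landscape`.
#' @export
kinase_activity <- function(proteome, phospho, annotations) {
  combine_activity_layers(
    layer_a_kinase_abundance(proteome, annotations),
    layer_b_kinase_phospho(phospho, annotations),
    layer_c_activation_loop(phospho, annotations),
    layer_d_substrates(phospho, annotations))
}

#' Rank kinases by activity score within one cell line
#'
#' @param landscape an `activity_landscape`.
#' @param cell_line cell-line id (must exist in the landscape).
#' @param annotations `annotation_set`; required when `druggable_only`.
#' @param druggable_only restrict the ranking to kinases that are targets of
#'   at least one screened compound.
#' @return data.frame with columns `kinase`, `score`, ordered by descending
#'   score (ties broken lexicographically by kinase id).
#' @export
rank_kinases <- function(landscape, cell_line, annotations = NULL,
                         druggable_only = FALSE) {
  stopifnot(inherits(landscape, "activity_landscape"))
  if (!cell_line %in% colnames(landscape$score))
    stop("unknown cell line: ", cell_line)
  s <- landscape$score[, cell_line]
  if (druggable_only) {
    if (is.null(annotations))
      stop("`annotations` required when druggable_only = TRUE")
    s <- s[names(s) %in% annotations$druggable_kinases]
  }
  s <- s[!is.na(s)]
  if (length(s) == 0L) {
    warning("no scored kinases for cell line ", cell_line)
    return(data.frame(kinase = character(), score = numeric()))
  }
  ord <- order(-s, names(s))
  data.frame(kinase = names(s)[ord], score = unname(s[ord]),
             stringsAsFactors = FALSE)
}
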