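#' Time-course reporter-intensity analysis
#'
#' TMT reporter matrices from drug-treatment time courses are median
#' normalised per channel, duplicate modified sequences are collapsed, ratios
#' against the time-zero channel are formed, curves are linearly interpolated
#' and ranked by absolute maximal response, and features crossing a two-fold
#' ratio threshold at any time point are called regulated. The canonical time
#' grid is `{0, 5, 10, 15, 30, 90, 180, 360, 720, 1440}` minutes; a second
#' time-zero bridge channel shared between multiplexed batches is reduced to
#' the single t0 reference after channel normalisation.
#'
#' @name time_course
NULL

#' Median-normalise reporter channels
#'
#' Each channel (column) is scaled multiplicatively so that its median over
#' observed values equals the grand median of all observed values of the
#' input.
#'
#' @param reporter features x channels matrix of linear reporter intensities
#'   (`NA` for missing).
#' @return the normalised matrix.
#' @export
normalize_channels <- function(reporter) {
  reporter <- as.matrix(reporter)
  n_obs <- colSums(!is.na(reporter))
  if (any(n_obs == 0L))
    stop("channel(s) with no observed values: ",
         paste(colnames(reporter)[n_obs == 0L], collapse = ", "))
  grand <- stats::median(reporter, na.rm = TRUE)
  med <- apply(reporter, 2L, stats::median, na.rm = TRUE)
  sweep(reporter, 2L, grand / med, `*`)
}

#' Collapse duplicate modified sequences
#'
#' Methionine-oxidation tokens (`"(ox)"` by default) are stripped from the
#' modified-sequence row ids; rows whose stripped sequences coincide are
#' summed channel-wise (phospho and other tokens are preserved, so
#' differently phosphorylated forms stay separate). A channel is missing in
#' the collapsed row only when it is missing in all merged rows.
#'
#' @param reporter features x channels matrix with modified sequences as
#'   rownames.
#' @param oxidation_token token marking methionine oxidation.
#' @return the collapsed matrix.
#' @export
collapse_modified_sequences <- function(reporter, oxidation_token = "(ox)") {
  reporter <- as.matrix(reporter)
  seqs <- gsub(oxidation_token, "", rownames(reporter), fixed = TRUE)
  groups <- split(seq_len(nrow(reporter)), seqs)
  out <- t(vapply(groups, function(idx) {
    sub <- reporter[idx, , drop = FALSE]
    s <- colSums(sub, na.rm = TRUE)
    s[colSums(!is.na(sub)) == 0L] <- NA_real_
    s
  }, numeric(ncol(reporter))))
  colnames(out) <- colnames(reporter)
  out[order(rownames(out)), , drop = FALSE]
}

#' Ratios against the time-zero channel
#'
#' Divides every channel by the t0 channel, feature-wise, yielding
#' dimensionless ratio curves with ratio 1 at t0. Features whose t0 value is
#' missing (or zero) cannot be expressed as ratios; they are dropped and
#' listed in the `dropped` attribute.
#'
#' @param reporter normalised, collapsed features x channels matrix.
#' @param time_min numeric vector of time points (minutes) aligned to the
#'   channels; exactly one entry must be 0.
#' @return object of class `timecourse_matrix`: `ratios` (features x time
#'   points, columns named by minutes, ordered in time), `time_min`, and the
#'   `dropped` feature ids as an attribute.
#' @export
ratios_vs_t0 <- function(reporter, time_min) {
  reporter <- as.matrix(reporter)
  if (length(time_min) != ncol(reporter))
    stop("time_min must align with the channels")
  t0 <- which(time_min == 0)
  if (length(t0) != 1L) stop("exactly one channel must be time zero")
  ref <- reporter[, t0]
  bad <- is.na(ref) | ref == 0
  if (any(bad))
    warning(sum(bad), " feature(s) without usable t0 dropped")
  m <- reporter[!bad, , drop = FALSE] / ref[!bad]
  ord <- order(time_min)
  out <- structure(list(ratios = m[, ord, drop = FALSE],
                        time_min = time_min[ord]),
                   class = "timecourse_matrix")
  colnames(out$ratios) <- as.character(out$time_min)
  attr(out, "dropped") <- rownames(reporter)[bad]
  out
}

#' @export
print.timecourse_matrix <- function(x, ...) {
  cat(sprintf("timecourse_matrix: %d features x %d time points (%s min)\n",
              nrow(x$ratios), length(x$time_min),
              paste(x$time_min, collapse = ", ")))
  invisible(x)
}

#' Interpolate internal gaps and rank by maximal response
#'
#' Internal missing ratio values are filled by linear interpolation on the
#' minute axis (no extrapolation beyond a feature's first/last observed
#' point). Features are then ranked by the absolute maximal response,
#' measured as `max_t |log2 ratio(t)|` so that a 4-fold decrease and a 4-fold
#' increase are equally extreme.
#'
#' @param tc a `timecourse_matrix`.
#' @return data.frame ordered by descending `max_abs_log2`: `feature`,
#'   `max_abs_log2`, `max_response_time`, `ratio_at_max`; the interpolated
#'   ratio matrix is attached as attribute `interpolated`.
#' @export
interpolate_and_rank <- function(tc) {
  stopifnot(inherits(tc, "timecourse_matrix"))
  tm <- tc$time_min
  filled <- t(apply(tc$ratios, 1L, function(r) {
    obs <- !is.na(r)
    if (sum(obs) >= 2L && any(!obs))
      r[!obs] <- stats::approx(tm[obs], r[obs], xout = tm[!obs],
                               rule = 1)$y
    r
  }))
  dimnames(filled) <- dimnames(tc$ratios)
  l2 <- log2(filled)
  peak_idx <- apply(l2, 1L, function(r) {
    if (all(is.na(r))) return(NA_integer_)
    which.max(abs(r))
  })
  max_abs <- vapply(seq_len(nrow(l2)), function(i) {
    if (is.na(peak_idx[i])) return(NA_real_)
    abs(l2[i, peak_idx[i]])
  }, numeric(1))
  out <- data.frame(
    feature = rownames(l2),
    max_abs_log2 = max_abs,
    max_response_time = tm[peak_idx],
    ratio_at_max = vapply(seq_len(nrow(filled)), function(i) {
      if (is.na(peak_idx[i])) NA_real_ else filled[i, peak_idx[i]]
    }, numeric(1)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$max_abs_log2, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "interpolated") <- filled
  out
}

#' Call regulated features by a fold-change threshold
#'
#' A feature is regulated when its ratio crosses the fold threshold strictly
#' (`ratio < 1/fold` or `ratio > fold`) at at least one post-treatment time
#' point; a ratio of exactly 0.5 or 2 at `fold = 2` does not qualify. The
#' direction is the sign of the log2 ratio at the time point of maximal
#' absolute response.
#'
#' @param tc a `timecourse_matrix`.
#' @param fold fold-change threshold (default 2).
#' @return data.frame of regulated features: `feature`, `direction`
#'   (`"up"`/`"down"`), `max_abs_log2`, `max_response_time`.
#' @export
call_regulated <- function(tc, fold = 2) {
  stopifnot(inherits(tc, "timecourse_matrix"), fold > 1)
  post <- tc$time_min > 0
  r <- tc$ratios[, post, drop = FALSE]
  hit <- apply(r, 1L, function(x) any(x < 1 / fold | x > fold, na.rm = TRUE))
  ranked <- interpolate_and_rank(tc)
  ranked <- ranked[ranked$feature %in% rownames(tc$ratios)[hit], ,
                   drop = FALSE]
  data.frame(feature = ranked$feature,
             direction = ifelse(ranked$ratio_at_max > 1, "up", "down"),
             max_abs_log2 = ranked$max_abs_log2,
             max_response_time = ranked$max_response_time,
             stringsAsFactors = FALSE)
}
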