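#' Symmetric four-parameter log-logistic (4PL) dose-response model
#'
#' `f(x) = c + (d - c) / (1 + exp(b * (log(x) - log(e))))` with natural logs;
#' `c` is the lower limit, `d` the upper limit, `b` the slope and `e` the
#' ED50 (the dose at which the response is halfway between `c` and `d`).
#' The base of the logarithm is absorbed by `b`, so the natural-log form is
#' used throughout and documented for comparability of slopes.
#'
#' @param x dose (same units as `e`, typically micromolar; must be > 0).
#' @param b,c,d,e model parameters.
#' @return fitted viability at `x`.
#' @export
fourpl <- function(x, b, c, d, e) {
  c + (d - c) / (1 + exp(b * (log(x) - log(e))))
}

#' Normalise raw viability signals against plate controls
#'
#' Signals from one plate are scaled so the negative (vehicle) control mean
#' maps to 1 (full viability) and the positive (cytotoxic) control mean to 0.
#' Normalised values are clipped to `[0, 1.2]`; a `viability_fit` column
#' additionally caps at 1, the value used as fitting input. Replicates are
#' summarised per (drug, cell line, dose) with mean and SD.
#'
#' @param wells a data.frame of well records for one plate (columns `drug`,
#'   `cell_line`, `dose_uM`, `replicate`, `signal`, `well_role`).
#' @return data.frame with one row per (drug, cell_line, dose): `viability`
#'   (replicate mean, clipped), `viability_sd`, `viability_fit`, `n_wells`.
#' @export
normalize_viability <- function(wells) {
  pos <- wells$signal[wells$well_role == "positive_control"]
  neg <- wells$signal[wells$well_role == "negative_control"]
  if (length(pos) == 0L || length(neg) == 0L)
    stop("plate must contain positive and negative control wells")
  mu_pos <- mean(pos); mu_neg <- mean(neg)
  if (mu_neg <= mu_pos)
    stop("plate failure: negative-control mean <= positive-control mean")
  smp <- wells[wells$well_role == "sample", , drop = FALSE]
  v <- (smp$signal - mu_pos) / (mu_neg - mu_pos)
  v <- pmin(pmax(v, 0), 1.2)
  key <- interaction(smp$drug, smp$cell_line, smp$dose_uM, drop = TRUE)
  agg <- do.call(rbind, lapply(split(seq_len(nrow(smp)), key), function(idx) {
    data.frame(drug = smp$drug[idx[1L]],
               cell_line = smp$cell_line[idx[1L]],
               dose_uM = smp$dose_uM[idx[1L]],
               viability = mean(v[idx]),
               viability_sd = stats::sd(v[idx]),
               n_wells = length(idx))
  }))
  agg <- agg[order(agg$drug, agg$cell_line, agg$dose_uM), , drop = FALSE]
  agg$viability_fit <- pmin(agg$viability, 1)
  rownames(agg) <- NULL
  agg
}

#' Fit the 4PL model to one dose-response series
#'
#' Bounded Levenberg-Marquardt least squares on replicate-averaged viability.
#' Initialisation: `d = max(v)`, `c = min(v)`, `e` = the dose whose response
#' is nearest the half-maximal level, `b = 1`; bounds `c, d` in `[-0.2, 1.3]`,
#' `e` in `[min(dose)/100, max(dose)*100]`. These stabilise the well-known 4PL
#' identifiability problems with flat or one-sided curves. Practically flat
#' series (response range < 0.01) are not fitted: the fit is flagged
#' non-converged with `e = Inf` and downstream AUC falls back to the empirical
#' trapezoid.
#'
#' @param doses dose vector (micromolar, > 0), at least 4 distinct values.
#' @param viability replicate-averaged viability at each dose.
#' @return an object of class `curve_fit` with elements `b`, `c`, `d`, `e`,
#'   `converged`, `rmse` and the input points (used for empirical fallback).
#' @export
fit_4pl <- function(doses, viability) {
  if (length(doses) != length(viability))
    stop("doses and viability must have equal length")
  keep <- !is.na(doses) & !is.na(viability) & doses > 0
  doses <- doses[keep]; viability <- viability[keep]
  if (length(unique(doses)) < 4L)
    stop("need at least 4 distinct nonzero doses to fit a 4PL")
  new_fit <- function(b, c, d, e, converged, rmse) {
    structure(list(b = b, c = c, d = d, e = e, converged = converged,
                   rmse = rmse, doses = doses, viability = viability),
              class = "curve_fit")
  }
  d0 <- max(viability); c0 <- min(viability)
  if (d0 - c0 < 0.01) {
    return(new_fit(NA_real_, c0, d0, Inf, FALSE,
                   stats::sd(viability)))
  }
  half <- (d0 + c0) / 2
  e0 <- doses[which.min(abs(viability - half))]
  dat <- data.frame(x = doses, v = viability)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ c + (d - c) / (1 + exp(b * (log(x) - log(e)))),
      data = dat,
      start = list(b = 1, c = c0, d = d0, e = e0),
      lower = c(b = -50, c = -0.2, d = -0.2, e = min(doses) / 100),
      upper = c(b = 50, c = 1.3, d = 1.3, e = max(doses) * 100),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new_fit(NA_real_, c0, d0, Inf, FALSE,
                   sqrt(mean((viability - mean(viability))^2))))
  }
  p <- as.list(stats::coef(fit))
  # canonical orientation: c (lower) <= d (upper); swapping c/d while
  # negating b leaves the fitted function unchanged
  if (p$c > p$d) {
    tmp <- p$c; p$c <- p$d; p$d <- tmp; p$b <- -p$b
  }
  rmse <- sqrt(mean(stats::residuals(fit)^2))
  new_fit(p$b, p$c, p$d, p$e, TRUE, rmse)
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf(
    "curve_fit: b=%.3g c=%.3g d=%.3g ED50=%.4g uM (converged=%s, rmse=%.3g)\n",
    x$b, x$c, x$d, x$e, x$converged, x$rmse))
  invisible(x)
}

#' Standardised area under the dose-response curve
#'
#' The fitted viability curve is integrated over log10 dose across the tested
#' range and divided by the width of the log range, giving a dimensionless
#' AUC in `[0, 1]`: 1 means no response (full viability everywhere), 0 full
#' response. The standardisation makes the value invariant to the dose unit.
#' For non-converged fits the empirical trapezoid over the observed points
#' (capped at viability 1) is used instead.
#'
#' @param fit a `curve_fit`.
#' @param dose_range `c(x_min, x_max)` in the dose unit; defaults to the
#'   fitted dose range.
#' @return AUC in `[0, 1]`.
#' @export
standardized_auc <- function(fit, dose_range = range(fit$doses)) {
  x_min <- dose_range[1L]; x_max <- dose_range[2L]
  if (!(x_min > 0) || x_min >= x_max)
    stop("dose_range must satisfy 0 < x_min < x_max")
  if (isTRUE(fit$converged)) {
    u1 <- log10(x_min); u2 <- log10(x_max)
    val <- stats::integrate(function(u) fourpl(10^u, fit$b, fit$c, fit$d,
                                               fit$e),
                            u1, u2, rel.tol = 1e-8, abs.tol = 1e-10,
                            subdivisions = 500L)$value / (u2 - u1)
  } else {
    ord <- order(fit$doses)
    u <- log10(fit$doses[ord])
    v <- pmin(fit$viability[ord], 1)
    if (length(u) < 2L) stop("empirical AUC needs >= 2 dose points")
    val <- sum(diff(u) * (v[-1L] + v[-length(v)]) / 2) / (max(u) - min(u))
  }
  min(max(val, 0), 1)
}

#' Fit a whole screen into a drug-response object
#'
#' Normalises each cell line's wells against its plate controls, fits a 4PL
#' per (drug, cell line), and assembles matrices of standardised AUC, EC50
#' and maximal relative inhibition (1 minus the minimum of the fitted curve
#' over the tested range; for non-converged fits, 1 minus the lowest observed
#' capped viability).
#'
#' @param wells a drug-screen data.frame (see [read_drug_screen()]).
#' @return object of class `drug_response` with matrices `auc`, `ec50`,
#'   `max_inhibition` (drugs x cell lines) and the per-curve `fits` list.
#' @export
fit_screen <- function(wells) {
  norm <- do.call(rbind, lapply(split(wells, wells$cell_line),
                                normalize_viability))
  drugs <- sort(unique(norm$drug))
  lines <- sort(unique(norm$cell_line))
  shape <- function() matrix(NA_real_, length(drugs), length(lines),
                             dimnames = list(drugs, lines))
  auc <- shape(); ec50 <- shape(); maxinh <- shape()
  fits <- list()
  for (dg in drugs) for (cl in lines) {
    sub <- norm[norm$drug == dg & norm$cell_line == cl & norm$dose_uM > 0, ]
    if (nrow(sub) < 4L) next
    fit <- fit_4pl(sub$dose_uM, sub$viability_fit)
    key <- paste(dg, cl, sep = "|")
    fits[[key]] <- fit
    auc[dg, cl] <- standardized_auc(fit)
    ec50[dg, cl] <- fit$e
    if (isTRUE(fit$converged)) {
      lo <- min(fourpl(min(sub$dose_uM), fit$b, fit$c, fit$d, fit$e),
                fourpl(max(sub$dose_uM), fit$b, fit$c, fit$d, fit$e))
    } else {
      lo <- min(pmin(sub$viability_fit, 1))
    }
    maxinh[dg, cl] <- 1 - max(min(lo, 1), 0)
  }
  structure(list(auc = auc, ec50 = ec50, max_inhibition = maxinh,
                 fits = fits),
            class = "drug_response")
}

#' @export
print.drug_response <- function(x, ...) {
  cat(sprintf("drug_response: %d drugs x %d cell lines (%d fitted curves)\n",
              nrow(x$auc), ncol(x$auc), length(x$fits)))
  invisible(x)
}

#' Count effective kinase inhibitors per cell line
#'
#' A kinase inhibitor counts as effective in a cell line when its EC50 is
#' below `ec50_max` (default 0.1 uM = 100 nM), its standardised AUC is below
#' `auc_max` (default 0.9) and its maximal relative inhibition exceeds
#' `inhibition_min` (default 0.5).
#'
#' @param response a `drug_response`.
#' @param is_kinase_inhibitor logical vector named by drug (TRUE for KIs).
#' @param ec50_max,auc_max,inhibition_min filter thresholds.
#' @return named integer vector: effective-KI count per cell line.
#' @export
potency_filter <- function(response, is_kinase_inhibitor,
                           ec50_max = 0.1, auc_max = 0.9,
                           inhibition_min = 0.5) {
  stopifnot(inherits(response, "drug_response"))
  drugs <- rownames(response$auc)
  ki <- drugs[drugs %in% names(is_kinase_inhibitor)[is_kinase_inhibitor]]
  pass <- response$ec50[ki, , drop = FALSE] < ec50_max &
    response$auc[ki, , drop = FALSE] < auc_max &
    response$max_inhibition[ki, , drop = FALSE] > inhibition_min
  colSums(pass, na.rm = TRUE)
}

#' Z-prime plate-quality factor
#'
#' `Z' = 1 - 3 * (sd(pos) + sd(neg)) / |mean(pos) - mean(neg)|`. Values near 1
#' indicate a wide separation band between the control distributions; values
#' below 0 indicate overlapping controls.
#'
#' @param pos_signals,neg_signals raw signals of the positive and negative
#'   control wells (at least 2 each).
#' @return the Z-prime factor (may be negative).
#' @export
zprime <- function(pos_signals, neg_signals) {
  if (length(pos_signals) < 2L || length(neg_signals) < 2L)
    stop("need at least 2 wells per control group")
  mu_p <- mean(pos_signals); mu_n <- mean(neg_signals)
  if (mu_p == mu_n) stop("control means are identical; Z-prime undefined")
  1 - 3 * (stats::sd(pos_signals) + stats::sd(neg_signals)) / abs(mu_p - mu_n)
}
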