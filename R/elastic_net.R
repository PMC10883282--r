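#' Solve one elastic-net problem
#'
#' Minimises `1/(2n) ||y - X beta - beta0||^2 +
#' lambda * (alpha ||beta||_1 + (1-alpha)/2 ||beta||_2^2)`. Columns of `X`
#' are standardised internally; coefficients are returned on the original
#' scale. `lambda = 0` reduces to ordinary least squares (computed exactly),
#' `alpha = 0` to ridge, `alpha = 1` to the lasso. Deterministic for fixed
#' inputs.
#'
#' @param X samples x features matrix.
#' @param y response vector.
#' @param lambda penalty strength (>= 0).
#' @param alpha L1/L2 mixing parameter in `[0, 1]`.
#' @return list with `coefficients` (named by feature) and `intercept`.
#' @export
solve_elastic_net <- function(X, y, lambda, alpha) {
  X <- as.matrix(X)
  if (lambda < 0) stop("lambda must be >= 0")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (nrow(X) != length(y)) stop("X and y disagree on sample count")
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("f", seq_len(ncol(X)))
  if (lambda == 0) {
    fit <- stats::lm.fit(cbind(1, X), y)
    co <- fit$coefficients
    co[is.na(co)] <- 0
    return(list(coefficients = stats::setNames(co[-1L], cn),
                intercept = unname(co[1L])))
  }
  if (ncol(X) == 1L) {
    # glmnet needs >= 2 columns; the 1-D solution has a closed form on the
    # internally standardised scale (population-SD standardisation, matching
    # glmnet's convention)
    n <- nrow(X)
    mx <- mean(X[, 1L]); sx <- sqrt(mean((X[, 1L] - mx)^2))
    if (sx == 0) return(list(coefficients = stats::setNames(0, cn),
                             intercept = mean(y)))
    xs <- (X[, 1L] - mx) / sx
    my <- mean(y)
    rho <- sum(xs * (y - my)) / n
    bs <- sign(rho) * max(abs(rho) - lambda * alpha, 0) /
      (1 + lambda * (1 - alpha))
    beta <- bs / sx
    return(list(coefficients = stats::setNames(beta, cn),
                intercept = my - beta * mx))
  }
  fit <- glmnet::glmnet(X, y, alpha = alpha, lambda = lambda,
                        standardize = TRUE, thresh = 1e-12, maxit = 1e7)
  co <- as.numeric(stats::coef(fit))
  list(coefficients = stats::setNames(co[-1L], cn), intercept = co[1L])
}

# run expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Tune elastic-net hyperparameters in two stages
#'
#' Before any penalty is tuned, a seeded permutation gate tests the global
#' null of no feature-response association, using the omnibus statistic
#' `max_j |cor(x_j, y)|` against its distribution over `n_permutations`
#' permutations of `y`. At panel scale (tens of samples, hundreds of
#' features) cross-validated error alone cannot distinguish a genuine top
#' predictor from the best of hundreds of decoys - the CV gain of a heavily
#' shrunk near-ridge model is of the same order as CV noise - whereas the
#' omnibus statistic separates the two regimes sharply.
#'
#' Stage 1 selects the penalty strength `lambda` by cross-validated mean
#' squared error along glmnet's log-spaced lambda path with the mixing
#' parameter fixed at `alpha_for_lambda` (default 0.05): the CV-minimising
#' `lambda` when the gate detects association, otherwise the conservative
#' one-SE `lambda` (typically the near-empty model, so a null response
#' yields a near-empty fit). Stage 2 keeps that `lambda` fixed and compares
#' `alpha_grid` by fold-mean CV error, keeping `alpha_for_lambda` unless
#' another value is better by more than one standard error (switching alpha
#' at fixed lambda changes the effective penalty strength, so the switch
#' must be earned). Folds are a seed-deterministic 10-fold split (grouped
#' fold-mean errors give calibrated SEs, which leave-one-out squared errors
#' do not); leave-one-out is used only when n is too small to split.
#'
#' @param X samples x features matrix (complete; impute upstream).
#' @param y response vector (non-constant).
#' @param alpha_grid candidate mixing values (default `c(0.01, 0.05, 0.1)`).
#' @param alpha_for_lambda mixing value used during the lambda search.
#' @param seed integer seed controlling fold assignment and the gate's
#'   permutations.
#' @param n_permutations permutations for the association gate (default 20).
#' @return list with `lambda`, `alpha`, `associated` (gate verdict),
#'   `cv_mse` (named by alpha) and `foldid`.
#' @export
tune_elastic_net <- function(X, y, alpha_grid = c(0.01, 0.05, 0.1),
                             alpha_for_lambda = 0.05, seed = 1,
                             n_permutations = 20) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (stats::sd(y) == 0) stop("response is constant; nothing to tune")
  foldid <- if (n < 12L) seq_len(n) else
    with_seed(seed, sample(rep_len(1:10, n)))
  # global association gate: observed max |cor| vs permutation maxima
  max_abs_cor <- function(resp) max(abs(stats::cor(X, resp)), na.rm = TRUE)
  observed <- max_abs_cor(y)
  perm_max <- with_seed(seed + 1L, vapply(seq_len(n_permutations),
                                          function(b)
                                            max_abs_cor(sample(y)),
                                          numeric(1)))
  associated <- observed > max(perm_max)
  cv <- suppressWarnings(
    glmnet::cv.glmnet(X, y, alpha = alpha_for_lambda, foldid = foldid,
                      standardize = TRUE))
  lambda <- if (associated) cv$lambda.min else cv$lambda.1se
  folds <- sort(unique(foldid))
  fold_err <- vapply(alpha_grid, function(a) {
    vapply(folds, function(f) {
      hold <- foldid == f
      sub <- solve_elastic_net(X[!hold, , drop = FALSE], y[!hold],
                               lambda, a)
      pred <- drop(X[hold, , drop = FALSE] %*% sub$coefficients) +
        sub$intercept
      mean((y[hold] - pred)^2)
    }, numeric(1))
  }, numeric(length(folds)))
  cv_mse <- colMeans(fold_err)
  cv_se <- apply(fold_err, 2L, stats::sd) / sqrt(length(folds))
  names(cv_mse) <- names(cv_se) <- as.character(alpha_grid)
  best <- which.min(cv_mse)
  i0 <- which(alpha_grid == alpha_for_lambda)
  alpha <- if (length(i0) == 1L &&
               cv_mse[i0] <= cv_mse[best] + cv_se[best])
    alpha_for_lambda else alpha_grid[best]
  list(lambda = lambda, alpha = alpha, associated = associated,
       cv_mse = cv_mse, foldid = foldid)
}

#' Bootstrapped elastic-net marker report
#'
#' Refits the elastic net on `n_bootstrap` resamples of the sample index
#' (with replacement, size n) at fixed tuned hyperparameters and aggregates,
#' per feature, the mean coefficient over all models (zeros from unselected
#' features included, so magnitude is comparable to frequency) and the
#' selection frequency (fraction of models with a nonzero coefficient). The
#' resulting table supports volcano-style plots of frequency against mean
#' coefficient. A negative mean coefficient with the response on the AUC
#' scale means higher abundance tracks lower AUC, i.e. drug sensitivity.
#'
#' @param X samples x features matrix (complete).
#' @param y response vector (e.g. one drug's AUC profile).
#' @param lambda,alpha tuned hyperparameters (see [tune_elastic_net()]).
#' @param n_bootstrap number of bootstrap models (default 100).
#' @param seed integer seed for the resampling.
#' @return object of class `enet_report`: data.frame with `feature`,
#'   `mean_coefficient`, `selection_frequency`, `direction`.
#' @export
bootstrap_report <- function(X, y, lambda, alpha, n_bootstrap = 100,
                             seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("f", seq_len(p))
  coefs <- matrix(0, n_bootstrap, p)
  with_seed(seed, {
    b <- 1L
    while (b <= n_bootstrap) {
      ok <- FALSE
      for (attempt in 1:10) {
        idx <- sample.int(n, n, replace = TRUE)
        if (stats::sd(y[idx]) > 0) { ok <- TRUE; break }
      }
      if (!ok) {
        warning("could not draw a non-degenerate resample; skipping one")
        n_bootstrap <- n_bootstrap - 1L
        coefs <- coefs[-nrow(coefs), , drop = FALSE]
        next
      }
      coefs[b, ] <- solve_elastic_net(X[idx, , drop = FALSE], y[idx],
                                      lambda, alpha)$coefficients
      b <- b + 1L
    }
  })
  mean_co <- colMeans(coefs)
  freq <- colMeans(coefs != 0)
  direction <- ifelse(freq == 0, "none",
                      ifelse(mean_co < 0, "sensitivity", "resistance"))
  out <- data.frame(feature = cn, mean_coefficient = mean_co,
                    selection_frequency = freq, direction = direction,
                    stringsAsFactors = FALSE)
  class(out) <- c("enet_report", "data.frame")
  out
}

#' Feature-drug pairwise correlation screen
#'
#' Pearson correlation of every feature's abundance profile with every drug's
#' AUC profile over pairwise-complete cell lines, on the non-imputed matrix.
#' Pairs must have more than `min_pairs` complete observations (strictly
#' greater, i.e. at least `min_pairs + 1`) to enter the filtered output,
#' avoiding artificially extreme correlations driven by imputation. p-values
#' come from the t-distribution transform of r and are reported, not used as
#' a filter.
#'
#' @param features an `abundance_matrix` (typically log10, non-imputed).
#' @param response a `drug_response` or a drugs x cell lines AUC matrix.
#' @param min_pairs exclusive lower bound on complete pairs (default 8).
#' @return data.frame with `feature`, `drug`, `r`, `n`, `p`.
#' @export
pairwise_correlations <- function(features, response, min_pairs = 8) {
  stopifnot(inherits(features, "abundance_matrix"))
  auc <- if (inherits(response, "drug_response")) response$auc else
    as.matrix(response)
  shared <- intersect(sample_ids(features), colnames(auc))
  if (length(shared) < 3L) stop("need at least 3 shared cell lines")
  fm <- features$values[, shared, drop = FALSE]
  out <- list()
  for (dg in rownames(auc)) {
    y <- auc[dg, shared]
    n_pairs <- rowSums(!is.na(fm) & !is.na(y)[col(fm)])
    r <- suppressWarnings(as.numeric(stats::cor(t(fm), y,
                                                use = "pairwise.complete.obs")))
    keep <- n_pairs > min_pairs & !is.na(r)
    if (!any(keep)) next
    nn <- n_pairs[keep]; rr <- r[keep]
    tt <- rr * sqrt((nn - 2) / pmax(1 - rr^2, .Machine$double.eps))
    out[[dg]] <- data.frame(feature = rownames(fm)[keep], drug = dg,
                            r = rr, n = nn,
                            p = 2 * stats::pt(-abs(tt), nn - 2),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
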