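#' Sparse multiblock partial least-squares regression (SMBPLSR)
#'
#' SMBPLSR finds, per component, a sparse drug loading `v` and sparse
#' per-block feature loadings `u_k` (here two predictor blocks: protein
#' abundance and p-site intensity) maximising the summed squared covariance
#' `sum_k cov^2(X_k u_k, Y v)` between the block scores `t_k = X_k u_k` and
#' the response score `s = Y v`. Sparsity is imposed in cardinality form:
#' exactly `k_drugs` drugs and `k_features` features (pooled across blocks)
#' carry nonzero loadings, reproducing the configured counts
#' deterministically. Columns are centred, not scaled; covariance uses the
#' n-1 denominator.
#'
#' @name smbplsr
NULL

#' Assemble an SMBPLSR input
#'
#' @param X_blocks list of predictor matrices (samples x features), sharing
#'   the sample (row) index; typically protein and p-site blocks.
#' @param Y response matrix (samples x drugs; e.g. standardised AUC values).
#' @return object of class `smbplsr_input` holding column-centred copies of
#'   all blocks.
#' @export
smbplsr_input <- function(X_blocks, Y) {
  if (!is.list(X_blocks) || length(X_blocks) < 1L)
    stop("X_blocks must be a non-empty list of matrices")
  Y <- as.matrix(Y)
  n <- nrow(Y)
  X_blocks <- lapply(X_blocks, as.matrix)
  if (any(vapply(X_blocks, nrow, integer(1)) != n))
    stop("all blocks must share the sample (row) index")
  if (any(vapply(X_blocks, anyNA, logical(1))) || anyNA(Y))
    stop("SMBPLSR input must be complete (impute upstream)")
  structure(list(X = lapply(X_blocks, scale, center = TRUE, scale = FALSE),
                 Y = scale(Y, center = TRUE, scale = FALSE),
                 n = n),
            class = "smbplsr_input")
}

# keep the k largest-|.| entries of w, zero the rest, L2-normalise the
# survivors; ties broken by index order for determinism
hard_threshold <- function(w, k) {
  out <- numeric(length(w))
  if (k <= 0L) return(out)
  keep <- order(-abs(w), seq_along(w))[seq_len(min(k, length(w)))]
  out[keep] <- w[keep]
  nrm <- sqrt(sum(out^2))
  if (nrm > 0) out <- out / nrm
  out
}

# select the pooled feature support: with u_k L2-normalised on its support,
# block k contributes ||w_k restricted to S_k||^2 / (n-1)^2 to the objective
# (w_k = X_k' s), so the total is the sum of squared selected gradient
# entries across blocks -- the exact maximiser under the pooled cardinality
# is the global top-k of |w| over the concatenated blocks
select_pooled_support <- function(w_list, k_total) {
  sizes <- lengths(w_list)
  pool <- abs(unlist(w_list, use.names = FALSE))
  keep_global <- order(-pool, seq_along(pool))[seq_len(min(k_total,
                                                           length(pool)))]
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  lapply(seq_along(w_list), function(k) {
    local <- keep_global[keep_global > offsets[k] &
                           keep_global <= offsets[k] + sizes[k]] - offsets[k]
    out <- numeric(sizes[k])
    out[local] <- w_list[[k]][local]
    nrm <- sqrt(sum(out^2))
    if (nrm > 0) out / nrm else out
  })
}

smbplsr_objective <- function(X, Y, u, v, n) {
  s <- drop(Y %*% v)
  sum(vapply(seq_along(X), function(k) {
    (sum(drop(X[[k]] %*% u[[k]]) * s) / (n - 1))^2
  }, numeric(1)))
}

#' Fit one SMBPLSR component
#'
#' Alternating updates: given the drug loading `v`, the pooled feature
#' support is the global top-`k_features` of the concatenated gradients
#' `|X_k' Y v|`, with each block loading renormalised on its support (this
#' step is the exact maximiser of the objective under the pooled cardinality
#' constraint); given the block scores, the drug loading is the better of the
#' hard-thresholded super-score gradient `sum_k Y' t_k` and a truncated power
#' step on the induced quadratic form. A new iterate is accepted only if the
#' objective did not decrease; the update loop stops when the objective
#' changes by less than `tol` or after `max_iter` sweeps. To avoid poor local
#' optima of the non-convex problem the solver deterministically restarts
#' from the leading right singular vector of `Y` and from every single-drug
#' indicator vector, keeping the best objective.
#'
#' @param input an `smbplsr_input` (already deflated as needed).
#' @param k_drugs number of drugs with nonzero loading (default 6).
#' @param k_features pooled number of features with nonzero loading across
#'   all predictor blocks (default 50).
#' @param tol convergence tolerance on the objective (default 1e-6).
#' @param max_iter maximum alternating sweeps per start (default 500).
#' @return object of class `smbplsr_component`: loadings `u` (list per
#'   block), `v`, scores `t` (list), `s`, `objective`, `converged`,
#'   `selected_drugs`, `selected_features` (list per block).
#' @export
fit_component <- function(input, k_drugs = 6, k_features = 50,
                          tol = 1e-6, max_iter = 500) {
  stopifnot(inherits(input, "smbplsr_input"))
  X <- input$X; Y <- input$Y; n <- input$n
  q <- ncol(Y)
  dims <- vapply(X, ncol, integer(1))
  if (k_drugs > q) stop("k_drugs exceeds the number of drugs")
  if (k_features > sum(dims)) stop("k_features exceeds total features")

  run_from <- function(v0) {
    v <- hard_threshold(v0, k_drugs)
    if (sum(abs(v)) == 0) return(NULL)
    u <- lapply(dims, function(p) numeric(p))
    obj <- -Inf; converged <- FALSE
    best <- NULL
    for (iter in seq_len(max_iter)) {
      s <- drop(Y %*% v)
      w <- lapply(X, function(Xk) drop(crossprod(Xk, s)))
      u_new <- select_pooled_support(w, k_features)
      t_list <- mapply(function(Xk, uk) drop(Xk %*% uk), X, u_new,
                       SIMPLIFY = FALSE)
      # two candidate drug-loading updates: the super-score gradient
      # Y' sum_k t_k, and a truncated power step on the quadratic form
      # v' [Y' (sum_k t_k t_k') Y] v whose maximiser the v-step targets;
      # keep whichever scores higher
      z1 <- Reduce(`+`, lapply(t_list, function(tk) drop(crossprod(Y, tk))))
      z2 <- Reduce(`+`, lapply(t_list, function(tk) {
        ytk <- drop(crossprod(Y, tk))
        ytk * sum(ytk * v)
      }))
      cands <- Filter(function(x) sum(abs(x)) > 0,
                      list(hard_threshold(z1, k_drugs),
                           hard_threshold(z2, k_drugs)))
      if (length(cands) == 0L) cands <- list(v)
      objs <- vapply(cands, function(vc)
        smbplsr_objective(X, Y, u_new, vc, n), numeric(1))
      v_new <- cands[[which.max(objs)]]
      obj_new <- max(objs)
      if (obj_new < obj - 1e-12) break  # reject decreasing step
      u <- u_new; v <- v_new
      best <- list(u = u, v = v, objective = obj_new)
      if (is.finite(obj) && abs(obj_new - obj) < tol) {
        converged <- TRUE
        obj <- obj_new
        break
      }
      obj <- obj_new
    }
    if (is.null(best)) return(NULL)
    best$converged <- converged
    best
  }

  starts <- list(svd(Y, nu = 0L, nv = 1L)$v[, 1L])
  if (q <= 64L)
    starts <- c(starts, lapply(seq_len(q), function(j) {
      e <- numeric(q); e[j] <- 1; e
    }))
  if (k_drugs < q && choose(q, k_drugs) <= 256) {
    # small drug space: also start from the best rank-1 direction inside
    # every admissible drug support
    starts <- c(starts, utils::combn(q, k_drugs, simplify = FALSE,
      FUN = function(D) {
        e <- numeric(q)
        e[D] <- svd(Y[, D, drop = FALSE], nu = 0L, nv = 1L)$v[, 1L]
        e
      }))
  }
  if (k_features < sum(dims) && choose(sum(dims), k_features) <= 256) {
    # small feature space: start from the leading eigenvector of the
    # drug-space quadratic form induced by every pooled feature support
    offsets <- cumsum(c(0L, dims[-length(dims)]))
    starts <- c(starts, utils::combn(sum(dims), k_features,
      simplify = FALSE,
      FUN = function(S) {
        G <- matrix(0, q, q)
        for (k in seq_along(X)) {
          loc <- S[S > offsets[k] & S <= offsets[k] + dims[k]] - offsets[k]
          if (length(loc) == 0L) next
          A <- crossprod(X[[k]][, loc, drop = FALSE], Y) / (n - 1)
          G <- G + crossprod(A)
        }
        eigen(G, symmetric = TRUE)$vectors[, 1L]
      }))
  }
  fits <- Filter(Negate(is.null), lapply(starts, run_from))
  if (length(fits) == 0L) stop("no admissible start (response block zero?)")
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "objective"))]]

  u <- best$u; v <- best$v
  # sign convention: the largest-|loading| drug entry is positive
  if (v[which.max(abs(v))] < 0) {
    v <- -v
    u <- lapply(u, function(x) -x)
  }
  t_list <- mapply(function(Xk, uk) drop(Xk %*% uk), X, u, SIMPLIFY = FALSE)
  blk <- names(X)
  if (is.null(blk)) blk <- paste0("block", seq_along(X))
  names(u) <- names(t_list) <- blk
  structure(list(
    u = u, v = stats::setNames(v, colnames(Y)),
    t = t_list, s = drop(Y %*% v),
    objective = best$objective, converged = best$converged,
    selected_drugs = colnames(Y)[v != 0],
    selected_features = lapply(seq_along(u), function(k) {
      cn <- colnames(input$X[[k]])
      if (is.null(cn)) cn <- as.character(seq_len(dims[k]))
      cn[u[[k]] != 0]
    })),
    class = "smbplsr_component")
}

#' @export
print.smbplsr_component <- function(x, ...) {
  cat(sprintf(
    "smbplsr_component: objective %.4g, %d drugs, %d features selected\n",
    x$objective, length(x$selected_drugs),
    length(unlist(x$selected_features))))
  invisible(x)
}

#' Deflate an SMBPLSR input by a fitted component
#'
#' Standard PLS deflation: each block is regressed out on its own score
#' (`X_k <- X_k - t_k t_k' X_k / t_k' t_k`), and the response block on the
#' sample-wise sum of the block scores. Centring is preserved. Zero-norm
#' scores skip deflation with a warning.
#'
#' @param input an `smbplsr_input`.
#' @param component a fitted `smbplsr_component`.
#' @return the deflated `smbplsr_input`.
#' @export
deflate <- function(input, component) {
  stopifnot(inherits(input, "smbplsr_input"),
            inherits(component, "smbplsr_component"))
  X <- input$X
  for (k in seq_along(X)) {
    tk <- component$t[[k]]
    nt <- sum(tk^2)
    if (nt == 0) {
      warning("zero-norm block score; skipping deflation of block ", k)
      next
    }
    X[[k]] <- X[[k]] - tk %*% (crossprod(tk, X[[k]]) / nt)
  }
  tbar <- Reduce(`+`, component$t)
  Y <- input$Y
  nt <- sum(tbar^2)
  if (nt == 0) {
    warning("zero-norm super score; skipping deflation of Y")
  } else {
    Y <- Y - tbar %*% (crossprod(tbar, Y) / nt)
  }
  structure(list(X = X, Y = Y, n = input$n), class = "smbplsr_input")
}

#' Fit a full SMBPLSR model
#'
#' Sequentially fits `n_components` components, deflating between them. A
#' positive loading on a drug together with a negative feature loading (or
#' vice versa) associates higher feature abundance with lower AUC, i.e. a
#' sensitivity marker; the sign convention fixes the largest-|loading| drug
#' entry positive per component.
#'
#' @param input an `smbplsr_input`, or a list of predictor blocks if `Y` is
#'   given.
#' @param Y optional response matrix (used when `input` is a block list).
#' @param n_components number of components (default 12).
#' @param k_drugs drugs per component (default 6).
#' @param k_features pooled features per component (default 50).
#' @param tol,max_iter passed to [fit_component()].
#' @return object of class `smbplsr_model` with the component list.
#' @export
smbplsr_fit <- function(input, Y = NULL, n_components = 12, k_drugs = 6,
                        k_features = 50, tol = 1e-6, max_iter = 500) {
  if (!inherits(input, "smbplsr_input")) input <- smbplsr_input(input, Y)
  comps <- vector("list", n_components)
  for (h in seq_len(n_components)) {
    resid <- sum(unlist(lapply(input$X, function(m) sum(m^2)))) *
      sum(input$Y^2)
    if (resid < 1e-20) {
      warning("signal exhausted after ", h - 1L,
              " components; stopping early")
      comps <- comps[seq_len(h - 1L)]
      break
    }
    comps[[h]] <- fit_component(input, k_drugs, k_features, tol, max_iter)
    input <- deflate(input, comps[[h]])
  }
  structure(list(components = comps, k_drugs = k_drugs,
                 k_features = k_features),
            class = "smbplsr_model")
}

#' @export
print.smbplsr_model <- function(x, ...) {
  cat(sprintf("smbplsr_model: %d components (%d drugs, %d features each)\n",
              length(x$components), x$k_drugs, x$k_features))
  invisible(x)
}
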