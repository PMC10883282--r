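# small builders shared across test files

toy_matrix <- function(values, lines = NULL, feats = NULL,
                       scale = "log10") {
  m <- as.matrix(values)
  if (is.null(lines)) lines <- sprintf("CL%02d", seq_len(ncol(m)))
  if (is.null(feats)) feats <- sprintf("F%02d", seq_len(nrow(m)))
  dimnames(m) <- list(feats, lines)
  abundance_matrix(m, scale = scale)
}

write_lines_tmp <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# exhaustive-support oracle for the SMBPLSR objective: enumerate every
# pooled feature support and drug support; within a support the optimum is
# the top eigenvalue of the induced quadratic form in drug space
smbplsr_brute_force <- function(X_blocks, Y, k_drugs, k_features) {
  n <- nrow(Y)
  Xc <- lapply(X_blocks, scale, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  dims <- vapply(Xc, ncol, integer(1))
  q <- ncol(Yc)
  off <- cumsum(c(0L, dims[-length(dims)]))
  best <- -Inf
  for (S in utils::combn(sum(dims), k_features, simplify = FALSE)) {
    for (D in utils::combn(q, k_drugs, simplify = FALSE)) {
      M <- matrix(0, k_drugs, k_drugs)
      for (k in seq_along(Xc)) {
        loc <- S[S > off[k] & S <= off[k] + dims[k]] - off[k]
        if (length(loc) == 0L) next
        A <- crossprod(Xc[[k]][, loc, drop = FALSE],
                       Yc[, D, drop = FALSE]) / (n - 1)
        M <- M + crossprod(A)
      }
      ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values[1L]
      if (ev > best) best <- ev
    }
  }
  best
}
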