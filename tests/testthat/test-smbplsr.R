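test_that("dense single-block limit equals the SVD of X'Y", {
  set.seed(101)
  n <- 10
  X <- matrix(rnorm(n * 5), n)
  Y <- matrix(rnorm(n * 3), n)
  fit <- fit_component(smbplsr_input(list(X), Y), k_drugs = 3,
                       k_features = 5, tol = 1e-12)
  sv <- svd(crossprod(scale(X, scale = FALSE), scale(Y, scale = FALSE)))
  expect_equal(fit$objective, (sv$d[1] / (n - 1))^2, tolerance = 1e-6)
  # loadings match the singular vectors up to sign
  expect_equal(abs(fit$u[[1]]), abs(sv$u[, 1]), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(abs(unname(fit$v)), abs(sv$v[, 1]), tolerance = 1e-4)
})

test_that("iterative solver matches exhaustive support enumeration", {
  set.seed(202)
  for (rep in 1:25) {
    n <- sample(5:8, 1)
    K <- sample(1:2, 1)
    dims <- sample(2:6, K)
    q <- sample(2:4, 1)
    kd <- sample(1:min(2, q), 1)
    kf <- min(sample(1:2, 1), sum(dims))
    X <- lapply(dims, function(p) matrix(rnorm(n * p), n))
    Y <- matrix(rnorm(n * q), n)
    fit <- fit_component(smbplsr_input(X, Y), k_drugs = kd,
                         k_features = kf, tol = 1e-10)
    oracle <- smbplsr_brute_force(X, Y, kd, kf)
    expect_equal(fit$objective, oracle, tolerance = 1e-6)
  }
})

test_that("a single informative drug column forces its own support", {
  set.seed(303)
  n <- 12
  X <- matrix(rnorm(n * 4), n)
  Y <- cbind(drop(X %*% c(1, -1, 0, 0)) + rnorm(n, 0, 0.01),
             0, 0)
  colnames(Y) <- c("live", "dead1", "dead2")
  fit <- fit_component(smbplsr_input(list(X), Y), k_drugs = 1,
                       k_features = 4)
  expect_equal(fit$selected_drugs, "live")
  expect_equal(unname(fit$v[["live"]]), 1)
})

test_that("deflation orthogonalises scores and exhausts rank-1 signal", {
  set.seed(404)
  n <- 9
  X <- matrix(rnorm(n * 6), n)
  Y <- matrix(rnorm(n * 3), n)
  inp <- smbplsr_input(list(X), Y)
  fit <- fit_component(inp, k_drugs = 2, k_features = 3)
  defl <- deflate(inp, fit)
  expect_lt(max(abs(crossprod(fit$t[[1]], defl$X[[1]]))), 1e-9)
  # rank-1 problem: the second component has (near) zero objective
  u0 <- rnorm(5); v0 <- rnorm(2)
  t0 <- rnorm(n)
  X1 <- tcrossprod(t0, u0)
  Y1 <- tcrossprod(t0, v0)
  inp1 <- smbplsr_input(list(X1), Y1)
  f1 <- fit_component(inp1, k_drugs = 1, k_features = 2)
  inp2 <- deflate(inp1, f1)
  f2 <- fit_component(inp2, k_drugs = 1, k_features = 2)
  expect_lt(f2$objective / f1$objective, 1e-9)
})

test_that("cardinality constraints and sign convention hold per component", {
  set.seed(505)
  n <- 17
  X1 <- matrix(rnorm(n * 40), n)
  X2 <- matrix(rnorm(n * 60), n)
  Y <- matrix(rnorm(n * 10), n,
              dimnames = list(NULL, paste0("D", 1:10)))
  model <- smbplsr_fit(list(X1, X2), Y, n_components = 4, k_drugs = 3,
                       k_features = 12)
  for (comp in model$components) {
    expect_equal(sum(comp$v != 0), 3L)
    expect_equal(sum(unlist(comp$u) != 0), 12L)
    expect_equal(sum(comp$v^2), 1, tolerance = 1e-12)
    for (u in comp$u) {
      nz <- sum(u != 0)
      if (nz > 0) expect_equal(sum(u^2), 1, tolerance = 1e-12)
    }
    expect_gt(comp$v[which.max(abs(comp$v))], 0)
  }
})

test_that("sample permutation permutes scores and preserves loadings", {
  set.seed(606)
  n <- 11
  X <- matrix(rnorm(n * 8), n)
  Y <- matrix(rnorm(n * 4), n)
  f1 <- fit_component(smbplsr_input(list(X), Y), k_drugs = 2,
                      k_features = 3)
  perm <- sample(n)
  f2 <- fit_component(smbplsr_input(list(X[perm, ]), Y[perm, ]),
                      k_drugs = 2, k_features = 3)
  expect_equal(f2$u[[1]], f1$u[[1]], tolerance = 1e-8)
  expect_equal(unname(f2$v), unname(f1$v), tolerance = 1e-8)
  expect_equal(f2$t[[1]], f1$t[[1]][perm], tolerance = 1e-8)
})

test_that("planted orthogonal drug-marker groups are co-selected", {
  set.seed(707)
  recovered <- replicate(10, {
    n <- 17
    lat1 <- rnorm(n); lat2 <- rnorm(n)
    X <- cbind(sapply(1:5, function(i) lat1 + rnorm(n, 0, 0.2)),
               sapply(1:5, function(i) lat2 + rnorm(n, 0, 0.2)),
               matrix(rnorm(n * 30), n))
    Y <- cbind(sapply(1:3, function(i) -lat1 + rnorm(n, 0, 0.2)),
               sapply(1:3, function(i) lat2 + rnorm(n, 0, 0.2)))
    colnames(Y) <- paste0("D", 1:6)
    model <- smbplsr_fit(list(X), Y, n_components = 2, k_drugs = 3,
                         k_features = 5)
    sel1 <- model$components[[1]]$selected_drugs
    sel2 <- model$components[[2]]$selected_drugs
    jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
    g1 <- paste0("D", 1:3); g2 <- paste0("D", 4:6)
    max(jac(sel1, g1), jac(sel1, g2)) >= 0.8 &&
      max(jac(sel2, g1), jac(sel2, g2)) >= 0.8 &&
      !setequal(sel1, sel2)
  })
  expect_gte(mean(recovered), 0.8)
})

test_that("accepted iterates never decrease the objective", {
  # the update loop rejects decreasing steps by construction; verify the
  # reported objective dominates every restart's first-sweep objective
  set.seed(808)
  n <- 10
  X <- list(matrix(rnorm(n * 7), n), matrix(rnorm(n * 5), n))
  Y <- matrix(rnorm(n * 4), n)
  inp <- smbplsr_input(X, Y)
  f_tight <- fit_component(inp, k_drugs = 2, k_features = 4, tol = 1e-12,
                           max_iter = 500)
  f_single <- fit_component(inp, k_drugs = 2, k_features = 4, tol = 1e-12,
                            max_iter = 1)
  expect_gte(f_tight$objective, f_single$objective - 1e-10)
})
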