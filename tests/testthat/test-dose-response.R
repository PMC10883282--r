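test_that("viability normalisation maps controls to the unit interval", {
  wells <- data.frame(
    drug = c(rep("D1", 3), "DMSO", "DMSO", "STS", "STS"),
    cell_line = "CL1",
    dose_uM = c(1, 1, 1, 0, 0, 5, 5),
    replicate = c(1:3, 1, 2, 1, 2),
    signal = c(100, 55, 10, 100, 100, 10, 10),
    well_role = c(rep("sample", 3), rep("negative_control", 2),
                  rep("positive_control", 2)),
    stringsAsFactors = FALSE)
  out <- normalize_viability(wells)
  # signals at neg mean, midway, pos mean -> 1, 0.5, 0
  expect_equal(out$viability, mean(c(1, 0.5, 0)))
  expect_equal(out$n_wells, 3L)
  # plate failure when controls are inverted
  bad <- wells
  bad$signal[bad$well_role == "negative_control"] <- 5
  expect_error(normalize_viability(bad), "plate failure")
})

test_that("4PL fit recovers exact-model parameters and the ED50 midpoint", {
  doses <- 10^seq(-3, 1, length.out = 10)
  v <- fourpl(doses, b = 1, c = 0, d = 1, e = 1)
  fit <- fit_4pl(doses, v)
  expect_true(fit$converged)
  expect_lt(abs(fit$e - 1) / 1, 0.01)
  expect_equal(fit$c, 0, tolerance = 1e-4)
  expect_equal(fit$d, 1, tolerance = 1e-4)
  # the fitted response at the ED50 is the midpoint of the limits
  expect_equal(fourpl(fit$e, fit$b, fit$c, fit$d, fit$e),
               (fit$c + fit$d) / 2, tolerance = 1e-12)
  # parameter self-recovery across a range of slopes
  for (b in c(0.3, 1, 2.5, 5)) {
    vb <- fourpl(doses, b = b, c = 0.1, d = 0.95, e = 0.05)
    fb <- fit_4pl(doses, vb)
    expect_lt(abs(fb$e - 0.05) / 0.05, 1e-3)
    expect_lt(abs(fb$b - b) / b, 1e-3)
  }
  expect_error(fit_4pl(c(1, 2, 3), c(1, 0.5, 0)), "4 distinct")
})

test_that("flat curves yield the empirical fallback with infinite ED50", {
  doses <- 10^seq(-2, 1, length.out = 8)
  fit <- fit_4pl(doses, rep(1, 8))
  expect_false(fit$converged)
  expect_equal(fit$e, Inf)
  expect_equal(standardized_auc(fit), 1)
  fit0 <- fit_4pl(doses, rep(0, 8))
  expect_equal(standardized_auc(fit0), 0)
})

test_that("standardised AUC integrates in log-dose space and is unit-free", {
  # symmetric sigmoid centred at the geometric middle of the range: AUC 1/2
  doses <- 10^seq(-2, 2, length.out = 12)
  fit <- fit_4pl(doses, fourpl(doses, b = 6, c = 0, d = 1, e = 1))
  expect_equal(standardized_auc(fit, c(1e-2, 1e2)), 0.5, tolerance = 1e-3)
  # independent quadrature oracle at asymmetric placement
  fit2 <- fit_4pl(doses, fourpl(doses, b = 1.2, c = 0.05, d = 1, e = 0.3))
  oracle <- integrate(function(u) fourpl(10^u, fit2$b, fit2$c, fit2$d,
                                         fit2$e),
                      -2, 2, rel.tol = 1e-10)$value / 4
  expect_equal(standardized_auc(fit2, c(1e-2, 1e2)), oracle,
               tolerance = 1e-6)
  # rescaling the dose unit leaves the standardised AUC unchanged
  fit_nm <- fit_4pl(doses * 1000,
                    fourpl(doses, b = 1.2, c = 0.05, d = 1, e = 0.3))
  expect_equal(standardized_auc(fit_nm, c(1e-2, 1e2) * 1000),
               standardized_auc(fit2, c(1e-2, 1e2)), tolerance = 1e-4)
  expect_error(standardized_auc(fit2, c(1, 1)), "x_min < x_max")
})

test_that("AUC is monotone in pointwise viability", {
  doses <- 10^seq(-2, 2, length.out = 10)
  set.seed(7)
  for (i in 1:10) {
    e1 <- 10^runif(1, -1, 1)
    hi <- fit_4pl(doses, fourpl(doses, 1.5, 0.1, 1, e1))
    lo <- fit_4pl(doses, fourpl(doses, 1.5, 0.02, 0.9, e1))
    expect_gte(standardized_auc(hi), standardized_auc(lo))
  }
})

test_that("potency filter counts effective kinase inhibitors", {
  auc <- matrix(c(0.8, 0.95, 0.5, 0.85), 2,
                dimnames = list(c("KI_A", "KI_B"), c("L1", "L2")))
  ec50 <- matrix(c(0.05, 0.05, 0.02, 0.5), 2, dimnames = dimnames(auc))
  mi <- matrix(c(0.9, 0.6, 0.8, 0.7), 2, dimnames = dimnames(auc))
  resp <- structure(list(auc = auc, ec50 = ec50, max_inhibition = mi,
                         fits = list()), class = "drug_response")
  counts <- potency_filter(resp, c(KI_A = TRUE, KI_B = TRUE))
  # L1: KI_A passes all three, KI_B fails AUC; L2: KI_A passes, KI_B fails EC50
  expect_equal(counts, c(L1 = 1L, L2 = 1L), ignore_attr = FALSE)
  # excluding KI_A from the KI class drops it
  counts2 <- potency_filter(resp, c(KI_A = FALSE, KI_B = TRUE))
  expect_equal(unname(counts2), c(0L, 0L))
})

test_that("potency filter recovers planted effective-drug counts", {
  cfg <- panel_config(n_cell_lines = 6, n_proteins = 200, n_psites = 300,
                      n_kinases = 8, n_drugs = 6, n_active_pairs = 3,
                      doses = 10^seq(-3, 1, length.out = 10),
                      ed50_sensitization = 1e4,
                      signal_noise_frac = 0, missing_rate = 0, seed = 21)
  panel <- generate_panel(cfg)
  resp <- fit_screen(panel$screen)
  truth <- panel$truth
  is_ki <- setNames(lengths(truth$drug_targets[rownames(resp$auc)]) > 0,
                    rownames(resp$auc))
  counts <- potency_filter(resp, is_ki)
  expected <- vapply(colnames(resp$auc), function(cl) {
    sum(vapply(names(truth$drug_targets), function(dg) {
      is_ki[[dg]] &&
        truth$true_curves$e[truth$true_curves$drug == dg &
                              truth$true_curves$cell_line == cl] < 0.1 &&
        truth$true_auc[dg, cl] < 0.9
    }, logical(1)))
  }, integer(1))
  expect_equal(counts[names(expected)], expected)
})

test_that("Z-prime follows its closed form and sign behaviour", {
  # noiseless controls: Z' = 1
  expect_equal(zprime(c(1, 1, 1), c(9, 9, 9)), 1)
  # hand-computed: mu+ = 0, mu- = 10, sd = 0.5 each -> 1 - 3*(0.5+0.5)/10
  half <- 0.25 * sqrt(2)            # two points at +/-half have sd 0.5
  pos <- c(-half, half); neg <- 10 + c(-half, half)
  expect_equal(sd(pos), 0.5)
  expect_equal(zprime(pos, neg), 0.7, tolerance = 1e-12)
  # overlapping controls go negative
  set.seed(3)
  expect_lt(zprime(rnorm(20, 0, 5), rnorm(20, 1, 5)), 0)
  expect_error(zprime(c(1, 1), c(1, 1)), "identical")
  expect_error(zprime(1, c(1, 2)), "at least 2")
})
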