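make_ann <- function(kinases, loops = list(), subs = list()) {
  annotation_set(kinase_ids = kinases, activation_loop_sites = loops,
                 substrate_sites = subs)
}

test_that("layer (a) standardises kinase abundance rows", {
  prot <- toy_matrix(rbind(c(1, 2, 3), c(5, 5, 5), c(9, 1, 2)),
                     feats = c("KIN1", "KIN2", "PROT1"), scale = "log10")
  za <- layer_a_kinase_abundance(prot, make_ann(c("KIN1", "KIN2", "KIN9")))
  # (1,2,3) under the sample-SD convention -> (-1, 0, 1)
  expect_equal(unname(za["KIN1", ]), c(-1, 0, 1))
  # constant rows get z = 0, keeping the layer available
  expect_equal(unname(za["KIN2", ]), c(0, 0, 0))
  # kinases never quantified stay missing; non-kinases are not rows
  expect_true(all(is.na(za["KIN9", ])))
  expect_false("PROT1" %in% rownames(za))
})

test_that("layers (b)-(d) sum linear site intensities then log-standardise", {
  sites <- toy_matrix(rbind(c(1e5, 2e5, 4e5),
                            c(3e5, NA, 1e5),
                            c(2e4, 2e4, NA)),
                      feats = c("KIN1_S10", "KIN1_T20", "OTHER_S5"),
                      scale = "linear")
  ann <- make_ann("KIN1",
                  loops = list(KIN1 = "KIN1_S10"),
                  subs = list(KIN1 = c("OTHER_S5")))
  zb_raw <- proteoscreen:::sum_sites_log10(sites,
                                           list(KIN1 = c("KIN1_S10",
                                                         "KIN1_T20")),
                                           "KIN1")
  # missing site treated as 0 when the other site is observed
  expect_equal(unname(zb_raw["KIN1", ]), log10(c(4e5, 2e5, 5e5)))
  zb <- layer_b_kinase_phospho(sites, ann)
  expect_equal(mean(zb["KIN1", ]), 0, tolerance = 1e-12)
  expect_equal(sd(zb["KIN1", ]), 1, tolerance = 1e-12)
  # layer c restricted to the loop site; single site reduces to its profile
  zc <- layer_c_activation_loop(sites, ann)
  prof <- log10(c(1e5, 2e5, 4e5))
  expect_equal(unname(zc["KIN1", ]),
               unname((prof - mean(prof)) / sd(prof)))
  # layer d over substrates; all-missing sample stays missing
  zd <- layer_d_substrates(sites, ann)
  expect_true(is.na(zd["KIN1", 3]))
})

test_that("layer combination enforces the abundance-plus-evidence rule", {
  dn <- list(c("K1", "K2", "K3", "K4"), c("A", "B"))
  mk <- function(v) matrix(v, 4, 2, dimnames = dn, byrow = TRUE)
  a <- mk(c(1, 1,  1, 1,  NA, NA, 1, 1))
  b <- mk(c(1, 1,  NA, NA, 1, 1,  NA, NA))
  cc <- mk(c(1, 1,  NA, NA, NA, NA, NA, NA))
  d <- mk(c(1, 1,  1, 1,  1, 1,  NA, NA))
  land <- combine_activity_layers(a, b, cc, d)
  # all four layers -> additive score of 4
  expect_equal(land$score["K1", "A"], 4)
  expect_equal(land$n_layers["K1", "A"], 4L)
  # a + d only
  expect_equal(land$score["K2", "A"], 2)
  expect_equal(land$layer_mask["K2", "A"], "ad")
  # no abundance -> no score, even with phospho evidence
  expect_true(is.na(land$score["K3", "A"]))
  # abundance alone does not suffice; reported in a_only
  expect_true(is.na(land$score["K4", "A"]))
  expect_true(all(c("K4") %in% land$a_only$kinase))
})

test_that("activity scores ignore per-sample additive proteome offsets", {
  panel <- generate_panel(panel_config(n_cell_lines = 5, n_proteins = 300,
                                       n_psites = 600, n_kinases = 10,
                                       n_drugs = 4, n_active_pairs = 3,
                                       missing_rate = 0, seed = 31))
  # median-centring (the documented precondition of layer a) absorbs
  # per-sample additive offsets, so the landscape is offset-invariant
  prot <- to_log10(panel$proteome)
  land1 <- kinase_activity(median_center(prot), panel$phospho,
                           panel$annotations)
  shifted <- prot
  shifted$values[, 2] <- shifted$values[, 2] + 0.9
  land2 <- kinase_activity(median_center(shifted), panel$phospho,
                           panel$annotations)
  expect_equal(land1$score, land2$score, tolerance = 1e-9)
})

test_that("z-layer rows have mean 0 and unit SD over observed entries", {
  panel <- generate_panel(panel_config(n_cell_lines = 6, n_proteins = 300,
                                       n_psites = 600, n_kinases = 10,
                                       n_drugs = 4, n_active_pairs = 3,
                                       seed = 32))
  za <- layer_a_kinase_abundance(preprocess_matrix(panel$proteome,
                                                   impute = FALSE),
                                 panel$annotations)
  for (i in seq_len(nrow(za))) {
    r <- za[i, !is.na(za[i, ])]
    if (length(r) < 2 || sd(r) == 0) next
    expect_equal(mean(r), 0, tolerance = 1e-9)
    expect_equal(sd(r), 1, tolerance = 1e-9)
  }
})

test_that("planted active kinases top the per-line rankings", {
  panel <- generate_panel(panel_config(seed = 41))
  prot <- preprocess_matrix(panel$proteome, impute = FALSE)
  land <- kinase_activity(prot, panel$phospho, panel$annotations)
  for (cl in names(panel$truth$active_kinases)) {
    rk <- rank_kinases(land, cl)
    expect_lte(match(panel$truth$active_kinases[[cl]], rk$kinase), 5L)
  }
  # druggable-only ranking is a subset
  rk_all <- rank_kinases(land, "CL01")
  rk_dr <- rank_kinases(land, "CL01", panel$annotations,
                        druggable_only = TRUE)
  expect_true(all(rk_dr$kinase %in% panel$annotations$druggable_kinases))
  expect_true(all(rk_dr$kinase %in% rk_all$kinase))
  expect_error(rank_kinases(land, "NOSUCH"), "unknown cell line")
})
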