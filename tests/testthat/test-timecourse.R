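tc_grid <- c(0, 5, 10, 15, 30, 90, 180, 360, 720, 1440)

test_that("channel normalisation equalises medians multiplicatively", {
  set.seed(61)
  m <- matrix(10^runif(50, 4, 7), 10, 5,
              dimnames = list(paste0("F", 1:10), paste0("ch", 1:5)))
  norm <- normalize_channels(m)
  med <- apply(norm, 2, median)
  expect_lt(diff(range(med)), 1e-9 * med[1])
  # pre-equalised input is untouched
  eq <- sweep(m, 2, apply(m, 2, median), "/")
  expect_equal(normalize_channels(eq), eq, tolerance = 1e-12)
  # doubling one channel is undone up to the overall scale: relative to any
  # untouched channel, the doubled one is rescaled by exactly 0.5
  m2 <- norm; m2[, 3] <- m2[, 3] * 2
  renorm <- normalize_channels(m2)
  expect_equal(renorm[, 3] / renorm[, 1], norm[, 3] / norm[, 1],
               tolerance = 1e-12)
  m3 <- m; m3[, 2] <- NA
  expect_error(normalize_channels(m3), "no observed values")
})

test_that("oxidation stripping collapses duplicates, preserving phospho", {
  m <- rbind("PEPT(ox)IDE" = c(10, 20),
             "PEPTIDE" = c(1, 2),
             "PES(ph)TIDE" = c(5, NA),
             "OTHER" = c(NA, 7))
  colnames(m) <- c("A", "B")
  out <- collapse_modified_sequences(m)
  expect_equal(nrow(out), 3L)
  expect_equal(unname(out["PEPTIDE", ]), c(11, 22))
  expect_true("PES(ph)TIDE" %in% rownames(out))
  # all-missing channels stay missing after the merge
  expect_true(is.na(out["OTHER", "A"]))
  # no duplicates: identity up to row order
  single <- m[2:4, ]
  expect_equal(collapse_modified_sequences(single),
               single[order(rownames(single)), ])
})

test_that("t0 ratios are exactly 1 and unusable t0 rows are dropped", {
  set.seed(62)
  m <- matrix(10^runif(30, 4, 6), 3, 10,
              dimnames = list(paste0("F", 1:3), NULL))
  m[2, 1] <- NA
  expect_warning(tc <- ratios_vs_t0(m, tc_grid), "dropped")
  expect_equal(attr(tc, "dropped"), "F2")
  expect_equal(unname(tc$ratios[, "0"]), rep(1, 2))
  # a flat profile stays at ratio 1
  flat <- matrix(5e5, 1, 10, dimnames = list("FLAT", NULL))
  tcf <- ratios_vs_t0(flat, tc_grid)
  expect_equal(unname(tcf$ratios[1, ]), rep(1, 10))
})

test_that("internal gaps interpolate linearly in time and rank by |log2|", {
  r <- matrix(1, 2, 10, dimnames = list(c("gap", "flat"), NULL))
  r["gap", ] <- c(1, 1, 1, 1, 2, NA, 6, 1, 1, 1)  # missing at 90 min
  tc <- structure(list(ratios = r, time_min = tc_grid),
                  class = "timecourse_matrix")
  colnames(tc$ratios) <- as.character(tc_grid)
  ranked <- interpolate_and_rank(tc)
  interp <- attr(ranked, "interpolated")
  # linear in t between 30 min (value 2) and 180 min (value 6)
  expect_equal(interp["gap", "90"], 2 + (6 - 2) * (90 - 30) / (180 - 30))
  # flat feature sorts last
  expect_equal(ranked$feature[nrow(ranked)], "flat")
  # 4-fold-down outranks 2-fold-up
  r2 <- matrix(1, 2, 10, dimnames = list(c("down4", "up2"), NULL))
  r2["down4", 7] <- 0.25
  r2["up2", 7] <- 2
  tc2 <- structure(list(ratios = r2, time_min = tc_grid),
                   class = "timecourse_matrix")
  colnames(tc2$ratios) <- as.character(tc_grid)
  expect_equal(interpolate_and_rank(tc2)$feature[1], "down4")
})

test_that("regulation calls use strict two-fold boundaries", {
  r <- matrix(1, 4, 10,
              dimnames = list(c("down", "edge_lo", "edge_hi", "up"), NULL))
  r["down", 5] <- 0.45
  r["edge_lo", 5] <- 0.5   # exactly two-fold: not regulated
  r["edge_hi", 5] <- 2     # exactly two-fold: not regulated
  r["up", 5] <- 2.05
  tc <- structure(list(ratios = r, time_min = tc_grid),
                  class = "timecourse_matrix")
  colnames(tc$ratios) <- as.character(tc_grid)
  calls <- call_regulated(tc)
  expect_setequal(calls$feature, c("down", "up"))
  expect_equal(calls$direction[calls$feature == "down"], "down")
  expect_equal(calls$direction[calls$feature == "up"], "up")
})

test_that("generated time courses reproduce planted plateaus and nulls", {
  tc <- generate_timecourse(n_features = 100, n_regulated = 15,
                            noise_sd_log2 = 0.05, seed = 63)
  ratios <- ratios_vs_t0(normalize_channels(tc$treated), tc$time_min)
  # terminal treated-arm ratio approximates the planted fold change
  term <- ratios$ratios[tc$truth$feature, "1440"]
  expect_equal(unname(log2(term)), tc$truth$plateau_log2, tolerance = 0.35)
  # vehicle arm is flat: no feature crosses two-fold
  veh <- ratios_vs_t0(normalize_channels(tc$vehicle), tc$time_min)
  expect_equal(nrow(call_regulated(veh)), 0L)
  # noiseless recovery is exact
  tc0 <- generate_timecourse(n_features = 80, n_regulated = 10,
                             noise_sd_log2 = 0, seed = 64)
  r0 <- ratios_vs_t0(tc0$treated, tc0$time_min)
  calls <- call_regulated(r0)
  expect_setequal(calls$feature, tc0$truth$feature)
  got <- calls$direction[match(tc0$truth$feature, calls$feature)]
  expect_equal(got, tc0$truth$direction)
})

test_that("early-response features peak early with monotone curves", {
  tc <- generate_timecourse(n_features = 60, n_regulated = 8,
                            noise_sd_log2 = 0, seed = 65)
  ratios <- ratios_vs_t0(tc$treated, tc$time_min)
  l2 <- log2(ratios$ratios[tc$truth$feature, , drop = FALSE])
  # exponential approach: |log2 ratio| is non-decreasing in time
  for (i in seq_len(nrow(l2)))
    expect_true(all(diff(abs(l2[i, ])) >= -1e-9))
  # fast features (small tau) are already half-saturated at 30 min
  fast <- tc$truth$tau_min < 40
  half <- abs(l2[fast, "30", drop = TRUE]) /
    abs(tc$truth$plateau_log2[fast])
  expect_true(all(half >= 0.5))
})
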