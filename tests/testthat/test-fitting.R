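test_that("an exactly representable spectrum is recovered with zero residual", {
  ref <- test_sbs_reference()
  counts <- 1000 * ref$matrix[, "SBS17b"]
  f <- fit_exposures(setNames(counts, rownames(ref$matrix)), ref)
  expect_equal(unname(f$exposures["SBS17b"]), 1)
  expect_true(all(f$exposures[setdiff(names(f$exposures), "SBS17b")] == 0))
  expect_lt(f$residual, 1e-6)
})

test_that("a planted two-signature mixture matches the grid-search oracle", {
  ref <- test_sbs_reference()
  a <- ref$matrix[, "SBS17b"]; b <- ref$matrix[, "SBS1"]
  set.seed(1)
  counts <- as.numeric(stats::rmultinom(1, 10000, 0.7 * a + 0.3 * b))
  f <- fit_exposures(setNames(counts, rownames(ref$matrix)),
                     new_signature_reference(cbind(SBS17b = a, SBS1 = b), "sbs96"))
  expect_lt(abs(f$exposures["SBS17b"] - 0.7), 0.03)
  w_oracle <- oracle_two_sig_weight(counts / sum(counts), a, b)
  expect_lt(abs(f$exposures["SBS17b"] - w_oracle), 0.011)
})

test_that("contributions below 5% are zeroed and the fit renormalized", {
  ref <- test_sbs_reference()
  a <- ref$matrix[, "SBS17b"]; b <- ref$matrix[, "SBS1"]; c3 <- ref$matrix[, "SBS18"]
  v <- 0.93 * a + 0.04 * b + 0.03 * c3
  f <- fit_exposures(setNames(round(v * 1e5), rownames(ref$matrix)),
                     new_signature_reference(cbind(SBS17b = a, SBS1 = b,
                                                   SBS18 = c3), "sbs96"))
  expect_equal(unname(f$exposures["SBS1"]), 0)
  expect_equal(unname(f$exposures["SBS18"]), 0)
  expect_equal(unname(f$exposures["SBS17b"]), 1)
})

test_that("thresholded refits are idempotent", {
  ref <- test_sbs_reference()
  set.seed(3)
  mix <- 0.5 * ref$matrix[, "SBS17b"] + 0.3 * ref$matrix[, "SBS1"] +
    0.2 * ref$matrix[, "SBS18"]
  counts <- as.numeric(stats::rmultinom(1, 5000, mix))
  f1 <- fit_exposures(setNames(counts, rownames(ref$matrix)), ref)
  recon <- ref$matrix %*% f1$exposures
  f2 <- fit_exposures(setNames(round(recon * 1e6), rownames(ref$matrix)), ref)
  expect_equal(names(which(f2$exposures > 0)), names(which(f1$exposures > 0)))
})

test_that("residual does not increase when the true signatures are a reference subset", {
  ref <- test_sbs_reference()
  small <- new_signature_reference(ref$matrix[, c("SBS17b", "SBS1")], "sbs96")
  set.seed(9)
  counts <- as.numeric(stats::rmultinom(1, 5000,
                                        0.6 * ref$matrix[, "SBS17b"] +
                                          0.4 * ref$matrix[, "SBS1"]))
  f_small <- fit_exposures(setNames(counts, rownames(ref$matrix)), small)
  f_full <- fit_exposures(setNames(counts, rownames(ref$matrix)), ref)
  expect_lte(f_full$residual, f_small$residual + 1e-9)
})

test_that("cohort fitting is row-wise, deterministic, and handles empty rows", {
  ref <- test_sbs_reference()
  g <- test_genome()
  tr <- truth_record("S1", exposures = list(all = c(SBS17b = 0.6, SBS1 = 0.4)))
  sim <- simulate_sample(g, tr, n_snvs = 2000, seed = 4)
  cat1 <- build_catalogue(sim$variants, g, "sbs96")
  cat2 <- dplyr::bind_rows(cat1, dplyr::mutate(cat1, sample = "S2"))
  fit <- fit_cohort(cat2, ref)
  expect_equal(nrow(fit), 2)
  expect_equal(fit$SBS17b[1], fit$SBS17b[2])  # identical rows, identical fits
  zero <- cat1
  zero[1, -1] <- 0L
  f0 <- fit_cohort(zero, ref)
  expect_equal(f0$flag, "empty")
  expect_true(all(as.numeric(f0[1, attr(f0, "signatures")]) == 0))
})

test_that("deficiency calls follow the >5 percent conjunction rules", {
  sbs <- tibble::tibble(sample = c("a", "b", "c"),
                        n_mutations = 1000, residual = 0, flag = "ok",
                        SBS3 = c(0.06, 0.06, 0.01), SBS8 = c(0.06, 0.06, 0.01),
                        SBS41 = c(0.06, 0.01, 0.01), SBS44 = c(0.04, 0.06, 0.01))
  attr(sbs, "signatures") <- c("SBS3", "SBS8", "SBS41", "SBS44")
  class(sbs) <- c("exposure_table", class(sbs))
  id <- tibble::tibble(sample = c("a", "b", "c"),
                       n_mutations = 100, residual = 0, flag = "ok",
                       ID6 = c(0.07, 0.04, 0.01), ID8 = c(0.06, 0.06, 0.01),
                       ID18 = c(0.08, 0.01, 0.01))
  attr(id, "signatures") <- c("ID6", "ID8", "ID18")
  class(id) <- c("exposure_table", class(id))
  calls <- call_deficiencies(sbs, id)
  expect_equal(calls$HRD, c(TRUE, FALSE, FALSE))         # b fails ID6
  expect_equal(calls$colibactin, c(TRUE, FALSE, FALSE))  # SBS41 + ID18 both > 5%
  expect_equal(calls$MMRd, c(FALSE, TRUE, FALSE))        # 0.04 is below threshold
  expect_error(call_deficiencies(sbs, NULL), "absent")
})
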