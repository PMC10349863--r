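test_that("CCF and multiplicity follow the purity/copy-number arithmetic", {
  seg <- tibble::tibble(sample_id = "S1", chrom = "chr1", start = 0L,
                        end = 10000L, n_major = 1L, n_minor = 1L)
  v <- make_variants("S1", "chr1", 100L, "A", "T",
                     alt_reads = 25L, ref_reads = 75L)   # vaf 0.25
  r <- ccf_and_multiplicity(v, seg, c(S1 = 1.0))
  expect_equal(r$multiplicity, 1L)
  expect_equal(r$ccf, 0.5)
  seg2 <- dplyr::mutate(seg, n_major = 2L, n_minor = 2L)
  v2 <- make_variants("S1", "chr1", 100L, "A", "T",
                      alt_reads = 50L, ref_reads = 50L)  # vaf 0.5
  r2 <- ccf_and_multiplicity(v2, seg2, c(S1 = 1.0))
  expect_equal(r2$multiplicity, 2L)
  expect_equal(r2$ccf, 1.0)
  v3 <- make_variants("S1", "chr1", 100L, "A", "T",
                      alt_reads = 20L, ref_reads = 80L)  # vaf 0.2, purity 0.8
  r3 <- ccf_and_multiplicity(v3, seg, c(S1 = 0.8))
  expect_equal(r3$multiplicity, 1L)
  expect_equal(r3$ccf, 0.5)
  # variant outside any segment is flagged
  v4 <- make_variants("S1", "chr1", 99999L, "A", "T")
  r4 <- ccf_and_multiplicity(v4, seg, c(S1 = 0.8))
  expect_true(r4$no_cn)
})

test_that("the dip statistic matches the brute-force mode-enumeration oracle", {
  set.seed(21)
  cases <- c(
    lapply(1:6, function(i) runif(5)),
    lapply(1:6, function(i) rnorm(8)),
    list(c(0.1, 0.1, 0.5, 0.9, 0.9), c(1, 2, 3, 4, 5), rep(0.3, 6),
         c(rnorm(6, 0, 0.1), rnorm(6, 3, 0.1)))
  )
  for (x in cases)
    expect_equal(dip_stat(x), oracle_dip(x), tolerance = 1e-9)
})

test_that("the dip test separates bimodal from unimodal CCF distributions", {
  set.seed(11)
  bim <- c(rnorm(500, 0.3, 0.02), rnorm(500, 0.9, 0.02))
  expect_lt(dip_test(bim, n_ref = 500, seed = 11)$p, 0.01)
  uni <- rnorm(1000, 0.5, 0.1)
  expect_gt(dip_test(uni, n_ref = 500, seed = 11)$p, 0.05)
  short <- dip_test(rnorm(5), n_ref = 100)
  expect_equal(short$flag, "insufficient-n")
  expect_false(short$is_multimodal)
})

test_that("the two-component mixture recovers planted clusters and labels", {
  set.seed(2)
  x <- c(rnorm(1200, 1.0, 0.08), rnorm(800, 0.4, 0.08))
  truth_sub <- rep(c(FALSE, TRUE), c(1200, 800))
  fit <- fit_subclonal_mixture(x)
  expect_equal(fit$flag, "ok")
  expect_lt(abs(fit$means[1] - 1.0), 0.05)
  expect_lt(abs(fit$means[2] - 0.4), 0.05)
  expect_lt(abs(fit$subclonal_fraction - 0.4), 0.05)
  expect_gt(mean(fit$is_subclonal == truth_sub), 0.9)
  # identical values are degenerate -> fully clonal
  expect_equal(fit_subclonal_mixture(rep(0.8, 100))$flag, "degenerate")
})

test_that("timing labels follow the deterministic multiplicity rules", {
  m <- tibble::tibble(no_cn = c(FALSE, FALSE, FALSE, FALSE, TRUE),
                      n_major = c(2L, 2L, 1L, 2L, NA),
                      multiplicity = c(2L, 1L, 1L, 1L, NA),
                      is_subclonal = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  r <- assign_timing(m)
  expect_equal(r$timing, c("clonal_early", "clonal_late", "clonal_other",
                           "subclonal", "clonal_other"))
})

test_that("WGD status requires both genome fraction and ploidy evidence", {
  seg <- tibble::tibble(sample_id = rep(c("wgd", "dip"), each = 1),
                        chrom = "chr1", start = 0L, end = 1000L,
                        n_major = c(2L, 1L), n_minor = c(2L, 1L))
  w <- wgd_status(seg, c(wgd = 4.0, dip = 2.0))
  expect_equal(w$wgd[w$sample == "wgd"], TRUE)
  expect_equal(w$wgd[w$sample == "dip"], FALSE)
  # high fraction but ploidy below 2.9 is not WGD
  w2 <- wgd_status(seg[1, ], c(wgd = 2.5))
  expect_false(w2$wgd)
})

test_that("full clonality analysis labels a two-clone sample correctly", {
  g <- test_genome()
  tr <- truth_record("S1", purity = 0.9,
                     exposures = list(all = c(SBS17b = 1)),
                     clone_table = tibble::tibble(ccf = c(1, 0.4),
                                                  fraction = c(0.6, 0.4)))
  sim <- simulate_sample(g, tr, n_snvs = 2000, depth = 60, seed = 6)
  cl <- analyze_clonality(sim$variants, sim$segments, sim$purity_table,
                          n_ref = 400, seed = 1)
  expect_true(cl$samples$is_multimodal)
  expect_lt(abs(cl$samples$subclonal_fraction - 0.4), 0.08)
  agree <- mean((cl$mutations$timing == "subclonal") ==
                  (cl$mutations$compartment == "subclonal"))
  expect_gt(agree, 0.9)
  # labels partition all mutations
  expect_true(all(cl$mutations$timing %in%
                    c("clonal_early", "clonal_late", "clonal_other", "subclonal")))
  expect_equal(nrow(cl$mutations), nrow(sim$variants))
})
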