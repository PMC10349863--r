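test_that("stacking geometry follows the offset conventions", {
  dyads <- tibble::tibble(chrom = "chr1", pos = c(1000L, 1144L))
  # one mutation at a dyad centre
  s1 <- stack_mutations(tibble::tibble(chrom = "chr1", pos = 1000L), dyads, 72L)
  expect_equal(unname(s1[as.character(0) == names(s1)]), 1)
  expect_equal(sum(s1), 1)
  # equidistant between two dyads 144 bp apart: offsets +72 and -72
  s2 <- stack_mutations(tibble::tibble(chrom = "chr1", pos = 1072L), dyads, 72L)
  expect_equal(unname(s2[names(s2) == "72"]), 1)
  expect_equal(unname(s2[names(s2) == "-72"]), 1)
  expect_equal(sum(s2), 2)
})

test_that("uniform mutations give a flat profile within Poisson bounds", {
  g <- test_genome()
  set.seed(9)
  pos <- sample.int(g$chrom_lengths[[1]] - 200L, 10000L) + 100L
  s <- stack_mutations(tibble::tibble(chrom = "chr1", pos = pos), g$dyads, 72L)
  lambda <- mean(s)
  expect_true(all(s < lambda + 5 * sqrt(lambda)))
  expect_true(all(s > lambda - 5 * sqrt(lambda)))
})

test_that("pentamer randomization conserves the pentamer multiset exactly", {
  g <- test_genome()
  tr <- truth_record("S1", exposures = list(all = c(SBS17b = 0.7, SBS18 = 0.3)))
  sim <- simulate_sample(g, tr, n_snvs = 500, restrict_to_dyads = TRUE, seed = 3)
  sn <- classify_snvs(sim$variants, g)
  set.seed(1)
  rp <- randomize_pentamer(sn, g, window = 72L)
  new_pent <- mutsigdyn:::canonical_context(g$sequences[[1]], rp$pos, 2L)
  expect_equal(sort(new_pent), sort(sn$pentamer))
})

test_that("randomization is the identity when a pentamer has one candidate", {
  g <- genome_from_sequences(c(chr1 = paste0(strrep("A", 60), "TTCAG",
                                             strrep("A", 60))),
                             dyads = tibble::tibble(chrom = "chr1", pos = 62L))
  v <- make_variants("S1", "chr1", 63L, "C", "T")
  sn <- classify_snvs(v, g)
  rp <- randomize_pentamer(sn, g, window = 30L)
  expect_equal(rp$pos, 62L)  # the unique TTCAG centre
})

test_that("the periodogram resolves a pure tone and matches the direct sum", {
  x <- seq(-72, 72)
  r <- cos(2 * pi * x / 10)
  pg <- periodogram(r, x)
  expect_lt(abs(pg$max_power_period - 10.0), 0.011)
  # noisy tone
  set.seed(4)
  pg2 <- periodogram(r + rnorm(length(x), 0, 0.2), x)
  expect_lt(abs(pg2$max_power_period - 10.0), 0.2)
  # direct-sum oracle at 20 grid points
  probe <- pg$period[seq(1, length(pg$period), length.out = 20)]
  expect_equal(pg$power[match(probe, pg$period)],
               oracle_power(r, x, probe), tolerance = 1e-9)
})

test_that("the periodogram is invariant to constant shifts (mean-centring)", {
  x <- seq(-72, 72)
  set.seed(8)
  r <- cos(2 * pi * x / 10.3) + rnorm(length(x), 0, 0.1)
  p1 <- periodogram(r, x)
  p2 <- periodogram(r + 5, x)
  expect_equal(p1$power, p2$power, tolerance = 1e-9)
  expect_equal(p1$max_power_period, p2$max_power_period)
})

test_that("all-masked profiles are an error", {
  expect_error(periodogram(rep(NA_real_, 145)), "masked")
})

test_that("a planted periodic signal yields a small empirical p, a flat null does not", {
  g <- test_genome()
  tr <- truth_record("S1", exposures = list(all = c(SBS17b = 1)))
  sim <- simulate_sample(g, tr, n_snvs = 6000,
                         periodic_config = list(signature = "SBS17b",
                                                period = 10.3, amplitude = 0.6),
                         restrict_to_dyads = TRUE, seed = 13)
  sn <- classify_snvs(sim$variants, g)
  res <- nucleosome_periodicity(sn, g, window = 72L, n_rand = 150, seed = 13)
  expect_lt(res$p, 0.01)
  expect_lt(abs(res$max_power_period - 10.3), 0.3)
  # non-periodic sample from the same generative process
  sim0 <- simulate_sample(g, tr, n_snvs = 6000, restrict_to_dyads = TRUE,
                          seed = 14)
  sn0 <- classify_snvs(sim0$variants, g)
  res0 <- nucleosome_periodicity(sn0, g, window = 72L, n_rand = 150, seed = 14)
  expect_gt(res0$p, 0.05)
})
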