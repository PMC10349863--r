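test_that("simulated variant counts and channels match the request exactly", {
  g <- test_genome()
  tr <- truth_record("S1", exposures = list(all = c(SBS17b = 0.5, SBS1 = 0.5)),
                     id_exposures = list(all = c(ID1 = 0.5, ID2 = 0.5)))
  sim <- simulate_sample(g, tr, n_snvs = 800, n_indels = 30, seed = 1)
  expect_equal(sum(sim$variants$kind == "snv"), 800)
  expect_equal(sum(sim$variants$kind != "snv"), 30)
  # emitted SNVs classify to exactly the channel they were drawn from
  cl <- classify_snvs(sim$variants, g)
  drawn <- sim$variants$channel[sim$variants$kind == "snv"]
  expect_equal(cl$channel, drawn)
  # emitted indels classify to their drawn ID-83 channel
  ci <- classify_indels(sim$variants, g)
  expect_equal(ci$channel, sim$variants$channel[sim$variants$kind != "snv"])
})

test_that("simulation is deterministic given the seed", {
  g <- test_genome()
  tr <- truth_record("S1", exposures = list(all = c(SBS17b = 1)))
  s1 <- simulate_sample(g, tr, n_snvs = 300, seed = 5)
  s2 <- simulate_sample(g, tr, n_snvs = 300, seed = 5)
  expect_identical(s1$variants, s2$variants)
})

test_that("clonal multiplicity-1 VAF in a 1+1 region has expectation purity/2", {
  g <- test_genome()
  rho <- 0.8
  tr <- truth_record("S1", purity = rho, exposures = list(all = c(SBS17b = 1)))
  sim <- simulate_sample(g, tr, n_snvs = 4000, depth = 50, seed = 8)
  v <- sim$variants[sim$variants$multiplicity == 1, ]
  vaf <- v$alt_reads / (v$alt_reads + v$ref_reads)
  se <- sd(vaf) / sqrt(nrow(v))
  expect_lt(abs(mean(vaf) - rho / 2), 4 * se)
})

test_that("mutated positions carry the pentamer context of the sampled channels", {
  g <- test_genome()
  tr <- truth_record("S1", exposures = list(all = c(SBS17b = 1)))
  sim <- simulate_sample(g, tr, n_snvs = 500, seed = 12)
  cl <- classify_snvs(sim$variants, g)
  # the central trinucleotide of every pentamer equals the channel context
  tri_from_pent <- substr(cl$pentamer, 2, 4)
  tri_from_channel <- paste0(substr(cl$channel, 1, 1), substr(cl$channel, 3, 3),
                             substr(cl$channel, 7, 7))
  expect_equal(tri_from_pent, tri_from_channel)
})

test_that("planted copy-number events and pathway hits are reflected in outputs", {
  g <- test_genome()
  ev <- tibble::tibble(chrom = "chr1", start = 10000L, end = 40000L,
                       n_major = 4L, n_minor = 0L)
  hits <- tibble::tibble(gene = g$genes$gene[2], consequence = "missense_variant")
  tr <- truth_record("S1", exposures = list(all = c(SBS17b = 1)),
                     cn_events = ev, pathway_hits = hits)
  sim <- simulate_sample(g, tr, n_snvs = 100, seed = 3)
  seg <- sim$segments
  expect_true(any(seg$n_major == 4 & seg$n_minor == 0 &
                    seg$start == 10000 & seg$end == 40000))
  planted <- sim$variants[sim$variants$planted, ]
  expect_equal(nrow(planted), 1)
  expect_equal(planted$consequence, "missense_variant")
  gi <- g$genes[g$genes$gene == hits$gene, ]
  expect_true(planted$pos - 1 >= gi$start && planted$pos - 1 < gi$end)
  expect_equal(nrow(sim$variants), 101)  # n_snvs + planted hits
})

test_that("cohort simulation writes a deterministic, self-consistent dataset", {
  g <- generate_genome(chrom_length = 2e5, id_sites_per_channel = 10, seed = 2)
  cfg <- default_cohort_config(n_barrett = 2, n_primary = 3, n_metastasis = 1)
  cfg$n_snvs <- 200; cfg$n_indels <- 20
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  c1 <- simulate_cohort(cfg, genome = g, out_dir = d1, seed = 9)
  c2 <- simulate_cohort(cfg, genome = g, out_dir = d2, seed = 9)
  expect_equal(nrow(c1$clinical), 6)
  expect_equal(sort(c1$clinical$stage),
               sort(rep(c("barrett", "primary", "metastasis"), c(2, 3, 1))))
  expect_equal(c1$manifest$md5, c2$manifest$md5)  # same seed, same checksums
  # files round-trip through the readers
  v <- read_vcf(file.path(d1, "S001.vcf"), min_alt_reads = 0)
  expect_equal(nrow(v), nrow(c1$samples$S001$variants))
  seg <- read_segments(file.path(d1, "segments.tsv"))
  expect_equal(nrow(seg), nrow(c1$segments))
  pp <- read_purity_table(file.path(d1, "purity.tsv"))
  expect_equal(pp$purity, c1$purity_table$purity, tolerance = 1e-12)
})
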