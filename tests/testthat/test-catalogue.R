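test_that("canonical channel sets have the expected structure", {
  expect_length(sbs96_channels(), 96)
  expect_length(id83_channels(), 83)
  expect_false(anyDuplicated(sbs96_channels()) > 0)
  expect_false(anyDuplicated(id83_channels()) > 0)
})

test_that("SNV classification folds purines onto the pyrimidine strand", {
  g <- genome_from_sequences(c(chr1 = "ACGTA"))
  # G>A at 1-based position 3: purine reference, reverse-complements to A[C>T]G
  v <- make_variants("S1", "chr1", 3L, "G", "A")
  cl <- classify_snvs(v, g)
  expect_equal(cl$channel, "A[C>T]G")
  expect_equal(cl$pyr_strand, "-")
  # C>T at the centre of TCA: stays T[C>T]A on the plus strand
  g2 <- genome_from_sequences(c(chr1 = "TTCAT"))
  v2 <- make_variants("S1", "chr1", 3L, "C", "T")
  cl2 <- classify_snvs(v2, g2)
  expect_equal(cl2$channel, "T[C>T]A")
  expect_equal(cl2$pyr_strand, "+")
  # reference mismatch is a validation error
  v3 <- make_variants("S1", "chr1", 3L, "G", "A")
  expect_error(classify_snvs(v3, g2), "mismatch")
})

test_that("classifying the reverse-complement description yields the same channel", {
  g <- test_genome()
  seq <- g$sequences[[1]]
  set.seed(5)
  pos <- sample(1000:2000, 50)
  ref <- substring(seq, pos, pos)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  v <- make_variants("S1", "chr1", as.integer(pos), ref, alt)
  cl <- classify_snvs(v, g)
  # the same physical event described from the other strand: a genome with
  # the reverse-complemented sequence and mirrored coordinates
  L <- nchar(seq)
  rc <- function(s) mutsigdyn:::revcomp(s)
  g_rc <- genome_from_sequences(c(chr1 = rc(seq)))
  v_rc <- make_variants("S1", "chr1", as.integer(L - pos + 1L), rc(ref), rc(alt))
  cl_rc <- classify_snvs(v_rc, g_rc)
  expect_equal(cl_rc$channel, cl$channel)
})

test_that("indel classification handles canonical homopolymer, repeat and MH cases", {
  # insertion of T immediately 3' of run TTT -> 1:Ins:T:3
  g <- "GACTTTAGC"
  expect_equal(classify_indel(g, 3L, "C", "CT"), "1:Ins:T:3")
  # deletion of TAG followed by TA (no tandem repeat) -> 3 bp MH length 2
  g2 <- "GCTAGTACCG"
  expect_equal(classify_indel(g2, 2L, "CTAG", "C"), "3:Del:M:2")
  # deletion of one CA from CACACA -> 2 bp repeat-unit deletion, 3 copies
  g3 <- "GGCACACATT"
  expect_equal(classify_indel(g3, 2L, "GCA", "G"), "2:Del:R:2")
})

test_that("indel classification agrees with the brute-force oracle", {
  g <- test_genome()
  s <- g$id_sites
  set.seed(11)
  idx <- sample(nrow(s), 500, replace = nrow(s) < 500)
  for (i in idx) {
    seq <- g$sequences[[s$chrom[i]]]
    expect_identical(classify_indel(seq, s$pos[i], s$ref[i], s$alt[i]),
                     oracle_indel_channel(seq, s$pos[i], s$ref[i], s$alt[i]))
  }
})

test_that("catalogues conserve counts and are additive over samples", {
  g <- test_genome()
  seq <- g$sequences[[1]]
  # 100 T[C>T]A events: find TCA contexts
  pos <- which(vapply(2000:4000, function(p)
    substring(seq, p - 1, p + 1) == "TCA", logical(1))) + 1999L
  pos <- pos[1:20]
  v1 <- make_variants("A", "chr1", as.integer(pos), "C", "T")
  v2 <- make_variants("B", "chr1", as.integer(pos[1:10]), "C", "T")
  cat1 <- build_catalogue(v1, g, "sbs96")
  expect_equal(sum(catalogue_matrix(cat1)), 20)
  expect_equal(unname(catalogue_matrix(cat1)["A", "T[C>T]A"]), 20)
  both <- build_catalogue(dplyr::bind_rows(v1, v2), g, "sbs96")
  expect_equal(colSums(catalogue_matrix(both)),
               catalogue_matrix(cat1)["A", ] +
                 catalogue_matrix(build_catalogue(v2, g, "sbs96"))["B", ])
  # a sample with no classifiable SNV is retained as a zero row
  anchor <- substring(seq, 6000, 6000)
  v3 <- dplyr::bind_rows(v1, make_variants("C", "chr1", 6000L, anchor,
                                           paste0(anchor, "T")))
  cat3 <- build_catalogue(v3, g, "sbs96")
  expect_setequal(cat3$sample, c("A", "C"))
  expect_equal(sum(catalogue_matrix(cat3)["C", ]), 0)
})

test_that("a single-signature sample's catalogue matches the signature", {
  g <- test_genome()
  ref <- test_sbs_reference()
  tr <- truth_record("S1", exposures = list(all = c(SBS17b = 1)))
  sim <- simulate_sample(g, tr, n_snvs = 10000, seed = 5)
  cat1 <- build_catalogue(sim$variants, g, "sbs96")
  row <- catalogue_matrix(cat1)[1, ]
  expect_gte(cosine_sim(row, ref$matrix[, "SBS17b"]), 0.99)
  # total-variation convergence of channel frequencies
  tv <- 0.5 * sum(abs(row / sum(row) - ref$matrix[, "SBS17b"]))
  expect_lt(tv, 0.03)
})

test_that("tmb counts SNVs and indels after the read-support filter", {
  v <- make_variants("S1", "chr1", 1:5 * 10L,
                     c("A", "C", "G", "GAT", "T"),
                     c("T", "G", "GTT", "G", "C"),
                     alt_reads = c(10L, 10L, 10L, 10L, 2L))
  t1 <- tmb(v)
  expect_equal(t1$snvs, 2L)   # the alt=2 SNV is filtered
  expect_equal(t1$indels, 2L)
  expect_equal(t1$total, 4L)
  expect_equal(nrow(tmb(v[0, ])), 0)
})
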