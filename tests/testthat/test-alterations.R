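test_that("gene copy-number classes follow the ploidy-relative rules", {
  genes <- tibble::tibble(chrom = "chr1", start = 100L, end = 200L, gene = "g1")
  seg <- function(maj, min) tibble::tibble(sample_id = "S1", chrom = "chr1",
                                           start = 0L, end = 1000L,
                                           n_major = maj, n_minor = min)
  r <- classify_gene_cn(genes, seg(3L, 1L), c(S1 = 2.0))
  expect_true(r$amp); expect_false(r$del); expect_false(r$loh)
  r2 <- classify_gene_cn(genes, seg(1L, 0L), c(S1 = 2.0))
  expect_false(r2$amp); expect_true(r2$del); expect_true(r2$loh)
  r3 <- classify_gene_cn(genes, seg(1L, 1L), c(S1 = 4.0))
  expect_true(r3$del); expect_false(r3$amp)
  # AMP and DEL cannot co-occur for positive ploidy
  for (m in list(c(5L, 4L), c(1L, 0L), c(2L, 2L)))
    expect_false(with(classify_gene_cn(genes, seg(m[1], m[2]), c(S1 = 2.0)),
                      amp & del))
  # no overlapping segment -> flagged
  far <- tibble::tibble(sample_id = "S1", chrom = "chr2", start = 0L,
                        end = 1000L, n_major = 1L, n_minor = 1L)
  r4 <- classify_gene_cn(genes, far, c(S1 = 2.0))
  expect_true(r4$no_cn); expect_false(r4$amp | r4$del | r4$loh)
})

test_that("gene SNV calls respect the consequence allow-list", {
  genes <- tibble::tibble(chrom = "chr1", start = 100L, end = 200L, gene = "g1")
  v <- make_variants("S1", "chr1", c(150L, 160L, 500L), "A", "T",
                     consequence = c("missense_variant", "synonymous_variant",
                                     "missense_variant"))
  r <- classify_gene_snv(v, genes)
  expect_true(r$snv_indel)                       # missense inside the gene
  r2 <- classify_gene_snv(v[2, ], genes)
  expect_false(r2$snv_indel)                     # synonymous doesn't count
  r3 <- classify_gene_snv(v[3, ], genes)
  expect_false(r3$snv_indel)                     # outside gene bounds
  v_nocsq <- make_variants("S1", "chr1", 150L, "A", "T")
  expect_error(classify_gene_snv(v_nocsq, genes), "consequence")
  expect_true(classify_gene_snv(v_nocsq, genes,
                                ignore_consequence = TRUE)$snv_indel)
})

test_that("pathway matrix unions member genes and orders by deletion fraction", {
  membership <- tibble::tibble(gene = c("g1", "g2", "g3"),
                               pathway = c("BER", "BER", "HR"))
  calls <- tidyr::expand_grid(sample = sprintf("S%02d", 1:10),
                              gene = c("g1", "g2", "g3")) |>
    dplyr::mutate(del = .data$sample %in% c("S01", "S02") & .data$gene == "g1",
                  amp = FALSE)
  pm <- pathway_matrix(calls, membership)
  ber <- pm$fractions[pm$fractions$pathway == "BER", ]
  expect_equal(ber$del, 0.2)
  expect_equal(pm$fractions$pathway[1], "BER")   # ordered by del fraction
  expect_equal(pm$fractions$del[pm$fractions$pathway == "HR"], 0)
  # monotone under adding member genes
  membership2 <- dplyr::bind_rows(membership,
                                  tibble::tibble(gene = "g3", pathway = "BER"))
  calls2 <- dplyr::mutate(calls, del = .data$del |
                            (.data$sample == "S03" & .data$gene == "g3"))
  pm2 <- pathway_matrix(calls2, membership2)
  expect_gte(pm2$fractions$del[pm2$fractions$pathway == "BER"], ber$del)
  # unknown gene warned and ignored
  calls3 <- dplyr::bind_rows(calls, tibble::tibble(sample = "S01", gene = "gX",
                                                   del = TRUE, amp = FALSE))
  expect_warning(pathway_matrix(calls3, membership), "not in the membership")
})

test_that("CIN counts large ploidy-divergent segments and Z-scales", {
  lens <- c(chr1 = 100e6)
  seg <- tibble::tibble(
    sample_id = c("a", "a", "b", "c"),
    chrom = "chr1",
    start = c(0L, 10e6L, 0L, 0L) |> as.integer(),
    end = c(6e6L, 14e6L, 100e6L, 6e6L) |> as.integer(),
    n_major = c(2L, 2L, 1L, 1L), n_minor = c(1L, 1L, 1L, 1L))
  r <- cin_score(seg, c(a = 2, b = 2, c = 2), lens)
  expect_equal(r$cin_raw[r$sample == "a"], 1)  # 6 Mb gain counts, 4 Mb does not
  expect_equal(r$cin_raw[r$sample == "b"], 0)  # 1+1 at ploidy 2 is normal
  expect_equal(mean(r$cin_z), 0, tolerance = 1e-12)
  expect_equal(sd(r$cin_z), 1, tolerance = 1e-12)
  # all-normal cohort has zero variance -> z defined as 0
  r0 <- cin_score(seg[3, ], c(b = 2), lens)
  expect_equal(r0$cin_z, 0)
})

test_that("proliferation score is 1 minus the mean marker Z-score", {
  set.seed(17)
  expr <- tibble::tibble(sample = sprintf("S%02d", 1:20),
                         m1 = rnorm(20), m2 = rnorm(20), other = rnorm(20))
  r <- proliferation_score(expr, c("m1", "m2"))
  expect_equal(mean(r$proliferation), 1, tolerance = 1e-9)
  # QS equals the mean marker Z-score computed directly
  z <- scale(as.matrix(expr[c("m1", "m2")]))
  expect_equal(r$qs, unname(rowMeans(z)), tolerance = 1e-9)
  # planted arrested group anti-correlates with the score
  arrested <- rep(c(TRUE, FALSE), each = 10)
  expr3 <- tibble::tibble(sample = sprintf("S%02d", 1:20),
                          m1 = rnorm(20, ifelse(arrested, 2, 0), 0.3),
                          m2 = rnorm(20, ifelse(arrested, 2, 0), 0.3))
  r3 <- proliferation_score(expr3, c("m1", "m2"))
  expect_lt(mean(r3$proliferation[arrested]), mean(r3$proliferation[!arrested]))
  expect_warning(proliferation_score(expr3, c("m1", "missing_marker")), "missing")
  expect_error(proliferation_score(expr3, "absent"), "none of")
})
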