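make_exposure_table <- function(samples, n_mutations, ...) {
  sigs <- list(...)
  tab <- tibble::tibble(sample = samples, n_mutations = n_mutations,
                        residual = 0, flag = "ok", !!!sigs)
  attr(tab, "signatures") <- names(sigs)
  class(tab) <- c("exposure_table", class(tab))
  tab
}

test_that("subclonal shifts are the per-signature exposure differences", {
  cl <- make_exposure_table(c("a", "b"), c(1000, 30),
                            SBS17b = c(0.40, 0.5), SBS1 = c(0.60, 0.5))
  sub <- make_exposure_table(c("a", "b"), c(800, 900),
                             SBS17b = c(0.25, 0.5), SBS1 = c(0.75, 0.5))
  sh <- subclonal_shifts(cl, sub, min_mutations = 50)
  expect_equal(sh$delta[sh$sample == "a" & sh$signature == "SBS17b"], -0.15)
  expect_false("b" %in% sh$sample)  # below the clonal mutation floor
  # identical compartments give zero shifts
  sh0 <- subclonal_shifts(cl, cl, min_mutations = 50)
  expect_true(all(sh0$delta == 0))
})

test_that("group comparisons match exact rank enumeration and handle ties", {
  d <- tibble::tibble(v = c(1, 2, 3, 4, 5, 6),
                      g = rep(c("x", "y"), each = 3))
  r <- compare_groups(d, "v", "g")
  expect_equal(r$p, 0.1)   # exact two-sided rank-sum for {1,2,3} vs {4,5,6}
  # identical groups give p = 1
  d2 <- tibble::tibble(v = rep(c(1, 2, 3), 2), g = rep(c("x", "y"), each = 3))
  expect_equal(compare_groups(d2, "v", "g")$p, 1)
  # all-tied values are flagged with p = 1
  d3 <- tibble::tibble(v = rep(1, 6), g = rep(c("x", "y"), each = 3))
  r3 <- compare_groups(d3, "v", "g")
  expect_equal(r3$p, 1)
  expect_equal(r3$flag, "all-tied")
  # exact agreement with enumeration for all group sizes <= 6 (spot checks)
  set.seed(2)
  for (n1 in c(3, 4, 6)) for (n2 in c(3, 5)) {
    x <- sample(100, n1); y <- sample(100, n2) + 0.5
    dd <- tibble::tibble(v = c(x, y), g = rep(c("x", "y"), c(n1, n2)))
    expect_equal(compare_groups(dd, "v", "g")$p,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("paired comparisons use the signed-rank test on aligned pairs", {
  d <- tibble::tibble(v = c(1, 2, 3, 4, 2.5, 3.5, 4.5, 5.5),
                      g = rep(c("pre", "post"), each = 4),
                      id = rep(1:4, 2))
  r <- compare_groups(d, "v", "g", pair = "id", paired = TRUE)
  expect_equal(r$p, suppressWarnings(
    stats::wilcox.test(c(1, 2, 3, 4), c(2.5, 3.5, 4.5, 5.5),
                       paired = TRUE)$p.value))
})

test_that("BH adjustment matches the hand-computed step-up values", {
  d <- tibble::tibble(v = c(rnorm(20), rnorm(20)), g = rep(c("x", "y"), each = 20),
                      s = rep(rep(c("A", "B", "C"), length.out = 20), 2))
  # oracle check of the BH formula itself on fixed p-values
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))
  r <- compare_groups(d, "v", "g", by = "s", adjust = "BH")
  expect_equal(r$q, stats::p.adjust(r$p, "BH"))
})

test_that("dominance requires a strict majority of the signature set", {
  tab <- make_exposure_table(c("a", "b", "c"), 1000,
                             SBS17a = c(0.30, 0.25, 0.1),
                             SBS17b = c(0.25, 0.25, 0.1),
                             SBS5 = c(0.45, 0.5, 0.8))
  r <- dominance_groups(tab, c("SBS17a", "SBS17b"))
  expect_equal(r$dominant, c(TRUE, FALSE, FALSE))  # 0.55 > 0.5; 0.50 is not
  r0 <- dominance_groups(tab, character(0))
  expect_false(any(r0$dominant))
})

test_that("a planted subclonal decrease is recovered through compartment refits", {
  g <- test_genome()
  ref <- test_sbs_reference()
  set.seed(23)
  deltas <- vapply(1:8, function(i) {
    e_cl <- c(SBS17b = 0.5, SBS1 = 0.3, SBS18 = 0.2)
    e_sub <- c(SBS17b = 0.3, SBS1 = 0.5, SBS18 = 0.2)
    tr <- truth_record(paste0("S", i), purity = 0.9,
                       exposures = list(clonal = e_cl, subclonal = e_sub),
                       clone_table = tibble::tibble(ccf = c(1, 0.35),
                                                    fraction = c(0.5, 0.5)))
    sim <- simulate_sample(g, tr, n_snvs = 3000, depth = 60, seed = 100 + i)
    cl <- analyze_clonality(sim$variants, sim$segments, sim$purity_table,
                            n_ref = 300)
    muts <- cl$mutations
    fit_comp <- function(sel) {
      fit_cohort(build_catalogue(muts[sel, ], g, "sbs96"), ref)
    }
    f_cl <- fit_comp(muts$timing != "subclonal")
    f_sub <- fit_comp(muts$timing == "subclonal")
    sh <- subclonal_shifts(f_cl, f_sub, min_mutations = 50)
    sh$delta[sh$signature == "SBS17b"]
  }, numeric(1))
  expect_lt(abs(median(deltas) - (-0.2)), 0.06)
})
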