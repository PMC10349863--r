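# Clonality decomposition: cancer cell fractions with per-mutation
# multiplicity, a unimodality (dip) test on the CCF distribution, a
# two-component Gaussian mixture for subclonal samples, and deterministic
# early/late/subclonal timing labels aware of whole-genome doubling.

#' Cancer cell fraction and multiplicity
#'
#' For each variant with an overlapping copy-number segment, computes
#' `N = purity * (n_major + n_minor) + (1 - purity) * 2` (the
#' purity-weighted local total copy number), multiplicity
#' `m = clamp(round(vaf * N / purity), 1, n_major)`, and
#' `ccf = vaf * N / (purity * m)`. CCF is capped at 1.25 with an overflow
#' flag (`ccf_raw` keeps the uncapped value). Variants without a segment are
#' flagged `no_cn` and excluded from timing.
#'
#' @param variants Variant tibble (single sample or multi-sample; matched to
#'   segments by `sample_id`).
#' @param segments Internal segment tibble ([read_segments()] convention).
#' @param purity Named vector of purities by sample id, or a single value.
#' @return Variants with added `vaf`, `n_major`, `n_minor`, `multiplicity`,
#'   `ccf`, `ccf_raw`, `ccf_overflow`, `no_cn` columns.
#' @export
ccf_and_multiplicity <- function(variants, segments, purity) {
  v <- variants
  if (length(purity) == 1 && is.null(names(purity)))
    purity <- setNames(rep(purity, length(unique(v$sample_id))), unique(v$sample_id))
  if (any(!unique(v$sample_id) %in% names(purity)))
    abort("purity missing for some samples")
  rho <- unname(purity[v$sample_id])
  if (any(rho <= 0 | rho > 1)) abort("purity must be in (0, 1]")
  v$vaf <- v$alt_reads / (v$alt_reads + v$ref_reads)

  v$n_major <- NA_integer_; v$n_minor <- NA_integer_
  key <- paste(v$sample_id, v$chrom)
  for (k in unique(key)) {
    i <- which(key == k)
    s <- segments[segments$sample_id == v$sample_id[i[1]] &
                  segments$chrom == v$chrom[i[1]], ]
    if (nrow(s) == 0) next
    s <- s[order(s$start), ]
    p0 <- v$pos[i] - 1L
    j <- findInterval(p0, s$start)
    ok <- j >= 1 & p0 < s$end[pmax(j, 1L)]
    v$n_major[i[ok]] <- s$n_major[j[ok]]
    v$n_minor[i[ok]] <- s$n_minor[j[ok]]
  }
  v$no_cn <- is.na(v$n_major)
  tot <- v$n_major + v$n_minor
  N <- rho * tot + (1 - rho) * 2
  m <- pmin(pmax(round(v$vaf * N / rho), 1L), pmax(v$n_major, 1L))
  ccf_raw <- v$vaf * N / (rho * m)
  v$multiplicity <- ifelse(v$no_cn, NA_integer_, as.integer(m))
  v$ccf_raw <- ifelse(v$no_cn, NA_real_, ccf_raw)
  v$ccf_overflow <- !v$no_cn & ccf_raw > 1.25
  v$ccf <- pmin(v$ccf_raw, 1.25)
  v
}

#' Dip statistic for unimodality
#'
#' Sup-distance-based deviation of the empirical CDF from the nearest
#' unimodal CDF, computed by the greatest-convex-minorant /
#' least-concave-majorant band construction over candidate mode placements
#' (an atom is permitted at the mode).
#'
#' @param values Numeric vector.
#' @return The dip statistic (scalar).
#' @export
dip_stat <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) return(NA_real_)
  .dip_stat_cpp(as.numeric(values))
}

#' Null dip distribution for sample size n
#'
#' Dip statistics of `n_ref` i.i.d. uniform samples of size `n` — the
#' reference (least favourable) null for the dip test. The null depends only
#' on `n`, so a table can be shared across equal-sized samples.
#'
#' @param n Sample size.
#' @param n_ref Number of Monte Carlo draws.
#' @param seed Optional seed.
#' @return Numeric vector of length `n_ref`.
#' @export
dip_null <- function(n, n_ref = 2000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n_ref), function(i) .dip_stat_cpp(runif(n)), numeric(1))
}

#' Hartigan-style dip test with Monte Carlo p-value
#'
#' Tests the CCF (or VAF) distribution for deviation from unimodality. The
#' p-value is `(1 + #\{null dips >= observed\}) / (1 + n_ref)` against the
#' uniform reference null; ties count in favour of the null. Fewer than 10
#' values yield a fully-clonal call with an `insufficient-n` flag.
#'
#' @param values Numeric vector (>= 10 values for a test).
#' @param n_ref Monte Carlo reference draws (default 2000).
#' @param seed Optional seed for the reference draws.
#' @param alpha Multimodality threshold on the p-value (default 0.05).
#' @param null_dips Optional precomputed [dip_null()] table for `length(values)`.
#' @return List: `statistic`, `p`, `is_multimodal`, `flag`.
#' @export
dip_test <- function(values, n_ref = 2000L, seed = NULL, alpha = 0.05,
                     null_dips = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 10)
    return(list(statistic = NA_real_, p = NA_real_, is_multimodal = FALSE,
                flag = "insufficient-n"))
  d <- dip_stat(values)
  if (is.null(null_dips)) null_dips <- dip_null(length(values), n_ref, seed)
  p <- (1 + sum(null_dips >= d)) / (1 + length(null_dips))
  list(statistic = d, p = p, is_multimodal = p < alpha, flag = "ok")
}

#' Two-component Gaussian mixture for subclonal structure
#'
#' EM fit of a two-component Gaussian mixture to CCF values, initialized by
#' k-means started from the lower/upper quartiles. The component with mean
#' nearer 1 is the clonal one; the other component's weight is the subclonal
#' fraction, and a mutation is labelled subclonal when its posterior for the
#' subclonal component exceeds 0.5 (ties to clonal).
#'
#' @param ccfs Numeric CCF values of a sample flagged multimodal.
#' @param tol EM convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_iter Maximum EM iterations (default 500).
#' @param var_floor Variance floor (default 1e-4).
#' @return List: `means`, `sds`, `weights` (clonal first), `subclonal_fraction`,
#'   `is_subclonal` (logical per value), `flag` (`"ok"` or `"degenerate"`).
#' @export
fit_subclonal_mixture <- function(ccfs, tol = 1e-6, max_iter = 500L,
                                  var_floor = 1e-4) {
  x <- ccfs[is.finite(ccfs)]
  n <- length(x)
  degenerate <- function() list(means = NA_real_, sds = NA_real_, weights = c(1, 0),
                                subclonal_fraction = 0,
                                is_subclonal = rep(FALSE, length(ccfs)),
                                flag = "degenerate")
  q <- quantile(x, c(0.25, 0.75), names = FALSE)
  if (n < 4 || q[1] == q[2]) return(degenerate())
  km <- suppressWarnings(stats::kmeans(x, centers = matrix(q, ncol = 1)))
  mu <- as.numeric(km$centers)
  s2 <- pmax(tapply(x, km$cluster, stats::var), var_floor)
  s2[is.na(s2)] <- var_floor
  w <- as.numeric(table(factor(km$cluster, levels = 1:2))) / n
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sqrt(s2[1]))
    d2 <- w[2] * stats::dnorm(x, mu[2], sqrt(s2[2]))
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r2 <- d2 / tot
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
    w <- c(mean(1 - r2), mean(r2))
    if (any(w < 1e-12)) break
    mu[1] <- sum((1 - r2) * x) / sum(1 - r2)
    mu[2] <- sum(r2 * x) / sum(r2)
    s2[1] <- max(sum((1 - r2) * (x - mu[1])^2) / sum(1 - r2), var_floor)
    s2[2] <- max(sum(r2 * (x - mu[2])^2) / sum(r2), var_floor)
  }
  if (any(w < 0.01) || abs(mu[1] - mu[2]) < 1e-6) return(degenerate())
  clonal <- which.min(abs(mu - 1))
  sub <- 3 - clonal
  post_sub <- if (sub == 2) r2 else 1 - r2
  is_sub_x <- post_sub > 0.5
  is_sub <- rep(FALSE, length(ccfs))
  is_sub[is.finite(ccfs)] <- is_sub_x
  list(means = mu[c(clonal, sub)], sds = sqrt(s2[c(clonal, sub)]),
       weights = w[c(clonal, sub)], subclonal_fraction = w[sub],
       is_subclonal = is_sub, flag = "ok")
}

#' Whole-genome doubling status
#'
#' A sample is called whole-genome doubled when more than half of the
#' segment-covered genome has major copy number >= 2 and the average ploidy
#' exceeds 2.9.
#'
#' @param segments Segment tibble for one or more samples.
#' @param ploidy Named vector of ploidies by sample id, or a single value.
#' @return Tibble `sample`, `fraction_major_ge2`, `wgd`.
#' @export
wgd_status <- function(segments, ploidy) {
  if (length(ploidy) == 1 && is.null(names(ploidy)))
    ploidy <- setNames(rep(ploidy, length(unique(segments$sample_id))),
                       unique(segments$sample_id))
  segments |>
    dplyr::group_by(sample = .data$sample_id) |>
    dplyr::summarise(fraction_major_ge2 =
                       sum((.data$end - .data$start) * (.data$n_major >= 2)) /
                       sum(.data$end - .data$start), .groups = "drop") |>
    dplyr::mutate(ploidy = unname(ploidy[.data$sample]),
                  wgd = .data$fraction_major_ge2 > 0.5 & .data$ploidy > 2.9)
}

#' Assign clonal-early / clonal-late / clonal-other / subclonal labels
#'
#' Deterministic timing rules: subclonal mutations keep their mixture label;
#' clonal mutations in segments with major copy number >= 2 are early when
#' multiplicity >= 2 and late when multiplicity is 1; clonal mutations at
#' major copy number 1 (or without copy-number information) are
#' `clonal_other`.
#'
#' @param mutations Tibble from [ccf_and_multiplicity()] with a logical
#'   `is_subclonal` column (all-`FALSE` for fully clonal samples).
#' @return The tibble with an added `timing` column.
#' @export
assign_timing <- function(mutations) {
  m <- mutations
  if (is.null(m$is_subclonal)) m$is_subclonal <- FALSE
  m$timing <- dplyr::case_when(
    m$is_subclonal ~ "subclonal",
    m$no_cn ~ "clonal_other",
    m$n_major >= 2 & m$multiplicity >= 2 ~ "clonal_early",
    m$n_major >= 2 & m$multiplicity == 1 ~ "clonal_late",
    TRUE ~ "clonal_other"
  )
  m
}

#' Full clonality/timing decomposition for a cohort
#'
#' Per sample: CCF and multiplicity, dip test on the (uncapped) CCF values,
#' two-component mixture when multimodal, then timing labels. Returns both
#' the per-mutation assignment and a per-sample summary.
#'
#' @param variants Variant tibble (all samples).
#' @param segments Segment tibble.
#' @param purity_table Tibble `sample_id`, `purity`, `ploidy`
#'   ([read_purity_table()]).
#' @param alpha Dip-test multimodality threshold (default 0.05).
#' @param n_ref Monte Carlo draws for the dip null (default 2000).
#' @param seed Optional seed (dip null draws).
#' @param null_dip_cache Optional environment used to share [dip_null()]
#'   tables across samples of equal size.
#' @return Object of class `clonality_assignment`: list with `mutations`
#'   (per-mutation tibble incl. `timing`) and `samples` (per-sample summary:
#'   dip statistic and p, multimodality, subclonal fraction, mixture
#'   parameters, WGD status).
#' @export
analyze_clonality <- function(variants, segments, purity_table, alpha = 0.05,
                              n_ref = 2000L, seed = NULL,
                              null_dip_cache = NULL) {
  purity <- setNames(purity_table$purity, purity_table$sample_id)
  ploidy <- setNames(purity_table$ploidy, purity_table$sample_id)
  if (!is.null(seed)) set.seed(seed)
  ann <- ccf_and_multiplicity(variants, segments, purity)
  wgd <- wgd_status(segments, ploidy)
  muts <- list(); summaries <- list()
  for (sid in unique(ann$sample_id)) {
    mv <- ann[ann$sample_id == sid, ]
    ccfs <- mv$ccf_raw[!mv$no_cn]
    nd <- NULL
    if (!is.null(null_dip_cache)) {
      key <- as.character(length(ccfs))
      if (is.null(null_dip_cache[[key]]))
        null_dip_cache[[key]] <- dip_null(length(ccfs), n_ref)
      nd <- null_dip_cache[[key]]
    }
    dt <- dip_test(ccfs, n_ref = n_ref, alpha = alpha, null_dips = nd)
    mv$is_subclonal <- FALSE
    mix <- NULL
    if (isTRUE(dt$is_multimodal)) {
      mix <- fit_subclonal_mixture(mv$ccf[!mv$no_cn])
      if (mix$flag == "ok") mv$is_subclonal[!mv$no_cn] <- mix$is_subclonal
    }
    mv <- assign_timing(mv)
    muts[[sid]] <- mv
    summaries[[sid]] <- tibble::tibble(
      sample = sid, n_mutations = nrow(mv),
      dip_stat = dt$statistic, dip_p = dt$p,
      is_multimodal = isTRUE(dt$is_multimodal) &&
        (!is.null(mix) && mix$flag == "ok"),
      subclonal_fraction = if (!is.null(mix) && mix$flag == "ok")
        mix$subclonal_fraction else 0,
      mix_mean_clonal = if (!is.null(mix) && mix$flag == "ok") mix$means[1] else NA_real_,
      mix_mean_subclonal = if (!is.null(mix) && mix$flag == "ok") mix$means[2] else NA_real_,
      flag = if (dt$flag != "ok") dt$flag
             else if (isTRUE(dt$is_multimodal) && !is.null(mix) && mix$flag != "ok")
               "degenerate-mixture" else "ok")
  }
  out <- list(mutations = dplyr::bind_rows(muts),
              samples = dplyr::bind_rows(summaries) |>
                dplyr::left_join(wgd[c("sample", "fraction_major_ge2", "wgd")],
                                 by = "sample"))
  class(out) <- "clonality_assignment"
  out
}

#' @export
print.clonality_assignment <- function(x, ...) {
  cat("<clonality_assignment>", nrow(x$samples), "samples,",
      nrow(x$mutations), "mutations\n")
  cat("  multimodal samples:", sum(x$samples$is_multimodal), "\n")
  invisible(x)
}

#' @export
tidy.clonality_assignment <- function(x, ...) tibble::as_tibble(x$mutations)

#' @export
glance.clonality_assignment <- function(x, ...) tibble::as_tibble(x$samples)
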