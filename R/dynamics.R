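# Cohort-level signature dynamics: subclonal-vs-clonal exposure shifts,
# group comparisons (Wilcoxon, optional Benjamini-Hochberg), and signature
# dominance grouping.

#' Subclonal signature exposure shifts
#'
#' Per sample and signature, the change in relative exposure from the clonal
#' to the subclonal compartment (`delta = subclonal - clonal`; values below
#' zero indicate a subclonal decrease). Samples whose compartment holds fewer
#' than `min_mutations` mutations are excluded (the exposure estimate is
#' unstable below that).
#'
#' @param clonal,subclonal `exposure_table`s fitted on the clonal and
#'   subclonal mutations of the same samples.
#' @param min_mutations Per-compartment mutation floor (default 50).
#' @param stages Optional named vector of stage labels by sample.
#' @return Tibble `sample`, `signature`, `clonal`, `subclonal`, `delta`
#'   (+ `stage` when given), class `shift_table`.
#' @export
subclonal_shifts <- function(clonal, subclonal, min_mutations = 50L, stages = NULL) {
  sigs <- intersect(attr(clonal, "signatures"), attr(subclonal, "signatures"))
  keep_c <- clonal$sample[clonal$n_mutations >= min_mutations]
  keep_s <- subclonal$sample[subclonal$n_mutations >= min_mutations]
  samples <- intersect(keep_c, keep_s)
  long <- function(tab, name) {
    tibble::as_tibble(tab)[tab$sample %in% samples, c("sample", sigs)] |>
      tidyr::pivot_longer(dplyr::all_of(sigs), names_to = "signature",
                          values_to = name)
  }
  out <- dplyr::inner_join(long(clonal, "clonal"), long(subclonal, "subclonal"),
                           by = c("sample", "signature")) |>
    dplyr::mutate(delta = .data$subclonal - .data$clonal)
  if (!is.null(stages)) out$stage <- unname(stages[out$sample])
  class(out) <- c("shift_table", class(out))
  out
}

#' Summarise shifts per signature (and stage)
#' @param shifts A [subclonal_shifts()] table.
#' @return Tibble with median and IQR of `delta` per signature (x stage).
#' @export
shift_summary <- function(shifts) {
  grp <- if ("stage" %in% names(shifts)) c("signature", "stage") else "signature"
  shifts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(n = dplyr::n(), median_delta = median(.data$delta),
                     iqr_delta = stats::IQR(.data$delta), .groups = "drop")
}

#' Two-group Wilcoxon comparisons with optional BH correction
#'
#' Unpaired comparisons use the two-sided Wilcoxon rank-sum test; paired
#' comparisons the two-sided signed-rank test on pairs aligned by `pair`.
#' When `by` is given, one test is run per stratum and the BH adjustment is
#' applied across that family. All-tied strata report p = 1 with a flag.
#'
#' @param data Tibble with the value and grouping columns.
#' @param value,group Column names (strings) of the measurement and the
#'   two-level grouping factor.
#' @param by Optional column name defining the family of tests (e.g.
#'   signature).
#' @param pair Optional column name aligning paired observations.
#' @param paired Use the signed-rank test on pairs?
#' @param adjust `"none"` or `"BH"`.
#' @return Tibble with one row per stratum: `statistic`, `p`, optionally `q`,
#'   and a `flag`.
#' @export
compare_groups <- function(data, value, group, by = NULL, pair = NULL,
                           paired = FALSE, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  strata <- if (is.null(by)) list(`1` = data) else split(data, data[[by]])
  rows <- purrr::imap_dfr(strata, function(d, lab) {
    g <- d[[group]]
    lev <- unique(g)
    if (length(lev) != 2)
      abort(sprintf("grouping column must have exactly 2 levels, found %d",
                    length(lev)))
    x <- d[[value]][g == lev[1]]
    y <- d[[value]][g == lev[2]]
    if (paired) {
      if (is.null(pair)) abort("paired comparisons need a `pair` column")
      p1 <- d[[pair]][g == lev[1]]; p2 <- d[[pair]][g == lev[2]]
      common <- intersect(p1, p2)
      x <- x[match(common, p1)]; y <- y[match(common, p2)]
      if (length(common) < 3) abort("need >= 3 pairs")
      if (all(x == y))
        return(tibble::tibble(stratum = lab, n1 = length(x), n2 = length(y),
                              statistic = NA_real_, p = 1, flag = "all-tied"))
      wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
    } else {
      if (length(x) < 3 || length(y) < 3) abort("need >= 3 values per group")
      if (length(unique(c(x, y))) == 1)
        return(tibble::tibble(stratum = lab, n1 = length(x), n2 = length(y),
                              statistic = NA_real_, p = 1, flag = "all-tied"))
      wt <- suppressWarnings(stats::wilcox.test(x, y))
    }
    tibble::tibble(stratum = lab, n1 = length(x), n2 = length(y),
                   statistic = unname(wt$statistic), p = wt$p.value, flag = "ok")
  })
  if (adjust == "BH") rows$q <- stats::p.adjust(rows$p, method = "BH")
  if (is.null(by)) rows$stratum <- NULL
  rows
}

#' Signature dominance grouping
#'
#' A sample is "dominant" for a signature set when the summed exposures of
#' the set contribute the majority (> 0.5, strictly) of its mutations.
#'
#' @param exposures An `exposure_table` (fractions).
#' @param signatures Character vector of signature names (e.g.
#'   `c("SBS17a", "SBS17b")`).
#' @return Tibble `sample`, `set_exposure`, `dominant`.
#' @export
dominance_groups <- function(exposures, signatures) {
  present <- intersect(signatures, names(exposures))
  tot <- if (length(present) == 0) rep(0, nrow(exposures))
         else rowSums(tibble::as_tibble(exposures)[present])
  tibble::tibble(sample = exposures$sample, set_exposure = tot,
                 dominant = tot > 0.5)
}
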