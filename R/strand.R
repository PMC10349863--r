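# Transcription and replication strand assignment for classified SNVs, and
# strand-bias statistics.

# Overlap helper: label of the single overlapping interval, "ambiguous" when
# intervals on both strands overlap, NA when none does.
overlap_strands <- function(chrom, pos0, intervals) {
  res <- vector("list", length(chrom))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    iv <- intervals[intervals$chrom == ch, ]
    res[i] <- lapply(pos0[i], function(p) {
      unique(iv$strand[p >= iv$start & p < iv$end])
    })
  }
  res
}

#' Transcriptional strand of SNVs
#'
#' A mutation is on the transcribed (template) strand when its pyrimidine
#' lies on the strand opposite the overlapping gene's coding strand;
#' positions covered by genes on both strands are `ambiguous`; positions with
#' no gene are `intergenic`.
#'
#' @param snvs Classified SNV tibble (needs `chrom`, `pos`, `pyr_strand`).
#' @param genes Gene tibble `chrom`, `start`, `end` (0-based half-open),
#'   `strand`.
#' @return `snvs` with an added `tx_strand` column
#'   (`transcribed`/`untranscribed`/`intergenic`/`ambiguous`).
#' @export
assign_tx_strand <- function(snvs, genes) {
  hits <- overlap_strands(snvs$chrom, snvs$pos - 1L, genes)
  snvs$tx_strand <- vapply(seq_along(hits), function(i) {
    s <- hits[[i]]
    if (length(s) == 0) "intergenic"
    else if (length(s) > 1) "ambiguous"
    else if (s != snvs$pyr_strand[i]) "transcribed"
    else "untranscribed"
  }, character(1))
  snvs
}

#' Replication strand of SNVs
#'
#' Convention (fixed and documented): in a right-replicating domain the
#' reference "+" strand is the lagging-strand template, so a pyrimidine on
#' "+" is labelled `lagging`; a left-replicating domain flips the labels.
#' Positions outside any domain are `unknown`.
#'
#' @param snvs Classified SNV tibble.
#' @param repl_domains Tibble `chrom`, `start`, `end`, `direction`
#'   (`right`/`left`).
#' @return `snvs` with an added `repl_strand` column.
#' @export
assign_repl_strand <- function(snvs, repl_domains) {
  doms <- repl_domains
  doms$strand <- doms$direction
  hits <- overlap_strands(snvs$chrom, snvs$pos - 1L, doms)
  snvs$repl_strand <- vapply(seq_along(hits), function(i) {
    s <- hits[[i]]
    if (length(s) != 1) return("unknown")
    if ((s == "right") == (snvs$pyr_strand[i] == "+")) "lagging" else "leading"
  }, character(1))
  snvs
}

#' Strand bias statistic
#'
#' Log2 ratio of counts on two strands with a two-sided exact binomial test
#' against 0.5. When either count is zero a continuity correction of +0.5 is
#' added to both counts for the ratio (the test uses the raw counts).
#'
#' @param n1,n2 Mutation counts on the two strands.
#' @return Tibble `n1`, `n2`, `log2_ratio`, `p`.
#' @export
strand_bias <- function(n1, n2) {
  cc <- ifelse(n1 == 0 | n2 == 0, 0.5, 0)
  lr <- log2((n1 + cc) / (n2 + cc))
  p <- mapply(function(a, b) {
    if (a + b == 0) return(1)
    stats::binom.test(a, a + b, p = 0.5)$p.value
  }, n1, n2)
  tibble::tibble(n1 = n1, n2 = n2, log2_ratio = lr, p = p)
}
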