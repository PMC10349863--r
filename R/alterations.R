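# DNA-damage-repair gene/pathway alteration scoring from variants and
# allele-specific copy number, chromosomal instability, and a
# proliferation score from G0-arrest expression markers.

#' Default consequence allow-list for non-synonymous events
#'
#' Consequence classes counted as gene-altering SNV/indel events: missense,
#' nonsense (stop gained/lost), frameshift and in-frame indels, initiator
#' codon and incomplete terminal codon variants, 5'/3' UTR variants and
#' transcription-factor-binding-site variants.
#' @return Character vector of consequence strings.
#' @export
default_consequence_allowlist <- function() {
  c("missense_variant", "stop_gained", "stop_lost", "start_lost",
    "initiator_codon_variant", "incomplete_terminal_codon_variant",
    "frameshift_variant", "inframe_insertion", "inframe_deletion",
    "5_prime_UTR_variant", "3_prime_UTR_variant", "TF_binding_site_variant")
}

#' Copy-number alteration classes for genes
#'
#' Using the copy-number segment with maximal overlap of each gene:
#' amplification when total copy number is at least twice the sample's
#' average ploidy; deletion when it is at most half the ploidy; LOH when the
#' minor allele is completely lost (`n_minor = 0`). Classes are independent
#' (a gene can be DEL and LOH). Genes with no overlapping segment get all
#' classes `FALSE` and `no_cn = TRUE`.
#'
#' @param genes Gene tibble `chrom`, `start`, `end`, `gene` (0-based
#'   half-open).
#' @param segments Segment tibble for one or more samples.
#' @param ploidy Named vector of ploidies by sample id, or single value.
#' @return Tibble `sample`, `gene`, `amp`, `del`, `loh`, `no_cn`.
#' @export
classify_gene_cn <- function(genes, segments, ploidy) {
  samples <- unique(segments$sample_id)
  if (length(ploidy) == 1 && is.null(names(ploidy)))
    ploidy <- setNames(rep(ploidy, length(samples)), samples)
  out <- tidyr::expand_grid(sample = samples, gi = seq_len(nrow(genes)))
  res <- purrr::pmap_dfr(out, function(sample, gi) {
    g <- genes[gi, ]
    s <- segments[segments$sample_id == sample & segments$chrom == g$chrom, ]
    ov <- pmin(s$end, g$end) - pmax(s$start, g$start)
    if (nrow(s) == 0 || all(ov <= 0))
      return(tibble::tibble(sample = sample, gene = g$gene, amp = FALSE,
                            del = FALSE, loh = FALSE, no_cn = TRUE))
    seg <- s[which.max(ov), ]
    psi <- unname(ploidy[sample])
    tot <- seg$n_major + seg$n_minor
    tibble::tibble(sample = sample, gene = g$gene,
                   amp = tot >= 2 * psi, del = tot <= psi / 2,
                   loh = seg$n_minor == 0, no_cn = FALSE)
  })
  res
}

#' SNV/indel alteration calls for genes
#'
#' A gene is altered in a sample when at least one overlapping variant
#' carries a consequence in the allow-list. With `ignore_consequence = TRUE`
#' any overlapping variant counts; otherwise variants without consequence
#' annotation are a configuration error.
#'
#' @param variants Variant tibble (1-based `pos`; `consequence` column).
#' @param genes Gene tibble (0-based half-open, `gene` names).
#' @param allowlist Consequence allow-list
#'   (default [default_consequence_allowlist()]).
#' @param ignore_consequence Count any overlapping variant?
#' @return Tibble `sample`, `gene`, `snv_indel` (logical).
#' @export
classify_gene_snv <- function(variants, genes,
                              allowlist = default_consequence_allowlist(),
                              ignore_consequence = FALSE) {
  samples <- unique(variants$sample_id)
  if (!ignore_consequence) {
    if (is.null(variants$consequence) || all(is.na(variants$consequence)))
      abort(paste("variants carry no consequence annotation;",
                  "use `ignore_consequence = TRUE` to count any overlap"))
    variants <- variants[!is.na(variants$consequence) &
                           variants$consequence %in% allowlist, ]
  }
  grid <- tidyr::expand_grid(sample = samples, gi = seq_len(nrow(genes)))
  purrr::pmap_dfr(grid, function(sample, gi) {
    g <- genes[gi, ]
    v <- variants[variants$sample_id == sample & variants$chrom == g$chrom, ]
    hit <- any(v$pos - 1L >= g$start & v$pos - 1L < g$end)
    tibble::tibble(sample = sample, gene = g$gene, snv_indel = hit)
  })
}

#' Pathway-level alteration matrix
#'
#' Joins per-gene calls onto a gene-to-pathway membership table; a pathway is
#' flagged for an event class when any member gene is flagged. Also returns
#' per-pathway altered fractions across the cohort, ordered by decreasing
#' deletion fraction.
#'
#' @param gene_calls Tibble `sample`, `gene` plus logical event-class columns
#'   (any of `snv_indel`, `amp`, `del`, `loh`; join of [classify_gene_cn()]
#'   and [classify_gene_snv()] outputs).
#' @param membership Tibble `gene`, `pathway`.
#' @return List with `matrix` (tibble `sample`, `pathway`, event classes) and
#'   `fractions` (tibble `pathway` x class fractions, ordered by `del`).
#' @export
pathway_matrix <- function(gene_calls, membership) {
  classes <- intersect(c("snv_indel", "amp", "del", "loh"), names(gene_calls))
  if (length(classes) == 0) abort("`gene_calls` has no event-class columns")
  orphan <- setdiff(unique(gene_calls$gene), membership$gene)
  if (length(orphan))
    warn(sprintf("%d gene(s) not in the membership table are ignored: %s",
                 length(orphan), paste(head(orphan, 3), collapse = ", ")))
  joined <- dplyr::inner_join(gene_calls, membership, by = "gene",
                              relationship = "many-to-many")
  samples <- unique(gene_calls$sample)
  pathways <- unique(membership$pathway)
  mat <- tidyr::expand_grid(sample = samples, pathway = pathways) |>
    dplyr::left_join(
      joined |>
        dplyr::group_by(.data$sample, .data$pathway) |>
        dplyr::summarise(dplyr::across(dplyr::all_of(classes), any), .groups = "drop"),
      by = c("sample", "pathway")) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(classes), ~ !is.na(.x) & .x))
  fr <- mat |>
    dplyr::group_by(.data$pathway) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(classes), mean), .groups = "drop")
  if ("del" %in% classes) fr <- dplyr::arrange(fr, dplyr::desc(.data$del))
  list(matrix = mat, fractions = fr)
}

#' Chromosomal instability score
#'
#' Raw score: number of copy-number segments whose total copy number differs
#' from the rounded sample ploidy and which span more than 5% of their
#' chromosome's length. Scores are Z-scaled across the cohort (a
#' zero-variance cohort yields z = 0 for all samples).
#'
#' @param segments Segment tibble (all samples).
#' @param ploidy Named vector of ploidies by sample id, or single value.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @return Tibble `sample`, `cin_raw`, `cin_z`.
#' @export
cin_score <- function(segments, ploidy, chrom_lengths) {
  samples <- unique(segments$sample_id)
  if (length(ploidy) == 1 && is.null(names(ploidy)))
    ploidy <- setNames(rep(ploidy, length(samples)), samples)
  raw <- segments |>
    dplyr::mutate(
      abnormal = (.data$n_major + .data$n_minor) !=
        round(unname(ploidy[.data$sample_id])),
      large = (.data$end - .data$start) > 0.05 * unname(chrom_lengths[.data$chrom])) |>
    dplyr::group_by(sample = .data$sample_id) |>
    dplyr::summarise(cin_raw = sum(.data$abnormal & .data$large), .groups = "drop")
  s <- sd(raw$cin_raw)
  raw$cin_z <- if (length(samples) < 2 || is.na(s) || s == 0) 0
               else (raw$cin_raw - mean(raw$cin_raw)) / s
  raw
}

#' Proliferation score from G0-arrest markers
#'
#' Per-gene cohort Z-scores are averaged over the G0-arrest marker genes to
#' give a quiescence score QS; the proliferation score is `1 - QS`, so a
#' sample at the cohort mean of every marker scores exactly 1.
#'
#' @param expression Tibble with a `sample` column and one column per gene
#'   (or a samples x genes matrix with rownames).
#' @param g0_markers Character vector of marker gene names; markers missing
#'   from the matrix are dropped with a warning, all missing is an error.
#' @return Tibble `sample`, `qs`, `proliferation`.
#' @export
proliferation_score <- function(expression, g0_markers) {
  if (is.matrix(expression))
    expression <- tibble::as_tibble(expression, rownames = "sample")
  if (nrow(expression) < 2) abort("need at least 2 samples for cohort Z-scores")
  present <- intersect(g0_markers, names(expression))
  if (length(present) == 0) abort("none of the G0 markers are in the expression matrix")
  if (length(present) < length(g0_markers))
    warn(sprintf("%d marker(s) missing from the expression matrix",
                 length(g0_markers) - length(present)))
  z <- scale(as.matrix(expression[present]))
  z[is.nan(z)] <- 0  # zero-variance markers
  qs <- rowMeans(z)
  tibble::tibble(sample = expression$sample, qs = qs, proliferation = 1 - qs)
}
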