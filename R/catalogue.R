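# Mutation channel classification: SBS-96 trinucleotide channels (pyrimidine
# oriented) and ID-83 indel channels (left-aligned, repeat > microhomology
# precedence as in the COSMIC scheme).

#' Classify SNVs into SBS-96 channels
#'
#' Adds the pyrimidine-centric trinucleotide channel, the canonical pentamer
#' context and the strand carrying the pyrimidine to each SNV. Purine
#' reference alleles are reverse-complemented into the pyrimidine
#' representation. A reference allele disagreeing with the genome is a
#' validation error; SNVs with an ambiguous (N) trinucleotide are dropped and
#' counted in the `n_dropped` attribute.
#'
#' @param variants Variant tibble (1-based `pos`, columns as [read_vcf()]).
#'   Non-SNV rows are ignored.
#' @param genome A `synthetic_genome` (or [genome_from_sequences()]) object.
#' @return The SNV rows with added `channel`, `pentamer`, `pyr_strand`
#'   columns; attribute `n_dropped` counts context-ambiguous SNVs.
#' @export
classify_snvs <- function(variants, genome) {
  snvs <- variants[variants$kind == "snv", , drop = FALSE]
  if (nrow(snvs) == 0) {
    out <- dplyr::mutate(snvs, channel = character(0), pentamer = character(0),
                         pyr_strand = character(0))
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  parts <- split(seq_len(nrow(snvs)), snvs$chrom)
  chan <- pent <- strand <- rep(NA_character_, nrow(snvs))
  for (ch in names(parts)) {
    i <- parts[[ch]]
    seq <- genome$sequences[[ch]]
    if (is.null(seq)) abort(sprintf("chromosome '%s' not in genome", ch))
    p0 <- snvs$pos[i] - 1L
    gref <- substring(seq, p0 + 1L, p0 + 1L)
    bad <- gref != snvs$ref[i]
    if (any(bad))
      abort(sprintf("reference mismatch at %s:%d (VCF says %s, genome says %s)",
                    ch, snvs$pos[i][bad][1], snvs$ref[i][bad][1], gref[bad][1]))
    tri <- canonical_context(seq, p0, 1L)
    pnt <- canonical_context(seq, p0, 2L)
    pyr <- gref %in% c("C", "T")
    alt_fold <- ifelse(pyr, snvs$alt[i], comp_chars(snvs$alt[i]))
    chan[i] <- paste0(substr(tri, 1, 1), "[", substr(tri, 2, 2), ">", alt_fold,
                      "]", substr(tri, 3, 3))
    chan[i][is.na(tri) | grepl("N", tri, fixed = TRUE)] <- NA
    pent[i] <- pnt
    strand[i] <- ifelse(pyr, "+", "-")
  }
  keep <- !is.na(chan) & chan %in% sbs96_channels()
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    warn(sprintf("%d SNV(s) dropped for ambiguous trinucleotide context", n_dropped))
  out <- snvs[keep, , drop = FALSE]
  out$channel <- chan[keep]
  out$pentamer <- pent[keep]
  out$pyr_strand <- strand[keep]
  attr(out, "n_dropped") <- n_dropped
  out
}

# Left-align an indel: `start0` is the 0-based position of the first
# inserted/deleted base, `seq` the inserted/deleted sequence. Shifts left
# while the base preceding the event equals the event's last base.
left_align_indel <- function(chrom_seq, start0, seq) {
  k <- nchar(seq)
  while (start0 > 0L &&
         substring(chrom_seq, start0, start0) == substring(seq, k, k)) {
    seq <- paste0(substring(seq, k, k), substring(seq, 1L, k - 1L))
    start0 <- start0 - 1L
  }
  list(start0 = start0, seq = seq)
}

# Count tandem copies of `unit` in `chrom_seq` starting at 0-based `start0`.
count_tandem <- function(chrom_seq, start0, unit, cap = 1000L) {
  k <- nchar(unit)
  n <- 0L
  p <- start0
  L <- nchar(chrom_seq)
  while (n < cap && p + k <= L && substring(chrom_seq, p + 1L, p + k) == unit) {
    n <- n + 1L
    p <- p + k
  }
  n
}

# Longest prefix of `seq` matching chrom_seq from 0-based `start0`.
prefix_match <- function(chrom_seq, start0, seq) {
  k <- nchar(seq)
  L <- nchar(chrom_seq)
  m <- 0L
  while (m < k && start0 + m < L &&
         substring(chrom_seq, start0 + m + 1L, start0 + m + 1L) ==
         substring(seq, m + 1L, m + 1L)) m <- m + 1L
  m
}

#' Classify a single indel into its ID-83 channel
#'
#' The event is reduced to its minimal representation (shared prefix/suffix
#' trimmed), left-aligned against the genome, then classified: 1-bp indels by
#' pyrimidine-folded base and homopolymer run length; longer indels by
#' repeat-unit size and tandem copy count; deletions not at a tandem repeat
#' by flanking microhomology length (repeat takes precedence over
#' microhomology).
#'
#' @param chrom_seq Chromosome sequence string.
#' @param pos 1-based VCF position (anchor base).
#' @param ref,alt VCF REF/ALT strings.
#' @return Channel label, or `NA` if the event overlaps the contig end.
#' @export
classify_indel <- function(chrom_seq, pos, ref, alt) {
  # trim shared suffix, then shared prefix (minimal representation)
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substring(ref, nchar(ref)) == substring(alt, nchar(alt))) {
    ref <- substring(ref, 1L, nchar(ref) - 1L)
    alt <- substring(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 1L && nchar(alt) >= 1L &&
         substring(ref, 1, 1) == substring(alt, 1, 1) && nchar(alt) > 1L) {
    ref <- substring(ref, 2L); alt <- substring(alt, 2L); pos <- pos + 1L
  }
  is_del <- nchar(ref) > nchar(alt)
  if (is_del) {
    seq <- substring(ref, 2L)
    start0 <- pos  # first deleted base, 0-based (pos is 1-based anchor)
  } else {
    seq <- substring(alt, 2L)
    start0 <- pos  # insertion occurs before this 0-based position
  }
  k <- nchar(seq)
  if (k == 0L) return(NA_character_)
  L <- nchar(chrom_seq)
  if (start0 + (if (is_del) k else 0L) > L || start0 < 0L) return(NA_character_)
  la <- left_align_indel(chrom_seq, start0, seq)
  start0 <- la$start0; seq <- la$seq
  if (k == 1L) {
    run <- count_tandem(chrom_seq, start0, seq, cap = 100L)
    if (!is_del) run <- run  # existing copies rightward (none leftward: left-aligned)
    b <- if (seq %in% c("C", "G")) "C" else "T"
    if (is_del) paste0("1:Del:", b, ":", min(run, 6L) - 1L)
    else paste0("1:Ins:", b, ":", min(run, 5L))
  } else {
    size <- min(k, 5L)
    copies <- count_tandem(chrom_seq, start0, seq)
    if (!is_del) {
      paste0(size, ":Ins:R:", min(copies, 5L))
    } else if (copies >= 2L) {
      paste0(size, ":Del:R:", min(copies, 6L) - 1L)
    } else {
      mh <- prefix_match(chrom_seq, start0 + k, seq)
      if (mh >= k) mh <- k - 1L  # a full following copy would be a repeat
      if (mh >= 1L) {
        cap <- c(`2` = 1L, `3` = 2L, `4` = 3L, `5` = 5L)[as.character(size)]
        paste0(size, ":Del:M:", min(mh, cap))
      } else paste0(size, ":Del:R:0")
    }
  }
}

#' Classify indel variants into ID-83 channels
#'
#' Vectorized wrapper around [classify_indel()]; indels overlapping a contig
#' end are dropped with a warning.
#'
#' @inheritParams classify_snvs
#' @return Indel rows with an added `channel` column; attribute `n_dropped`.
#' @export
classify_indels <- function(variants, genome) {
  ind <- variants[variants$kind %in% c("insertion", "deletion"), , drop = FALSE]
  if (nrow(ind) == 0) {
    out <- dplyr::mutate(ind, channel = character(0))
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  chan <- vapply(seq_len(nrow(ind)), function(i) {
    seq <- genome$sequences[[ind$chrom[i]]]
    if (is.null(seq)) abort(sprintf("chromosome '%s' not in genome", ind$chrom[i]))
    classify_indel(seq, ind$pos[i], ind$ref[i], ind$alt[i])
  }, character(1))
  keep <- !is.na(chan)
  if (any(!keep))
    warn(sprintf("%d indel(s) dropped (contig end or unclassifiable)", sum(!keep)))
  out <- ind[keep, , drop = FALSE]
  out$channel <- chan[keep]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Build a mutation catalogue
#'
#' Counts classified mutations per sample and channel in canonical channel
#' order. Samples present in the input but with no classifiable mutation are
#' retained as zero rows.
#'
#' @inheritParams classify_snvs
#' @param kind `"sbs96"` (SNVs) or `"id83"` (indels).
#' @return Wide tibble: `sample` plus one count column per channel, with
#'   attributes `kind` and `n_dropped`.
#' @export
build_catalogue <- function(variants, genome, kind = c("sbs96", "id83")) {
  kind <- match.arg(kind)
  samples <- unique(variants$sample_id)
  cls <- if (kind == "sbs96") classify_snvs(variants, genome)
         else classify_indels(variants, genome)
  channels <- channel_set(kind)
  m <- table(factor(cls$sample_id, levels = samples),
             factor(cls$channel, levels = channels))
  out <- tibble::as_tibble(as.data.frame.matrix(m), rownames = NA)
  out <- tibble::tibble(sample = samples, !!!setNames(out, channels))
  attr(out, "kind") <- kind
  attr(out, "n_dropped") <- attr(cls, "n_dropped")
  out
}

#' Extract the count matrix from a catalogue tibble
#' @param catalogue Output of [build_catalogue()] (or a compatible wide tibble).
#' @return Integer matrix samples x channels.
#' @export
catalogue_matrix <- function(catalogue) {
  m <- as.matrix(catalogue[, -1, drop = FALSE])
  rownames(m) <- catalogue$sample
  storage.mode(m) <- "double"
  m
}

#' Tumour mutational burden
#'
#' Plain SNV/indel/total counts after the minimum alt-read support filter.
#'
#' @param variants Variant tibble.
#' @param min_alt_reads Minimum alt-read support (default 3).
#' @return Tibble with one row per sample: `sample`, `snvs`, `indels`, `total`.
#' @export
tmb <- function(variants, min_alt_reads = 3L) {
  v <- variants[variants$alt_reads >= min_alt_reads, , drop = FALSE]
  if (nrow(v) == 0 && nrow(variants) == 0)
    return(tibble::tibble(sample = character(), snvs = integer(),
                          indels = integer(), total = integer()))
  v |>
    dplyr::group_by(sample = .data$sample_id) |>
    dplyr::summarise(snvs = sum(.data$kind == "snv"),
                     indels = sum(.data$kind != "snv"),
                     total = dplyr::n(), .groups = "drop")
}
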