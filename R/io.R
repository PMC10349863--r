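# External formats. Conventions, applied at the I/O boundary only:
#   * VCF positions are 1-based and stay 1-based in the variant tibble
#     (`pos` is the VCF POS of the record).
#   * copy-number segment files are 1-based inclusive on disk; internally all
#     intervals (segments, genes, BED features) are 0-based half-open.
#   * BED is 0-based half-open on disk and internally.

#' Read somatic variants from a VCF file
#'
#' Reads a VCF (v4.2+) with per-sample allelic depths, splits multi-allelic
#' sites into one record per ALT allele, drops records not passing FILTER
#' (unless `keep_nonpass`), and applies a minimum alt-read support filter.
#'
#' @param path Path to an (uncompressed or gzipped) VCF file.
#' @param sample_id Sample column to read; defaults to the only/first sample.
#' @param keep_nonpass Keep records whose FILTER is not PASS/"."?
#' @param min_alt_reads Minimum alt-read support (default 3, matching typical
#'   somatic-calling practice); variants below are dropped.
#' @param consequence_info INFO key carrying an upstream functional
#'   consequence annotation (free text), or `NULL`.
#' @return Tibble with columns `sample_id`, `chrom`, `pos` (1-based VCF POS),
#'   `ref`, `alt`, `ref_reads`, `alt_reads`, `kind` (snv/insertion/deletion),
#'   `consequence`.
#' @export
read_vcf <- function(path, sample_id = NULL, keep_nonpass = FALSE,
                     min_alt_reads = 3L, consequence_info = "CSQ") {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) abort(paste0("malformed VCF '", path, "': ",
                                                 conditionMessage(e))))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0)
    return(tibble::tibble(sample_id = character(), chrom = character(),
                          pos = integer(), ref = character(), alt = character(),
                          ref_reads = integer(), alt_reads = integer(),
                          kind = character(), consequence = character()))
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2) abort("VCF has no sample genotype columns with depths")
  samples <- colnames(gt)[-1]
  if (is.null(sample_id)) sample_id <- samples[1]
  if (!sample_id %in% samples)
    abort(sprintf("sample '%s' not in VCF (has: %s)", sample_id,
                  paste(samples, collapse = ", ")))
  ad <- vcfR::extract.gt(v, element = "AD")[, sample_id]
  if (all(is.na(ad))) abort("VCF records carry no AD (allelic depth) field")

  keep <- keep_nonpass | is.na(fix$FILTER) | fix$FILTER %in% c("PASS", ".")
  csq <- rep(NA_character_, nrow(fix))
  if (!is.null(consequence_info)) {
    m <- regmatches(fix$INFO, regexpr(paste0(consequence_info, "=[^;]+"), fix$INFO))
    has <- grepl(paste0(consequence_info, "="), fix$INFO)
    csq[has] <- sub(paste0(consequence_info, "="), "", m)
  }

  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  ads <- strsplit(ad, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  bad <- which(keep & (is.na(ad) | lengths(ads) != n_alt + 1L))
  if (length(bad))
    abort(sprintf("record %s:%s has missing or malformed AD depths",
                  fix$CHROM[bad[1]], fix$POS[bad[1]]))
  idx <- rep.int(seq_len(nrow(fix)), n_alt)
  allele <- sequence(n_alt)
  out <- tibble::tibble(
    sample_id = sample_id,
    chrom = fix$CHROM[idx],
    pos = as.integer(fix$POS[idx]),
    ref = fix$REF[idx],
    alt = unlist(alts),
    ref_reads = as.integer(vapply(ads, `[`, character(1), 1L))[idx],
    alt_reads = as.integer(mapply(function(a, k) a[k + 1L], ads[idx], allele)),
    keep = keep[idx],
    consequence = csq[idx]
  )
  out <- out[out$keep & !is.na(out$alt_reads) & out$alt_reads >= min_alt_reads, ]
  out$keep <- NULL
  out$kind <- variant_kind(out$ref, out$alt)
  out
}

variant_kind <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "snv",
         ifelse(nchar(ref) > nchar(alt), "deletion", "insertion"))
}

#' Write somatic variants as a minimal VCF v4.2
#'
#' Dialect: single tumour sample column with `GT:AD`, FILTER `PASS`, and an
#' optional `CSQ=` INFO key carrying the consequence string. Round-trips
#' through [read_vcf()].
#'
#' @param variants Variant tibble (see [read_vcf()] for columns).
#' @param path Output path.
#' @param sample_id Sample column name; defaults to the tibble's sample.
#' @export
write_vcf <- function(variants, path, sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- if (nrow(variants)) variants$sample_id[1] else "TUMOUR"
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 "FORMAT", sample_id, sep = "\t"))
  v <- variants[order(variants$chrom, variants$pos), ]
  info <- ifelse(is.na(v$consequence) | v$consequence == "", ".",
                 paste0("CSQ=", v$consequence))
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info, "GT:AD",
                paste0("0/1:", v$ref_reads, ",", v$alt_reads), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a signature reference matrix from TSV
#'
#' First column: channel labels; remaining columns: signatures. Channels are
#' reordered to canonical order; columns within 1e-3 of summing to one are
#' renormalized, others rejected.
#'
#' @param path TSV path.
#' @param kind `"sbs96"`, `"id83"`, or `NULL` to infer from the channel count.
#' @return A [new_signature_reference()] object.
#' @export
read_signature_matrix <- function(path, kind = NULL) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  channels <- as.character(d[[1]])
  if (is.null(kind)) {
    kind <- if (all(channels %in% sbs96_channels())) "sbs96"
    else if (all(channels %in% id83_channels())) "id83"
    else abort("unrecognized channel labels; cannot infer catalogue kind")
  }
  canon <- channel_set(kind)
  unknown <- setdiff(channels, canon)
  if (length(unknown))
    abort(sprintf("unknown %s channel label(s): %s", kind,
                  paste(head(unknown, 5), collapse = ", ")))
  if (length(channels) != length(canon))
    abort(sprintf("expected %d channels, found %d", length(canon), length(channels)))
  m <- as.matrix(d[-1])
  rownames(m) <- channels
  new_signature_reference(m, kind)
}

#' @rdname read_signature_matrix
#' @param reference A `signature_reference`.
#' @export
write_signature_matrix <- function(reference, path) {
  d <- tibble::as_tibble(reference$matrix, rownames = "channel")
  readr::write_tsv(d, path)
  invisible(path)
}

#' Read allele-specific copy-number segments
#'
#' TSV with columns `sample`, `chrom`, `start`, `end`, `nMajor`, `nMinor`;
#' 1-based inclusive on disk, converted to 0-based half-open internally.
#' Overlapping segments within a sample are a validation error.
#'
#' @param path TSV path.
#' @return Tibble `sample_id`, `chrom`, `start`, `end` (0-based half-open),
#'   `n_major`, `n_minor`.
#' @export
read_segments <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("sample", "chrom", "start", "end", "nMajor", "nMinor")
  if (!all(need %in% names(d)))
    abort(paste("segment file must have columns:", paste(need, collapse = ", ")))
  seg <- tibble::tibble(sample_id = as.character(d$sample), chrom = as.character(d$chrom),
                        start = as.integer(d$start) - 1L, end = as.integer(d$end),
                        n_major = as.integer(d$nMajor), n_minor = as.integer(d$nMinor))
  validate_segments(seg)
}

validate_segments <- function(seg) {
  if (any(seg$end <= seg$start)) abort("segments must have end > start")
  if (any(seg$n_minor > seg$n_major)) abort("segments must have n_major >= n_minor")
  if (any(seg$n_minor < 0)) abort("negative copy numbers")
  bad <- seg |>
    dplyr::group_by(.data$sample_id, .data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::filter(dplyr::lag(.data$end, default = -1L) > .data$start) |>
    dplyr::ungroup()
  if (nrow(bad))
    abort(paste0("overlapping copy-number segments: ",
                 paste(utils::head(paste0(bad$sample_id, " ", bad$chrom, ":",
                                          bad$start, "-", bad$end), 5),
                       collapse = "; ")))
  seg
}

#' @rdname read_segments
#' @param segments Internal segment tibble.
#' @export
write_segments <- function(segments, path) {
  d <- tibble::tibble(sample = segments$sample_id, chrom = segments$chrom,
                      start = segments$start + 1L, end = segments$end,
                      nMajor = segments$n_major, nMinor = segments$n_minor)
  readr::write_tsv(d, path)
  invisible(path)
}

#' Read / write BED intervals (0-based half-open)
#'
#' A 1-bp feature on line `chr1 100 101` is the internal position 100.
#'
#' @param path BED path.
#' @return Tibble `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  d <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  if (ncol(d) < 3) abort("BED file needs at least 3 columns")
  tibble::tibble(chrom = as.character(d[[1]]), start = as.integer(d[[2]]),
                 end = as.integer(d[[3]]))
}

#' @rdname read_bed
#' @param intervals Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @export
write_bed <- function(intervals, path) {
  readr::write_tsv(intervals[c("chrom", "start", "end")], path, col_names = FALSE)
  invisible(path)
}

#' Read / write exposure tables
#'
#' Wide TSV: `sample` column plus one column per signature (fractions).
#' Writing and re-reading is lossless to full double precision.
#'
#' @param path TSV path.
#' @export
read_exposures <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  names(d)[1] <- "sample"
  tibble::as_tibble(d)
}

#' @rdname read_exposures
#' @param exposures Wide exposure tibble (first column `sample`).
#' @export
write_exposures <- function(exposures, path) {
  readr::write_tsv(exposures, path)
  invisible(path)
}

#' Read a sample purity/ploidy table
#'
#' TSV with columns `sample`, `purity`, `ploidy`. Purity must lie in (0, 1],
#' ploidy must be positive.
#' @param path TSV path.
#' @export
read_purity_table <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("sample", "purity", "ploidy")
  if (!all(need %in% names(d)))
    abort(paste("purity table must have columns:", paste(need, collapse = ", ")))
  if (any(d$purity <= 0 | d$purity > 1)) abort("purity must be in (0, 1]")
  if (any(d$ploidy <= 0)) abort("ploidy must be positive")
  tibble::tibble(sample_id = as.character(d$sample), purity = d$purity, ploidy = d$ploidy)
}

#' Write a genome's sequences as FASTA (and dyads as BED)
#'
#' @param genome A `synthetic_genome`.
#' @param fasta_path,bed_path Output paths (`bed_path` optional).
#' @export
write_genome_fasta <- function(genome, fasta_path, bed_path = NULL) {
  dss <- Biostrings::DNAStringSet(genome$sequences)
  Biostrings::writeXStringSet(dss, fasta_path)
  if (!is.null(bed_path)) {
    d <- genome$dyads
    write_bed(tibble::tibble(chrom = d$chrom, start = d$pos, end = d$pos + 1L), bed_path)
  }
  invisible(fasta_path)
}

#' Assemble a genome object from sequences and annotation tables
#'
#' For running the pipeline on externally supplied references: sequences from
#' a FASTA (via [Biostrings::readDNAStringSet()]), dyad positions from BED,
#' and optional gene / replication-domain tables.
#'
#' @param sequences Named character vector of chromosome sequences.
#' @param dyads Tibble `chrom`, `pos` (0-based) of dyad centres.
#' @param genes Optional tibble `chrom`, `start`, `end`, `strand`, `gene`.
#' @param repl_domains Optional tibble `chrom`, `start`, `end`, `direction`.
#' @return A `synthetic_genome`-compatible object.
#' @export
genome_from_sequences <- function(sequences, dyads = NULL, genes = NULL,
                                  repl_domains = NULL) {
  if (is.null(names(sequences))) abort("`sequences` must be named by chromosome")
  lens <- setNames(nchar(sequences), names(sequences))
  if (!is.null(dyads) && any(dyads$pos < 0 | dyads$pos >= lens[dyads$chrom]))
    abort("dyad positions outside chromosome bounds")
  structure(list(sequences = sequences, chrom_lengths = lens,
                 dyads = dyads %||% tibble::tibble(chrom = character(), pos = integer()),
                 genes = genes %||% tibble::tibble(chrom = character(), start = integer(),
                                                  end = integer(), strand = character(),
                                                  gene = character()),
                 repl_domains = repl_domains %||%
                   tibble::tibble(chrom = character(), start = integer(),
                                  end = integer(), direction = character()),
                 id_sites = tibble::tibble(channel = character(), chrom = character(),
                                           pos = integer(), ref = character(),
                                           alt = character()),
                 params = list(), cache = new.env(parent = emptyenv())),
            class = "synthetic_genome")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
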