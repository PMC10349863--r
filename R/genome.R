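#' Generate a synthetic genome with chromatin-style annotations
#'
#' Builds a fully synthetic reference: i.i.d. bases at a requested GC
#' fraction, regularly spaced nucleosome dyad centres with positional jitter,
#' genes tiling roughly half the genome on alternating strands, and
#' replication domains of alternating fork direction. The genome also carries
#' a registry of engineered indel-context sites (homopolymers, tandem
#' repeats and microhomology-flanked tracts) so that every ID-83 channel is
#' realizable by construction when simulating indels.
#'
#' All internal coordinates are 0-based half-open. Dyad positions are placed
#' every `dyad_spacing` bp starting `margin` bp from the chromosome start,
#' then jittered by an integer uniform on `[-dyad_jitter, dyad_jitter]`; with
#' zero jitter there are exactly `floor((L - 2*margin)/dyad_spacing) + 1`
#' dyads on a chromosome of length `L`.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @param gc_fraction Target GC fraction in (0, 1).
#' @param dyad_spacing Nucleosome repeat length in bp (147 bp core + linker);
#'   default 197.
#' @param dyad_jitter Maximum absolute dyad jitter in bp.
#' @param margin Dyad-free margin at each chromosome end, bp.
#' @param gene_length,gene_gap Gene tile and intergenic gap lengths, bp.
#' @param repl_domain_length Replication domain length, bp.
#' @param id_sites_per_channel Engineered indel-context sites per ID-83
#'   channel (0 disables embedding).
#' @param seed Integer seed; the genome is deterministic given the seed.
#' @return An object of class `synthetic_genome`: a list with `sequences`
#'   (named character vector), `chrom_lengths`, `dyads`, `genes`,
#'   `repl_domains` (tibbles, 0-based half-open), and `id_sites` (engineered
#'   indel events as VCF-style anchored records).
#' @export
generate_genome <- function(n_chroms = 1L, chrom_length = 1e6, gc_fraction = 0.4,
                            dyad_spacing = 197L, dyad_jitter = 10L, margin = 150L,
                            gene_length = 3000L, gene_gap = 3000L,
                            repl_domain_length = 25000L,
                            id_sites_per_channel = 60L, seed = 1L) {
  stopifnot_scalar_number(n_chroms, "n_chroms")
  stopifnot_scalar_number(chrom_length, "chrom_length")
  if (gc_fraction <= 0 || gc_fraction >= 1) abort("`gc_fraction` must be in (0, 1)")
  if (chrom_length < 10 * dyad_spacing)
    abort("`chrom_length` must be at least 10 * `dyad_spacing`")
  set.seed(seed)
  L <- as.integer(chrom_length)
  chroms <- paste0("chr", seq_len(n_chroms))
  base_p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
              G = gc_fraction / 2, T = (1 - gc_fraction) / 2)

  sequences <- setNames(vapply(chroms, function(ch) {
    paste(sample(DNA_BASES, L, replace = TRUE, prob = base_p), collapse = "")
  }, character(1)), chroms)

  dyads <- purrr::map_dfr(chroms, function(ch) {
    base_pos <- seq.int(margin, L - margin, by = dyad_spacing)
    if (dyad_jitter > 0)
      base_pos <- base_pos + sample.int(2L * dyad_jitter + 1L, length(base_pos),
                                        replace = TRUE) - dyad_jitter - 1L
    tibble::tibble(chrom = ch, pos = pmin(pmax(base_pos, margin %/% 2L), L - margin %/% 2L))
  })

  genes <- purrr::map_dfr(chroms, function(ch) {
    starts <- seq.int(0L, L - gene_length, by = gene_length + gene_gap)
    tibble::tibble(chrom = ch, start = starts, end = starts + gene_length,
                   strand = rep_len(c("+", "-"), length(starts)),
                   gene = paste0(ch, "_g", seq_along(starts)))
  })

  repl_domains <- purrr::map_dfr(chroms, function(ch) {
    starts <- seq.int(0L, L - 1L, by = repl_domain_length)
    tibble::tibble(chrom = ch, start = starts,
                   end = pmin(starts + repl_domain_length, L),
                   direction = rep_len(c("right", "left"), length(starts)))
  })

  id_sites <- tibble::tibble(channel = character(), chrom = character(),
                             pos = integer(), ref = character(), alt = character())
  if (id_sites_per_channel > 0) {
    emb <- embed_id_sites(sequences, base_p, id_sites_per_channel)
    sequences <- emb$sequences
    id_sites <- emb$sites
  }

  structure(list(sequences = sequences,
                 chrom_lengths = setNames(rep(L, n_chroms), chroms),
                 dyads = dyads, genes = genes, repl_domains = repl_domains,
                 id_sites = id_sites,
                 params = list(gc_fraction = gc_fraction, dyad_spacing = dyad_spacing,
                               dyad_jitter = dyad_jitter, margin = margin, seed = seed),
                 cache = new.env(parent = emptyenv())),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("<synthetic_genome>\n")
  cat("  chromosomes:", length(x$sequences), "of length",
      format(unname(x$chrom_lengths[1]), big.mark = ","), "bp\n")
  cat("  dyads:", nrow(x$dyads), " genes:", nrow(x$genes),
      " engineered indel sites:", nrow(x$id_sites), "\n")
  invisible(x)
}

# ---- engineered indel-context sites --------------------------------------

sample_base <- function(n, p, exclude = NULL) {
  b <- DNA_BASES
  if (!is.null(exclude)) {
    keep <- !b %in% exclude
    b <- b[keep]; p <- p[keep]
  }
  sample(b, n, replace = TRUE, prob = p)
}

# Build the local sequence context and VCF-style anchored event realizing a
# given ID-83 channel. Guard bases at both ends pin down run lengths, repeat
# counts and microhomology lengths exactly.
build_id_context <- function(channel, base_p) {
  parts <- strsplit(channel, ":", fixed = TRUE)[[1]]
  size <- as.integer(parts[1]); type <- parts[2]; ctx <- parts[3]
  num <- as.integer(parts[4])
  if (size == 1L) {
    b <- if (ctx == "C") sample(c("C", "G"), 1) else sample(c("A", "T"), 1)
    if (type == "Del") {
      run <- if (num == 5L) 6L else num + 1L
      g1 <- sample_base(1, base_p, exclude = b)
      g2 <- sample_base(1, base_p, exclude = b)
      context <- paste0(g1, strrep(b, run), g2)
      list(context = context, offset = 0L, ref = paste0(g1, b), alt = g1)
    } else {
      run <- num  # existing copies; 5 means 5+
      g1 <- sample_base(1, base_p, exclude = b)
      g2 <- sample_base(1, base_p, exclude = b)
      context <- paste0(g1, strrep(b, run), g2)
      list(context = context, offset = 0L, ref = g1, alt = paste0(g1, b))
    }
  } else if (ctx == "R") {
    len <- if (size == 5L) 5L else size
    repeat {
      unit <- paste(sample(DNA_BASES, len, replace = TRUE, prob = base_p), collapse = "")
      f <- substr(unit, 1, 1); l <- substr(unit, len, len)
      if (f != l) break
    }
    copies <- if (type == "Del") (if (num == 5L) 6L else num + 1L) else num
    g1 <- sample_base(1, base_p, exclude = substr(unit, len, len))
    g2 <- sample_base(1, base_p, exclude = substr(unit, 1, 1))
    context <- paste0(g1, strrep(unit, max(copies, 0L)), g2)
    if (type == "Del") list(context = context, offset = 0L,
                            ref = paste0(g1, unit), alt = g1)
    else list(context = context, offset = 0L, ref = g1, alt = paste0(g1, unit))
  } else {  # microhomology deletion
    len <- if (size == 5L) max(6L, num + 1L) else size
    mh <- num
    repeat {
      d <- paste(sample(DNA_BASES, len, replace = TRUE, prob = base_p), collapse = "")
      # deleted tract must not be self-tandem at the boundary we use
      if (substr(d, 1, 1) != substr(d, len, len)) break
    }
    p <- substr(d, 1, mh)
    g1 <- sample_base(1, base_p, exclude = substr(d, len, len))
    g2 <- sample_base(1, base_p, exclude = substr(d, mh + 1, mh + 1))
    context <- paste0(g1, d, p, g2)
    list(context = context, offset = 0L, ref = paste0(g1, d), alt = g1)
  }
}

embed_id_sites <- function(sequences, base_p, per_channel) {
  channels <- id83_channels()
  chroms <- names(sequences)
  n_sites <- length(channels) * per_channel
  # pre-spaced grid of candidate anchors (60 bp apart) across all chromosomes
  grid <- purrr::map_dfr(chroms, function(ch) {
    L <- nchar(sequences[[ch]])
    tibble::tibble(chrom = ch, pos0 = seq.int(100L, L - 200L, by = 60L))
  })
  if (n_sites > nrow(grid))
    abort("genome too small for the requested number of engineered indel sites")
  slot <- grid[sample.int(nrow(grid), n_sites), ]
  ctxs <- lapply(rep(channels, each = per_channel), build_id_context, base_p = base_p)
  sites <- tibble::tibble(channel = rep(channels, each = per_channel),
                          chrom = slot$chrom, pos0 = slot$pos0,
                          context = vapply(ctxs, `[[`, character(1), "context"),
                          ref = vapply(ctxs, `[[`, character(1), "ref"),
                          alt = vapply(ctxs, `[[`, character(1), "alt"))
  # single-pass sequence reconstruction per chromosome
  for (ch in chroms) {
    s <- sites[sites$chrom == ch, ]
    s <- s[order(s$pos0), ]
    if (nrow(s) == 0) next
    seqc <- sequences[[ch]]
    gaps <- substring(seqc, c(1L, s$pos0 + nchar(s$context) + 1L),
                      c(s$pos0, nchar(seqc)))
    sequences[[ch]] <- paste0(paste0(gaps[seq_len(nrow(s))], s$context,
                                     collapse = ""), gaps[nrow(s) + 1L])
  }
  sites <- sites |>
    dplyr::transmute(channel = .data$channel, chrom = .data$chrom,
                     pos = .data$pos0 + 1L,  # VCF-style 1-based anchor
                     ref = .data$ref, alt = .data$alt)
  list(sequences = sequences, sites = sites)
}

# ---- context indexes ------------------------------------------------------

# Columnwise fixed-width reverse complement helpers.
comp_chars <- function(x) chartr("ACGTN", "TGCAN", x)

# Canonical (pyrimidine-centred) k-mer context at 0-based centre positions.
# Returns a character vector; positions whose window leaves the chromosome
# yield NA.
canonical_context <- function(seq, pos0, flank) {
  L <- nchar(seq)
  ok <- pos0 >= flank & pos0 < L - flank
  out <- rep(NA_character_, length(pos0))
  if (!any(ok)) return(out)
  p <- pos0[ok]
  cols <- lapply(seq(-flank, flank), function(k) substring(seq, p + 1L + k, p + 1L + k))
  centre <- cols[[flank + 1L]]
  fwd <- do.call(paste0, cols)
  rev <- do.call(paste0, lapply(rev(cols), comp_chars))
  pyr <- centre %in% c("C", "T")
  out[ok] <- ifelse(pyr, fwd, rev)
  out
}

# Strand on which the pyrimidine of the centre base lies ("+" if the genome
# base itself is C/T).
pyrimidine_strand <- function(seq, pos0) {
  centre <- substring(seq, pos0 + 1L, pos0 + 1L)
  ifelse(centre %in% c("C", "T"), "+", ifelse(centre %in% c("A", "G"), "-", NA))
}

# Index of genomic positions by canonical trinucleotide, cached on the genome.
trinucleotide_index <- function(genome) {
  cache <- genome$cache
  if (!is.null(cache$tri_index)) return(cache$tri_index)
  idx <- purrr::map_dfr(names(genome$sequences), function(ch) {
    seq <- genome$sequences[[ch]]
    L <- nchar(seq)
    pos0 <- seq.int(1L, L - 2L)
    tibble::tibble(chrom = ch, pos = pos0,
                   context = canonical_context(seq, pos0, 1L))
  })
  idx <- idx[!is.na(idx$context) & !grepl("N", idx$context, fixed = TRUE), ]
  cache$tri_index <- split(idx[c("chrom", "pos")], idx$context)
  cache$tri_index
}
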