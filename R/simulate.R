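# Synthetic cohort generation with known ground truth. Samples are built
# signature-first: each mutation draws a clone (cancer cell fraction), a
# signature from that compartment's exposures, a channel from the signature,
# and a genomic position matching the channel's context; read counts follow
# the expected VAF implied by purity, local copy number, multiplicity and
# clone CCF at the configured sequencing depth.

#' Default helical-repeat periods for periodic mutation planting
#'
#' Nucleosomal DNA rotational-setting periods used as the generator's
#' defaults: ~10.3 bp for bulk substitutions and 10.15 bp for
#' SBS17b-attributed substitutions.
#' @return Named numeric vector `c(bulk = 10.3, SBS17b = 10.15)`.
#' @export
default_periods <- function() c(bulk = 10.3, SBS17b = 10.15)

#' Construct a ground-truth record for one synthetic sample
#'
#' @param sample_id Sample identifier.
#' @param stage `"barrett"`, `"primary"` or `"metastasis"`.
#' @param purity Tumour purity in (0, 1].
#' @param exposures Named list of per-compartment exposure vectors (names
#'   `clonal`, `subclonal`, or a single `all`); each sums to one.
#' @param id_exposures Like `exposures` for ID-83 signatures (optional).
#' @param clone_table Tibble `ccf`, `fraction`: exactly one clone with
#'   CCF = 1, fractions summing to one.
#' @param wgd Whole-genome doubled? (background copy state 2+2 vs 1+1).
#' @param early_fraction Fraction of clonal mutations in gained segments
#'   assigned multiplicity 2 (pre-gain, "early").
#' @param cn_events Optional tibble `chrom`, `start`, `end`, `n_major`,
#'   `n_minor` of planted copy-number events (0-based half-open).
#' @param pathway_hits Optional tibble `gene`, `consequence` of planted
#'   gene-level SNV hits (emitted as extra annotated variants).
#' @return List of class `truth_record`.
#' @export
truth_record <- function(sample_id, stage = "primary", purity = 0.7,
                         exposures = list(all = c(SBS17b = 1)),
                         id_exposures = NULL,
                         clone_table = tibble::tibble(ccf = 1, fraction = 1),
                         wgd = FALSE, early_fraction = 0.5,
                         cn_events = NULL, pathway_hits = NULL) {
  if (purity <= 0 || purity > 1) abort("purity must be in (0, 1]")
  for (nm in names(exposures)) {
    e <- exposures[[nm]]
    if (abs(sum(e) - 1) > 1e-6) abort(sprintf("exposures[[%s]] must sum to 1", nm))
    if (any(e < 0)) abort("exposures must be non-negative")
  }
  if (abs(sum(clone_table$fraction) - 1) > 1e-6)
    abort("clone fractions must sum to 1")
  if (sum(clone_table$ccf == 1) != 1)
    abort("exactly one clone must have CCF = 1")
  if (any(clone_table$ccf <= 0 | clone_table$ccf > 1))
    abort("clone CCFs must be in (0, 1]")
  structure(list(sample_id = sample_id, stage = stage, purity = purity,
                 exposures = exposures, id_exposures = id_exposures,
                 clone_table = clone_table, wgd = wgd,
                 early_fraction = early_fraction, cn_events = cn_events,
                 pathway_hits = pathway_hits),
            class = "truth_record")
}

# Copy-number profile: wgd-dependent background with planted events overlaid.
simulate_segments <- function(genome, truth) {
  bg_maj <- if (isTRUE(truth$wgd)) 2L else 1L
  bg_min <- if (isTRUE(truth$wgd)) 2L else 1L
  segs <- purrr::map_dfr(names(genome$chrom_lengths), function(ch) {
    L <- genome$chrom_lengths[[ch]]
    ev <- truth$cn_events
    ev <- if (is.null(ev)) NULL else ev[ev$chrom == ch, ]
    if (is.null(ev) || nrow(ev) == 0)
      return(tibble::tibble(chrom = ch, start = 0L, end = L,
                            n_major = bg_maj, n_minor = bg_min))
    ev <- ev[order(ev$start), ]
    cuts <- sort(unique(c(0L, ev$start, ev$end, L)))
    out <- tibble::tibble(chrom = ch, start = head(cuts, -1), end = tail(cuts, -1),
                          n_major = bg_maj, n_minor = bg_min)
    for (i in seq_len(nrow(ev))) {
      hit <- out$start >= ev$start[i] & out$end <= ev$end[i]
      out$n_major[hit] <- ev$n_major[i]
      out$n_minor[hit] <- ev$n_minor[i]
    }
    out
  })
  segs$sample_id <- truth$sample_id
  segs[c("sample_id", "chrom", "start", "end", "n_major", "n_minor")]
}

# Signed distance to the nearest dyad (positive = downstream of the dyad).
dyad_distance <- function(pos, dyads_pos) {
  d <- sort(dyads_pos)
  i <- findInterval(pos, d)
  left <- ifelse(i >= 1, pos - d[pmax(i, 1L)], Inf)
  right <- ifelse(i < length(d), d[pmin(i + 1L, length(d))] - pos, Inf)
  ifelse(abs(left) <= abs(right), left, -right)
}

# Candidate positions for a canonical trinucleotide, optionally restricted to
# dyad windows.
channel_pool <- function(genome, trinuc, restrict_window = NULL) {
  idx <- trinucleotide_index(genome)
  pool <- idx[[trinuc]]
  if (is.null(pool) || nrow(pool) == 0) return(NULL)
  if (!is.null(restrict_window)) {
    keep <- logical(nrow(pool))
    for (ch in unique(pool$chrom)) {
      i <- pool$chrom == ch
      dd <- dyad_distance(pool$pos[i], genome$dyads$pos[genome$dyads$chrom == ch])
      keep[i] <- abs(dd) <= restrict_window
    }
    pool <- pool[keep, , drop = FALSE]
  }
  pool
}

#' Simulate one sample's somatic variants and copy-number profile
#'
#' SNVs are drawn signature-first (clone -> signature -> SBS-96 channel ->
#' matching genomic position); indels analogously over ID-83 channels using
#' the genome's engineered context sites. When `periodic_config` names a
#' signature, that signature's positions within +/-73 bp of a dyad are
#' accepted with probability proportional to
#' `1 + amplitude * cos(2 * pi * d / period)` (d = signed distance to the
#' dyad). Read counts: per-variant depth ~ Poisson(`depth`), alt reads
#' binomial at the expected VAF `ccf * m * purity / N` with
#' `N = purity * (n_major + n_minor) + 2 * (1 - purity)`.
#'
#' @param genome A [generate_genome()] object.
#' @param truth A [truth_record()].
#' @param n_snvs,n_indels Numbers of channel-sampled SNVs and indels (planted
#'   pathway hits are emitted in addition).
#' @param depth Mean sequencing depth (default 50).
#' @param periodic_config Optional `list(signature, period, amplitude)`.
#' @param sbs_reference,id_reference Signature references (defaults: the
#'   bundled synthetic references).
#' @param restrict_to_dyads If `TRUE`, SNV positions are restricted to within
#'   +/-72 bp of a dyad (useful for periodicity experiments).
#' @param seed Optional seed.
#' @return List: `variants` (tibble with read counts plus ground-truth
#'   columns `compartment`, `signature`, `channel`, `clone_ccf`,
#'   `multiplicity`, `planted`), `segments`, `purity_table`, `truth`.
#' @export
simulate_sample <- function(genome, truth, n_snvs = 5000L, n_indels = 0L,
                            depth = 50L, periodic_config = NULL,
                            sbs_reference = synthetic_signature_reference("sbs96"),
                            id_reference = synthetic_signature_reference("id83"),
                            restrict_to_dyads = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(periodic_config) &&
      (periodic_config$amplitude < 0 || periodic_config$amplitude >= 1))
    abort("periodic amplitude must be in [0, 1)")
  segments <- simulate_segments(genome, truth)
  glen <- sum(segments$end - segments$start)
  ploidy <- sum((segments$end - segments$start) *
                  (segments$n_major + segments$n_minor)) / glen
  rho <- truth$purity

  get_expo <- function(compartment, ref) {
    ex <- if (compartment == "clonal") truth$exposures[["clonal"]] %||%
            truth$exposures[["all"]]
          else truth$exposures[["subclonal"]] %||% truth$exposures[["all"]]
    if (is.null(ex)) abort("truth record lacks exposures for compartment")
    miss <- setdiff(names(ex), colnames(ref$matrix))
    if (length(miss))
      abort(sprintf("exposure signature(s) not in reference: %s",
                    paste(miss, collapse = ", ")))
    ex
  }

  variants <- NULL
  if (n_snvs > 0) {
    clone_i <- sample.int(nrow(truth$clone_table), n_snvs, replace = TRUE,
                          prob = truth$clone_table$fraction)
    ccf <- truth$clone_table$ccf[clone_i]
    compartment <- ifelse(ccf == 1, "clonal", "subclonal")
    sig <- character(n_snvs)
    for (cp in unique(compartment)) {
      ex <- get_expo(cp, sbs_reference)
      i <- compartment == cp
      sig[i] <- sample(names(ex), sum(i), replace = TRUE, prob = ex)
    }
    channel <- character(n_snvs)
    for (s in unique(sig)) {
      i <- sig == s
      pr <- sbs_reference$matrix[, s]
      channel[i] <- sample(rownames(sbs_reference$matrix), sum(i),
                           replace = TRUE, prob = pr)
    }
    chinfo <- parse_sbs_channel(channel)
    trinuc <- paste0(chinfo$five, chinfo$ref, chinfo$three)
    chrom <- character(n_snvs); pos0 <- integer(n_snvs)
    rw <- if (restrict_to_dyads) 72L else NULL
    per_sig <- if (is.null(periodic_config)) character(0) else periodic_config$signature
    for (tn in unique(trinuc)) {
      i <- which(trinuc == tn)
      pool <- channel_pool(genome, tn, rw)
      if (is.null(pool) || nrow(pool) == 0)
        abort(sprintf("no genomic position matches channel context '%s'", tn))
      periodic <- sig[i] %in% per_sig
      if (any(periodic) && !is.null(periodic_config)) {
        ip <- i[periodic]
        need <- length(ip)
        acc_chrom <- character(0); acc_pos <- integer(0)
        A <- periodic_config$amplitude; Tt <- periodic_config$period
        while (length(acc_pos) < need) {
          k <- max(2L * (need - length(acc_pos)), 64L)
          j <- sample.int(nrow(pool), k, replace = TRUE)
          pch <- pool$chrom[j]; pp <- pool$pos[j]
          w <- rep(1, k)
          for (ch in unique(pch)) {
            ii <- pch == ch
            dd <- dyad_distance(pp[ii], genome$dyads$pos[genome$dyads$chrom == ch])
            inwin <- abs(dd) <= 73
            w[ii][inwin] <- 1 + A * cos(2 * pi * dd[inwin] / Tt)
          }
          acc <- runif(k) < w / (1 + A)
          acc_chrom <- c(acc_chrom, pch[acc]); acc_pos <- c(acc_pos, pp[acc])
        }
        chrom[ip] <- acc_chrom[seq_len(need)]
        pos0[ip] <- acc_pos[seq_len(need)]
      }
      iu <- i[!periodic]
      if (length(iu)) {
        j <- sample.int(nrow(pool), length(iu), replace = TRUE)
        chrom[iu] <- pool$chrom[j]; pos0[iu] <- pool$pos[j]
      }
    }
    gbase <- vapply(seq_len(n_snvs), function(k)
      substring(genome$sequences[[chrom[k]]], pos0[k] + 1L, pos0[k] + 1L),
      character(1))
    pyr <- gbase %in% c("C", "T")
    alt <- ifelse(pyr, chinfo$alt, comp_chars(chinfo$alt))
    variants <- tibble::tibble(sample_id = truth$sample_id, chrom = chrom,
                               pos = pos0 + 1L, ref = gbase, alt = alt,
                               kind = "snv", consequence = NA_character_,
                               compartment = compartment, signature = sig,
                               channel = channel, clone_ccf = ccf,
                               planted = FALSE)
  }

  if (n_indels > 0) {
    clone_i <- sample.int(nrow(truth$clone_table), n_indels, replace = TRUE,
                          prob = truth$clone_table$fraction)
    ccf <- truth$clone_table$ccf[clone_i]
    compartment <- ifelse(ccf == 1, "clonal", "subclonal")
    id_truth <- truth$id_exposures %||% list(all = c(ID1 = 0.4, ID2 = 0.4, ID4 = 0.2))
    sig <- character(n_indels)
    for (cp in unique(compartment)) {
      ex <- id_truth[[if (cp == "clonal") "clonal" else "subclonal"]] %||% id_truth[["all"]]
      i <- compartment == cp
      sig[i] <- sample(names(ex), sum(i), replace = TRUE, prob = ex)
    }
    channel <- character(n_indels)
    for (s in unique(sig)) {
      i <- sig == s
      pr <- id_reference$matrix[, s]
      channel[i] <- sample(rownames(id_reference$matrix), sum(i),
                           replace = TRUE, prob = pr)
    }
    rows <- vector("list", n_indels)
    used <- integer(0)
    for (k in seq_len(n_indels)) {
      sites <- which(genome$id_sites$channel == channel[k])
      sites <- setdiff(sites, used)
      if (length(sites) == 0)
        abort(sprintf("engineered sites exhausted for indel channel '%s'",
                      channel[k]))
      si <- if (length(sites) == 1) sites else sample(sites, 1)
      used <- c(used, si)
      rows[[k]] <- genome$id_sites[si, c("chrom", "pos", "ref", "alt")]
    }
    ind <- dplyr::bind_rows(rows)
    ind <- tibble::tibble(sample_id = truth$sample_id, chrom = ind$chrom,
                          pos = ind$pos, ref = ind$ref, alt = ind$alt,
                          kind = variant_kind(ind$ref, ind$alt),
                          consequence = NA_character_,
                          compartment = compartment, signature = sig,
                          channel = channel, clone_ccf = ccf, planted = FALSE)
    variants <- dplyr::bind_rows(variants, ind)
  }

  # planted gene-level SNV hits (extra annotated clonal variants)
  if (!is.null(truth$pathway_hits) && nrow(truth$pathway_hits) > 0) {
    ph <- truth$pathway_hits
    extra <- purrr::map_dfr(seq_len(nrow(ph)), function(i) {
      g <- genome$genes[genome$genes$gene == ph$gene[i], ]
      if (nrow(g) == 0) abort(sprintf("planted gene '%s' not in genome", ph$gene[i]))
      p0 <- sample(seq.int(g$start, g$end - 1L), 1)
      rb <- substring(genome$sequences[[g$chrom]], p0 + 1L, p0 + 1L)
      tibble::tibble(sample_id = truth$sample_id, chrom = g$chrom, pos = p0 + 1L,
                     ref = rb, alt = sample(setdiff(DNA_BASES, rb), 1),
                     kind = "snv", consequence = ph$consequence[i],
                     compartment = "clonal", signature = NA_character_,
                     channel = NA_character_, clone_ccf = 1, planted = TRUE)
    })
    variants <- dplyr::bind_rows(variants, extra)
  }

  # multiplicity and read counts
  v <- variants
  v$n_major <- 1L; v$n_minor <- 1L
  key <- paste(v$chrom)
  for (ch in unique(v$chrom)) {
    i <- which(v$chrom == ch)
    s <- segments[segments$chrom == ch, ]
    s <- s[order(s$start), ]
    j <- findInterval(v$pos[i] - 1L, s$start)
    v$n_major[i] <- s$n_major[pmax(j, 1L)]
    v$n_minor[i] <- s$n_minor[pmax(j, 1L)]
  }
  early <- v$compartment == "clonal" & v$n_major >= 2L &
    runif(nrow(v)) < truth$early_fraction
  v$multiplicity <- ifelse(early, 2L, 1L)
  N <- rho * (v$n_major + v$n_minor) + 2 * (1 - rho)
  evaf <- pmin(v$clone_ccf * v$multiplicity * rho / N, 1)
  dp <- pmax(rpois(nrow(v), depth), 1L)
  v$alt_reads <- rbinom(nrow(v), dp, evaf)
  v$ref_reads <- dp - v$alt_reads

  list(variants = v, segments = segments,
       purity_table = tibble::tibble(sample_id = truth$sample_id,
                                     purity = rho, ploidy = ploidy),
       truth = truth)
}

#' Default cohort configuration
#'
#' Study-condition defaults for [simulate_cohort()]: per-stage sample counts,
#' 5000 SNVs and 300 indels per sample at 50x depth, purity uniform on
#' (0.3, 0.95), half the samples carrying a subclone (CCF uniform on
#' (0.25, 0.6), weight 0.2-0.45), whole-genome doubling probability rising
#' with stage, stage-specific mean exposure templates dominated by SBS17a/b
#' with ageing (SBS1/5/40), oxidative (SBS18) and stage-enriched APOBEC /
#' HRD / platinum contributions, and a subclonal decrease of SBS17a/b
#' (exposure shifted to SBS40/SBS5) in subclones.
#'
#' @param n_barrett,n_primary,n_metastasis Per-stage sample counts.
#' @return Config list for [simulate_cohort()].
#' @export
default_cohort_config <- function(n_barrett = 10L, n_primary = 20L,
                                  n_metastasis = 5L) {
  list(
    stages = list(barrett = n_barrett, primary = n_primary,
                  metastasis = n_metastasis),
    n_snvs = 5000L, n_indels = 200L, depth = 50L,
    purity_range = c(0.3, 0.95),
    subclone_prob = 0.5, subclone_ccf = c(0.25, 0.6),
    subclone_weight = c(0.2, 0.45),
    wgd_prob = c(barrett = 0.05, primary = 0.35, metastasis = 0.45),
    subclonal_sbs17_shift = 0.10,
    exposure_template = list(
      barrett = c(SBS17a = 0.12, SBS17b = 0.22, SBS1 = 0.18, SBS5 = 0.18,
                  SBS18 = 0.15, SBS40 = 0.15),
      primary = c(SBS17a = 0.12, SBS17b = 0.24, SBS1 = 0.10, SBS5 = 0.12,
                  SBS18 = 0.10, SBS40 = 0.12, SBS2 = 0.07, SBS3 = 0.07,
                  SBS35 = 0.06),
      metastasis = c(SBS17a = 0.15, SBS17b = 0.30, SBS1 = 0.08, SBS5 = 0.10,
                     SBS18 = 0.07, SBS40 = 0.15, SBS2 = 0.05, SBS3 = 0.05,
                     SBS35 = 0.05)),
    id_template = c(ID1 = 0.35, ID2 = 0.35, ID4 = 0.15, ID9 = 0.15),
    exposure_concentration = 60
  )
}

#' Simulate a multi-stage synthetic cohort
#'
#' Draws per-sample truth records from the configuration, simulates each
#' sample, and (optionally) writes a self-contained dataset: one VCF per
#' sample, combined copy-number segment and purity tables, a clinical table,
#' the ground truth (JSON), and a checksum manifest. Deterministic per seed.
#'
#' @param config See [default_cohort_config()].
#' @param genome A genome, or `NULL` to generate a default 1 Mb genome.
#' @param out_dir Output directory (`NULL` = in-memory only).
#' @param seed Seed.
#' @return List: `samples` (per-sample simulation outputs), `truth`
#'   (per-sample truth summary tibble), `clinical`, `purity_table`,
#'   `segments`, and `manifest` (when files were written).
#' @export
simulate_cohort <- function(config = default_cohort_config(), genome = NULL,
                            out_dir = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(genome)) genome <- generate_genome(seed = seed + 1000L)
  stages <- rep(names(config$stages), unlist(config$stages))
  n <- length(stages)
  ids <- sprintf("S%03d", seq_len(n))
  samples <- vector("list", n)
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    st <- stages[i]
    tmpl <- config$exposure_template[[st]]
    alpha <- tmpl * config$exposure_concentration
    e <- stats::rgamma(length(tmpl), shape = alpha)
    e <- setNames(e / sum(e), names(tmpl))
    has_sub <- runif(1) < config$subclone_prob
    clone_table <- tibble::tibble(ccf = 1, fraction = 1)
    expos <- list(all = e)
    if (has_sub) {
      w <- runif(1, config$subclone_weight[1], config$subclone_weight[2])
      clone_table <- tibble::tibble(
        ccf = c(1, runif(1, config$subclone_ccf[1], config$subclone_ccf[2])),
        fraction = c(1 - w, w))
      esub <- e
      for (s17 in intersect(c("SBS17a", "SBS17b"), names(esub))) {
        d <- min(config$subclonal_sbs17_shift, esub[s17])
        esub[s17] <- esub[s17] - d
        tgt <- intersect(c("SBS40", "SBS5"), names(esub))[1]
        esub[tgt] <- esub[tgt] + d
      }
      expos <- list(clonal = e, subclonal = esub / sum(esub))
    }
    tr <- truth_record(
      sample_id = ids[i], stage = st,
      purity = runif(1, config$purity_range[1], config$purity_range[2]),
      exposures = expos,
      id_exposures = list(all = config$id_template),
      clone_table = clone_table,
      wgd = runif(1) < config$wgd_prob[[st]])
    samples[[i]] <- simulate_sample(genome, tr, n_snvs = config$n_snvs,
                                    n_indels = config$n_indels,
                                    depth = config$depth)
    truth_rows[[i]] <- tibble::tibble(
      sample = ids[i], stage = st, purity = tr$purity,
      ploidy = samples[[i]]$purity_table$ploidy, wgd = tr$wgd,
      n_clones = nrow(clone_table),
      subclonal_fraction = ifelse(has_sub, clone_table$fraction[2], 0),
      subclone_ccf = ifelse(has_sub, clone_table$ccf[2], NA_real_),
      exposures = list(expos))
  }
  truth <- dplyr::bind_rows(truth_rows)
  clinical <- tibble::tibble(
    sample = ids, stage = stages,
    treated = stages != "barrett" & runif(n) < 0.7,
    smoking = sample(c("never", "past", "current"), n, replace = TRUE,
                     prob = c(0.4, 0.4, 0.2)),
    mandard_trg = ifelse(stages == "primary", sample(1:5, n, replace = TRUE),
                         NA_integer_),
    os_months = round(stats::rexp(n, rate = 1 / 36), 1),
    os_event = runif(n) < 0.6)
  segments <- dplyr::bind_rows(purrr::map(samples, "segments"))
  purity_table <- dplyr::bind_rows(purrr::map(samples, "purity_table"))
  out <- list(samples = setNames(samples, ids), truth = truth,
              clinical = clinical, purity_table = purity_table,
              segments = segments, genome = genome)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    if (file.access(out_dir, 2) != 0)
      abort(sprintf("output directory '%s' is not writable", out_dir))
    for (i in seq_len(n))
      write_vcf(samples[[i]]$variants, file.path(out_dir, paste0(ids[i], ".vcf")))
    write_segments(segments, file.path(out_dir, "segments.tsv"))
    readr::write_tsv(tibble::tibble(sample = purity_table$sample_id,
                                    purity = purity_table$purity,
                                    ploidy = purity_table$ploidy),
                     file.path(out_dir, "purity.tsv"))
    readr::write_tsv(clinical, file.path(out_dir, "clinical.tsv"))
    jsonlite::write_json(truth |> dplyr::select(-"exposures"),
                         file.path(out_dir, "truth.json"), digits = NA)
    write_genome_fasta(genome, file.path(out_dir, "genome.fa"),
                       file.path(out_dir, "dyads.bed"))
    files <- setdiff(list.files(out_dir), "manifest.tsv")
    manifest <- tibble::tibble(
      file = files,
      md5 = unname(tools::md5sum(file.path(out_dir, files))))
    readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
    out$manifest <- manifest
  }
  out
}
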