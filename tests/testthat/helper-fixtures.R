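# Shared fixtures (memoized across test files) and independent brute-force
# oracles used to validate the fast implementations.

.fixture_env <- new.env(parent = emptyenv())

# Small genome shared by most tests.
test_genome <- function() {
  if (is.null(.fixture_env$genome))
    .fixture_env$genome <- generate_genome(chrom_length = 3e5,
                                           id_sites_per_channel = 12L, seed = 42)
  .fixture_env$genome
}

test_sbs_reference <- function() synthetic_signature_reference("sbs96")
test_id_reference <- function() synthetic_signature_reference("id83")

# ---- dip statistic oracle -------------------------------------------------
# Direct enumeration over mode placements. The greatest convex minorant of a
# finite point set, evaluated at a data point, is the minimum over all chords
# between points spanning it; deviations are computed from that definition
# rather than from the incremental hull used by the implementation.

chord_min <- function(xs, ys, i) {
  n <- length(xs)
  best <- ys[i]
  for (a in seq_len(i)) for (b in i:n) {
    if (xs[b] == xs[a]) next
    lam <- (xs[i] - xs[a]) / (xs[b] - xs[a])
    best <- min(best, ys[a] + lam * (ys[b] - ys[a]))
  }
  best
}

oracle_prefix_dev <- function(xs, l, u, j) {
  if (j == 1) return(0)
  mx <- 0
  for (i in seq_len(j - 1)) {
    h <- chord_min(xs[1:j], l[1:j], i)
    mx <- max(mx, u[i] - h)
  }
  mx
}

oracle_dip <- function(values) {
  xs <- sort(values)
  n <- length(xs)
  ux <- unique(xs)
  k <- length(ux)
  u <- vapply(ux, function(v) sum(xs <= v) / n, numeric(1))
  l <- vapply(ux, function(v) sum(xs < v) / n, numeric(1))
  A <- vapply(seq_len(k), function(j) oracle_prefix_dev(ux, l, u, j), numeric(1))
  xr <- -rev(ux); lr <- 1 - rev(u); ur <- 1 - rev(l)
  Ar <- vapply(seq_len(k), function(j) oracle_prefix_dev(xr, lr, ur, j), numeric(1))
  B <- rev(Ar)
  0.5 * min(pmax(A, B))
}

# ---- periodogram oracle ---------------------------------------------------
oracle_power <- function(r, offsets, periods) {
  r <- r - mean(r)
  vapply(periods, function(Tt) {
    s <- sum(r * exp(-2i * pi * offsets / Tt))
    Mod(s)^2
  }, numeric(1))
}

# ---- NNLS oracle: grid search over the 2-signature weight simplex ---------
oracle_two_sig_weight <- function(v, a, b, step = 0.01) {
  ws <- seq(0, 1, by = step)
  errs <- vapply(ws, function(w) sum((v - (w * a + (1 - w) * b))^2), numeric(1))
  ws[which.min(errs)]
}

# ---- indel classification oracle ------------------------------------------
# Exhaustive repeat/homology scan written independently of the package code:
# run lengths via rle over the exploded sequence, repeats and microhomology
# via explicit character comparison.
oracle_indel_channel <- function(chrom_seq, pos, ref, alt) {
  chars <- strsplit(chrom_seq, "")[[1]]
  # minimal representation (suffix then prefix trim) and left alignment,
  # redone with character vectors
  r <- strsplit(ref, "")[[1]]; a <- strsplit(alt, "")[[1]]
  while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1
  }
  is_del <- length(r) > length(a)
  seq <- if (is_del) r[-1] else a[-1]
  start <- pos + 1  # 1-based index of first inserted/deleted base
  repeat {
    if (start <= 1) break
    if (chars[start - 1] != seq[length(seq)]) break
    seq <- c(seq[length(seq)], seq[-length(seq)])
    start <- start - 1
  }
  k <- length(seq)
  if (k == 1) {
    run <- 0; p <- start
    while (p <= length(chars) && chars[p] == seq) { run <- run + 1; p <- p + 1 }
    b <- if (seq %in% c("C", "G")) "C" else "T"
    if (is_del) paste0("1:Del:", b, ":", min(run, 6) - 1)
    else paste0("1:Ins:", b, ":", min(run, 5))
  } else {
    copies <- 0; p <- start
    while (p + k - 1 <= length(chars) &&
           identical(chars[p:(p + k - 1)], seq)) { copies <- copies + 1; p <- p + k }
    size <- min(k, 5)
    if (!is_del) return(paste0(size, ":Ins:R:", min(copies, 5)))
    if (copies >= 2) return(paste0(size, ":Del:R:", min(copies, 6) - 1))
    after <- start + k
    mh <- 0
    while (mh < k - 1 && after + mh <= length(chars) &&
           chars[after + mh] == seq[mh + 1]) mh <- mh + 1
    if (mh >= 1) {
      cap <- c(`2` = 1, `3` = 2, `4` = 3, `5` = 5)[as.character(size)]
      paste0(size, ":Del:M:", min(mh, cap))
    } else paste0(size, ":Del:R:0")
  }
}

# ---- misc helpers ---------------------------------------------------------
cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# A minimal variant tibble.
make_variants <- function(sample_id, chrom, pos, ref, alt,
                          alt_reads = 20L, ref_reads = 30L,
                          consequence = NA_character_) {
  tibble::tibble(sample_id = sample_id, chrom = chrom, pos = pos, ref = ref,
                 alt = alt, ref_reads = ref_reads, alt_reads = alt_reads,
                 kind = mutsigdyn:::variant_kind(ref, alt),
                 consequence = consequence)
}
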