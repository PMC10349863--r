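#' Signature reference matrices
#'
#' A signature reference holds per-channel probabilities for a set of named
#' mutational signatures over a canonical channel set (SBS-96 or ID-83).
#' Columns sum to one; channels are kept in canonical order.
#'
#' @param matrix Numeric matrix, channels x signatures, with rownames equal
#'   to the canonical channel labels and colnames the signature names.
#' @param kind `"sbs96"` or `"id83"`.
#' @return An object of class `signature_reference`.
#' @export
new_signature_reference <- function(matrix, kind = c("sbs96", "id83")) {
  kind <- match.arg(kind)
  channels <- channel_set(kind)
  if (is.null(rownames(matrix)) || !setequal(rownames(matrix), channels))
    abort(sprintf("signature matrix rows must be the %d canonical %s channels",
                  length(channels), kind))
  matrix <- matrix[channels, , drop = FALSE]
  if (any(matrix < 0)) abort("signature probabilities must be non-negative")
  sums <- colSums(matrix)
  off <- abs(sums - 1) > 1e-3
  if (any(off))
    abort(sprintf("signature column(s) %s do not sum to 1 (within 1e-3)",
                  paste(colnames(matrix)[off], collapse = ", ")))
  matrix <- sweep(matrix, 2, sums, "/")
  structure(list(kind = kind, channels = channels, matrix = matrix),
            class = "signature_reference")
}

#' @export
print.signature_reference <- function(x, ...) {
  cat("<signature_reference>", x$kind, ":", ncol(x$matrix), "signatures x",
      nrow(x$matrix), "channels\n")
  cat("  ", paste(colnames(x$matrix), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.signature_reference <- function(x, ...) {
  tibble::as_tibble(x$matrix, rownames = "channel") |>
    tidyr::pivot_longer(-"channel", names_to = "signature", values_to = "probability")
}

# Sparse Dirichlet profile over `channels`, mass on `n_active` channels.
dirichlet_profile <- function(n_channels, n_active, alpha = 0.5) {
  w <- numeric(n_channels)
  act <- sample.int(n_channels, n_active)
  g <- stats::rgamma(n_active, shape = alpha)
  w[act] <- g / sum(g)
  # small dense floor so no channel has exactly zero probability
  w <- 0.98 * w + 0.02 / n_channels
  w / sum(w)
}

#' Bundled synthetic signature reference
#'
#' A deterministic, fully synthetic stand-in for a catalogue of known
#' mutational signatures. Signature names reuse the field's labels (SBS1,
#' SBS17a/b, ID6, ...) so that downstream rules (repair-deficiency calls,
#' dominance grouping) can be expressed naturally, but the channel profiles
#' are synthetic: a few signatures carry a hand-crafted characteristic
#' (SBS1-like CpG C>T; APOBEC-like TpC; SBS17a/b-like T>C / T>G at NpTpT;
#' slippage-like 1-bp homopolymer indels; microhomology-deletion-rich ID6),
#' and the rest are sparse random profiles fixed by an internal seed. They
#' are NOT the COSMIC profiles.
#'
#' @param kind `"sbs96"` or `"id83"`.
#' @return A [new_signature_reference()] object.
#' @export
synthetic_signature_reference <- function(kind = c("sbs96", "id83")) {
  kind <- match.arg(kind)
  with_preserved_seed(8150423L, {
    if (kind == "sbs96") synthetic_sbs_reference() else synthetic_id_reference()
  })
}

synthetic_sbs_reference <- function() {
  ch <- sbs96_channels()
  n <- length(ch)
  put <- function(labels, weights) {
    w <- numeric(n)
    w[match(labels, ch)] <- weights
    w <- 0.9 * w / sum(w) + 0.1 * dirichlet_profile(n, 10)
    w / sum(w)
  }
  sigs <- list(
    SBS1   = put(paste0(DNA_BASES, "[C>T]G"), rep(1, 4)),
    SBS2   = put(c("T[C>T]A", "T[C>T]T", "T[C>G]A", "T[C>G]T"), c(1, 1, 0.8, 0.8)),
    SBS17a = put(c("C[T>C]T", "T[T>C]T", "A[T>C]T", "G[T>C]T"), c(1.2, 1, 0.5, 0.3)),
    SBS17b = put(c("C[T>G]T", "T[T>G]T", "A[T>G]T", "C[T>G]G"), c(1.8, 1, 0.4, 0.3)),
    SBS18  = put(c("C[C>A]A", "C[C>A]T", "T[C>A]T", "G[C>A]A"), c(1, 0.8, 0.8, 0.6))
  )
  for (s in c("SBS3", "SBS5", "SBS8", "SBS35", "SBS40", "SBS41", "SBS44"))
    sigs[[s]] <- dirichlet_profile(n, 14)
  m <- do.call(cbind, sigs)
  rownames(m) <- ch
  new_signature_reference(m, "sbs96")
}

synthetic_id_reference <- function() {
  ch <- id83_channels()
  n <- length(ch)
  put <- function(labels, weights) {
    w <- numeric(n)
    w[match(labels, ch)] <- weights
    w <- 0.9 * w / sum(w) + 0.1 * dirichlet_profile(n, 8)
    w / sum(w)
  }
  sigs <- list(
    ID1  = put(paste0("1:Ins:T:", 3:5), c(0.6, 1, 1.2)),
    ID2  = put(paste0("1:Del:T:", 3:5), c(0.6, 1, 1.2)),
    ID6  = put(paste0("5:Del:M:", 2:5), c(0.5, 0.8, 1, 1.2)),
    ID8  = put(c("5:Del:M:1", "5:Del:R:0", "4:Del:R:0", "3:Del:R:0"), c(1, 0.8, 0.6, 0.5)),
    ID18 = put(c("1:Del:T:4", "2:Del:R:1", "2:Del:R:2"), c(1, 0.7, 0.5))
  )
  for (s in c("ID4", "ID9"))
    sigs[[s]] <- dirichlet_profile(n, 10)
  m <- do.call(cbind, sigs)
  rownames(m) <- ch
  new_signature_reference(m, "id83")
}
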