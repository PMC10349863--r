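# Canonical mutation channel definitions: SBS-96 trinucleotide substitution
# channels and ID-83 indel channels, in the customary catalogue order
# (substitution class major, then 5' and 3' flank; indels grouped by size,
# type and repeat/microhomology context).

SBS_SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Canonical SBS-96 channel labels
#'
#' The 96 pyrimidine-centred single-base-substitution channels, e.g.
#' `A[C>T]G`, ordered by substitution class (`C>A`, `C>G`, `C>T`, `T>A`,
#' `T>C`, `T>G`) and within class by 5' then 3' flanking base (A, C, G, T).
#'
#' @return Character vector of length 96.
#' @export
sbs96_channels <- function() {
  unlist(lapply(SBS_SUBSTITUTIONS, function(s) {
    as.vector(t(outer(DNA_BASES, DNA_BASES, function(f, t)
      paste0(f, "[", s, "]", t))))
  }))
}

#' Canonical ID-83 channel labels
#'
#' Indel channels in COSMIC-style notation `size:type:context:count`:
#' 1-bp deletions/insertions by base (C/T after pyrimidine folding) and
#' homopolymer length; longer indels by repeat-unit size (capped at 5+) and
#' tandem repeat count; deletions not at repeats by flanking microhomology
#' length. For deletions `count` is the number of copies of the deleted unit
#' present in the reference minus one (so `1:Del:T:4` is a T deleted from a
#' homopolymer of length 5); for insertions it is the number of pre-existing
#' copies (so `1:Ins:T:0` is a T inserted with no adjacent T).
#'
#' @return Character vector of length 83.
#' @export
id83_channels <- function() {
  ch <- character(0)
  for (b in c("C", "T")) ch <- c(ch, paste0("1:Del:", b, ":", 0:5))
  for (b in c("C", "T")) ch <- c(ch, paste0("1:Ins:", b, ":", 0:5))
  for (k in 2:5) ch <- c(ch, paste0(k, ":Del:R:", 0:5))
  for (k in 2:5) ch <- c(ch, paste0(k, ":Ins:R:", 0:5))
  ch <- c(ch, "2:Del:M:1")
  ch <- c(ch, paste0("3:Del:M:", 1:2))
  ch <- c(ch, paste0("4:Del:M:", 1:3))
  ch <- c(ch, paste0("5:Del:M:", 1:5))
  ch
}

channel_set <- function(kind = c("sbs96", "id83")) {
  kind <- match.arg(kind)
  if (kind == "sbs96") sbs96_channels() else id83_channels()
}

# Split an SBS-96 label into its parts.
parse_sbs_channel <- function(channel) {
  tibble::tibble(
    channel = channel,
    five = substr(channel, 1, 1),
    ref = substr(channel, 3, 3),
    alt = substr(channel, 5, 5),
    three = substr(channel, 7, 7)
  )
}
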