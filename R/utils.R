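#' @importFrom rlang abort warn .data
#' @importFrom stats median sd quantile setNames rbinom rpois runif rnorm
#' @importFrom utils head tail
NULL

# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards.
# Used for deterministic built-in objects (e.g. the bundled synthetic
# signature reference) so they never perturb user seeds.
with_preserved_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(x) {
  vapply(strsplit(x, ""), function(b) paste(rev(unname(COMPLEMENT[b])), collapse = ""), character(1))
}

#' Extract substrings of a chromosome sequence
#'
#' Internal coordinates are 0-based half-open; this helper converts to the
#' 1-based inclusive coordinates `substring()` expects.
#' @noRd
seq_window <- function(seq, start0, end0) {
  substring(seq, start0 + 1L, end0)
}

stopifnot_scalar_number <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || (positive && x <= 0))
    abort(sprintf("`%s` must be a single %snumber", name, if (positive) "positive " else ""))
  invisible(x)
}
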