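# Signature refitting: non-negative least squares of the normalized channel
# spectrum on a reference matrix, pruning of small contributions at a 5%
# threshold, and a restricted refit on the surviving signatures. Mirrors the
# practice of fixing exposures below 5% to zero because contributions that
# small cannot be estimated reliably from a single genome.

#' Fit signature exposures for one catalogue row
#'
#' Stages: (1) non-negative least squares of the normalized spectrum on the
#' reference matrix; (2) normalization of the weights to sum one; (3) all
#' weights below `threshold` set to exactly zero; (4) restricted NNLS refit
#' on the surviving signatures, renormalized. The residual is the Euclidean
#' norm between the observed normalized spectrum and its reconstruction from
#' the restricted fit.
#'
#' @param counts Named numeric vector of channel counts (names must be the
#'   reference's channels, any order), or an unnamed vector in canonical
#'   channel order.
#' @param reference A [new_signature_reference()] object.
#' @param threshold Relative contribution below which a signature is zeroed
#'   (default 0.05).
#' @return List with `exposures` (named fractions summing to one, pruned
#'   entries exactly zero), `residual`, and `flag` (`"ok"` or `"empty"`).
#' @export
fit_exposures <- function(counts, reference, threshold = 0.05) {
  A <- reference$matrix
  if (!is.null(names(counts))) {
    if (!setequal(names(counts), rownames(A)))
      abort("channel names of `counts` do not match the reference")
    counts <- counts[rownames(A)]
  } else if (length(counts) != nrow(A)) {
    abort(sprintf("expected %d channels, got %d", nrow(A), length(counts)))
  }
  sigs <- colnames(A)
  if (sum(counts) == 0)
    return(list(exposures = setNames(rep(0, length(sigs)), sigs),
                residual = NA_real_, flag = "empty"))
  v <- as.numeric(counts) / sum(counts)
  w <- pracma::lsqnonneg(A, v)$x
  if (sum(w) == 0)
    return(list(exposures = setNames(rep(0, length(sigs)), sigs),
                residual = sqrt(sum(v^2)), flag = "degenerate"))
  w <- w / sum(w)
  keep <- w >= threshold
  if (!any(keep)) keep <- w == max(w)  # always retain the top signature
  w2 <- numeric(length(sigs))
  fit2 <- pracma::lsqnonneg(A[, keep, drop = FALSE], v)$x
  recon <- as.numeric(A[, keep, drop = FALSE] %*% fit2)
  if (sum(fit2) > 0) w2[keep] <- fit2 / sum(fit2)
  list(exposures = setNames(w2, sigs),
       residual = sqrt(sum((v - recon)^2)), flag = "ok")
}

#' Fit signature exposures for a whole catalogue
#'
#' Row-wise application of [fit_exposures()]. Per-sample failures are
#' recorded in the `flag` column rather than aborting the cohort.
#'
#' @param catalogue Wide catalogue tibble from [build_catalogue()].
#' @param reference A `signature_reference` matching the catalogue's kind.
#' @param threshold Pruning threshold, see [fit_exposures()].
#' @param compartment Label stored on the result (`"all"`, `"clonal"`,
#'   `"subclonal"`, `"clonal_early"`, `"clonal_late"`).
#' @return An `exposure_table`: tibble `sample`, `n_mutations`, `residual`,
#'   `flag`, then one fraction column per signature.
#' @export
fit_cohort <- function(catalogue, reference, threshold = 0.05, compartment = "all") {
  m <- catalogue_matrix(catalogue)
  rows <- lapply(seq_len(nrow(m)), function(i) {
    f <- fit_exposures(setNames(m[i, ], colnames(m)), reference, threshold)
    tibble::tibble(sample = catalogue$sample[i], n_mutations = sum(m[i, ]),
                   residual = f$residual, flag = f$flag,
                   !!!as.list(f$exposures))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("exposure_table", class(out))
  attr(out, "signatures") <- colnames(reference$matrix)
  attr(out, "compartment") <- compartment
  out
}

#' @export
tidy.exposure_table <- function(x, ...) {
  sigs <- attr(x, "signatures")
  tidyr::pivot_longer(tibble::as_tibble(x)[c("sample", "n_mutations", sigs)],
                      dplyr::all_of(sigs), names_to = "signature",
                      values_to = "fraction") |>
    dplyr::mutate(mutations = .data$fraction * .data$n_mutations)
}

#' @export
glance.exposure_table <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x),
                 n_signatures = length(attr(x, "signatures")),
                 compartment = attr(x, "compartment") %||% "all",
                 median_residual = median(x$residual, na.rm = TRUE))
}

#' Default repair-deficiency rules
#'
#' Each rule is a conjunction of signature exposures that must all exceed the
#' threshold (strictly): homologous-recombination deficiency requires SBS3,
#' SBS8, ID6 and ID8 each above 5%; the colibactin flag requires SBS41 and
#' ID18; mismatch-repair deficiency requires SBS44.
#'
#' @param threshold Exposure threshold (default 0.05).
#' @return Named list of rules, each `list(signatures, threshold)`.
#' @export
deficiency_rules <- function(threshold = 0.05) {
  list(HRD = list(signatures = c("SBS3", "SBS8", "ID6", "ID8"), threshold = threshold),
       colibactin = list(signatures = c("SBS41", "ID18"), threshold = threshold),
       MMRd = list(signatures = "SBS44", threshold = threshold))
}

#' Call repair-deficiency phenotypes from exposure tables
#'
#' @param sbs_exposures,id_exposures `exposure_table`s sharing samples (the
#'   ID table may be `NULL` if no rule references ID signatures).
#' @param rules Rules as produced by [deficiency_rules()].
#' @return Tibble `sample` plus one logical column per rule.
#' @export
call_deficiencies <- function(sbs_exposures, id_exposures = NULL,
                              rules = deficiency_rules()) {
  tabs <- list(sbs_exposures, id_exposures)
  tabs <- tabs[!vapply(tabs, is.null, logical(1))]
  lookup <- function(sig) {
    for (t in tabs) if (sig %in% names(t)) return(setNames(t[[sig]], t$sample))
    abort(sprintf("signature '%s' referenced by a deficiency rule is absent", sig))
  }
  samples <- sbs_exposures$sample
  if (!is.null(id_exposures) && !setequal(samples, id_exposures$sample))
    abort("SBS and ID exposure tables must share samples")
  out <- tibble::tibble(sample = samples)
  for (rn in names(rules)) {
    rule <- rules[[rn]]
    hit <- rep(TRUE, length(samples))
    for (sig in rule$signatures) {
      vals <- unname(lookup(sig)[samples])
      hit <- hit & !is.na(vals) & vals > rule$threshold
    }
    out[[rn]] <- hit
  }
  out
}
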