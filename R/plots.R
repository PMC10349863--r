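# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_point
#'   geom_vline geom_boxplot geom_hline labs facet_wrap theme_minimal
NULL

#' Plot a periodicity result
#'
#' Two panels are available: the relative-increase profile around the dyad
#' (`which = "profile"`) and the oversampled periodogram with the max-power
#' period marked (`which = "periodogram"`).
#'
#' @param object A `periodicity_result`.
#' @param which `"profile"` or `"periodogram"`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.periodicity_result <- function(object, which = c("periodogram", "profile"),
                                        ...) {
  which <- match.arg(which)
  if (which == "profile") {
    ggplot(object$profile, aes(x = .data$offset, y = .data$rel_increase)) +
      geom_line(colour = "grey30") +
      geom_hline(yintercept = 0, linetype = 2, colour = "grey70") +
      labs(x = "distance to dyad (bp)", y = "relative increase",
           title = sprintf("Nucleosome-relative mutation rate (n = %d)",
                           object$n_stacked)) +
      theme_minimal()
  } else {
    ggplot(object$periodogram, aes(x = .data$period, y = .data$power)) +
      geom_line(colour = "grey30") +
      geom_vline(xintercept = object$max_power_period, colour = "red",
                 linetype = 2) +
      labs(x = "period (bp)", y = "power",
           title = sprintf("MP = %.2f bp, SNR = %.1f, p = %.3g",
                           object$max_power_period, object$snr, object$p)) +
      theme_minimal()
  }
}

#' Plot an exposure table as stacked per-sample contributions
#'
#' @param object An `exposure_table`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.exposure_table <- function(object, ...) {
  tidy(object) |>
    ggplot(aes(x = .data$sample, y = .data$fraction, fill = .data$signature)) +
    geom_col() +
    labs(x = NULL, y = "exposure fraction", fill = "signature") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 6))
}

#' Plot subclonal exposure shifts
#'
#' Boxplots of the per-sample subclonal-minus-clonal exposure change by
#' signature (and stage when available); values below zero indicate a
#' subclonal decrease.
#'
#' @param object A `shift_table` from [subclonal_shifts()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.shift_table <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$signature, y = .data$delta)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    geom_boxplot(outlier.size = 0.5) +
    labs(x = NULL, y = expression(Delta ~ "(subclonal - clonal)")) +
    theme_minimal()
  if ("stage" %in% names(object))
    p <- p + ggplot2::aes(fill = .data$stage)
  p
}

#' Plot stage-model feature importances
#'
#' @param object A `stage_model`.
#' @param top_n Number of features to show.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.stage_model <- function(object, top_n = 15L, ...) {
  d <- head(object$importance, top_n)
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot(d, aes(x = .data$importance, y = .data$feature)) +
    geom_col(fill = "steelblue") +
    labs(x = "permutation importance (AUC drop)", y = NULL,
         title = sprintf("%s: held-out AUC %.2f", object$learner, object$auc)) +
    theme_minimal()
}
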