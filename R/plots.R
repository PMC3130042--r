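# ggplot2 displays: QQ diagnostics for the scan, factor composition bars,
# and score-by-genotype strip plots.

#' QQ plot of scan p-values
#'
#' Observed versus expected -log10 p-values under the uniform null, with the
#' identity line; Bonferroni-significant factors are highlighted.
#'
#' @param object A `pqtl_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pqtl_scan <- function(object, ...) {
  res <- dplyr::arrange(object$results, .data$p_value)
  qq <- qq_points(res$p_value)
  qq$significant <- res$significant  # both sorted ascending in p
  ggplot2::ggplot(qq, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p))) +
    ggplot2::theme_minimal()
}

#' Composition bars for a metaprotein fit
#'
#' Coverage (share of the seed protein's identified peptides inside the
#' factor) and signature (share of the factor coming from the seed protein)
#' per fitted metaprotein.
#'
#' @param object A `metaprotein_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metaprotein_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$composition,
                              c("coverage_pct", "signature_pct"),
                              names_to = "metric", values_to = "pct")
  long$metric <- ifelse(long$metric == "coverage_pct", "% coverage", "% signature")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$factor, y = .data$pct,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "percent", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Score-by-genotype strip plot
#'
#' One metaprotein score stratified by genotype, points coloured by outcome
#' when available.
#'
#' @param scores Score tibble (`sample_id` + factor columns).
#' @param cohort Cohort tibble.
#' @param factor Name of the score column to plot.
#' @return A ggplot.
#' @export
plot_score_by_genotype <- function(scores, cohort, factor) {
  d <- dplyr::inner_join(scores[c("sample_id", factor)], cohort, by = "sample_id")
  d$genotype <- base::factor(d$genotype, levels = c("CC", "CT", "TT"))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$genotype, y = .data[[factor]]))
  if (any(!is.na(d$outcome))) {
    p <- p + ggplot2::geom_jitter(ggplot2::aes(shape = .data$outcome),
                                  width = 0.1, size = 2)
  } else {
    p <- p + ggplot2::geom_jitter(width = 0.1, size = 2)
  }
  p + ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                            width = 0.4, linewidth = 0.3) +
    ggplot2::labs(y = sprintf("%s metaprotein score", factor)) +
    ggplot2::theme_minimal()
}
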