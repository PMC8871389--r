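# ggplot2 views of the main result types.

call_palette <- c(up = "#c0392b", down = "#2c6fbb", ns = "grey70")

#' Volcano plot of differential aggregation
#'
#' @param object An `aggdiff` fit.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot aggdiff
#' @export
autoplot.aggdiff <- function(object, ...) {
  r <- tidy(object)
  ggplot2::ggplot(r, ggplot2::aes(x = .data$log2fc,
                                  y = -log10(.data$p_adjusted),
                                  colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = call_palette) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * object$config$lfc_threshold,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(object$config$alpha),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "log2 fold change (case - control)",
                  y = "-log10 adjusted p", colour = "call") +
    ggplot2::theme_minimal()
}

#' Volcano plot of RNA-seq differential expression
#'
#' @param object An `aggde` fit.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot aggde
#' @export
autoplot.aggde <- function(object, ...) {
  r <- tidy(object)
  ggplot2::ggplot(r, ggplot2::aes(x = .data$logFC,
                                  y = -log10(.data$fdr),
                                  colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = call_palette) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 FDR",
                  colour = "call") +
    ggplot2::theme_minimal()
}

#' Supersaturation scatter with the median-saturation diagonal
#'
#' Transcript abundance against standardised aggregation propensity, with
#' the iso-sigma line through the reference median; proteins above the
#' diagonal are relatively supersaturated.
#'
#' @param scores A [supersaturation_scores()] tibble.
#' @param labels Optional [classify_fractions()] tibble to colour points by
#'   fraction.
#' @return A ggplot.
#' @export
plot_supersaturation <- function(scores, labels = NULL) {
  d <- scores
  if (!is.null(labels)) {
    d <- dplyr::left_join(d, labels, by = "id")
  } else {
    d$label <- factor("all")
  }
  tau <- attr(scores, "tau")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$z_propensity,
                                       y = .data$log_abundance,
                                       colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::labs(x = "aggregation propensity (z)",
                  y = "log10 transcript abundance", colour = "fraction") +
    ggplot2::theme_minimal()
  if (!is.null(tau)) {
    p <- p + ggplot2::geom_abline(intercept = tau, slope = -1,
                                  linetype = "dashed", colour = "grey30")
  }
  p
}

#' Per-fraction score distributions
#'
#' @param scores Named numeric vector id -> score.
#' @param labels A [classify_fractions()] tibble.
#' @param score_name Axis label.
#' @return A ggplot (violin + median).
#' @export
plot_fraction_scores <- function(scores, labels, score_name = "score") {
  d <- labels
  d$score <- unname(scores[match(d$id, names(scores))])
  d <- d[!is.na(d$score), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$score)) +
    ggplot2::geom_violin(fill = "grey85", colour = NA) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.5, colour = "#c0392b",
                          linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = score_name) +
    ggplot2::theme_minimal()
}
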