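#' Plot gamete-class frequencies across double-reduction values
#'
#' Shows how the three diploid-gamete classes of a tetraploid parent
#' shift with the double-reduction coefficient: double reduction converts
#' heterozygous gametes into the two homozygous classes.
#'
#' @param dosage parental mutant dosage (0..4).
#' @param alphas double-reduction coefficients to evaluate.
#' @return A ggplot object.
#' @examples
#' plot_gamete_frequencies(2)
#' @export
plot_gamete_frequencies <- function(dosage,
                                    alphas = seq(0, 1 / 6, length.out = 25)) {
  df <- purrr::map_dfr(alphas, function(a) {
    g <- gamete_frequencies(dosage, as_frac(a, strict = FALSE))
    tibble::tibble(alpha = a, label = g$label, prob = g$prob)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$alpha, y = .data$prob,
                                   colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "double-reduction coefficient α",
      y = "gamete-class frequency",
      colour = "gamete class",
      title = sprintf("%s parent (dosage %d)", dosage_name(dosage), dosage)
    ) +
    ggplot2::theme_minimal()
}

#' Autoplot a model-fit table
#'
#' One panel per assay, bars of the chi-square statistic per candidate
#' model on a log scale, with the rejection critical value drawn as a
#' dashed line. Accepted models are filled; rejected ones hollow.
#'
#' @param object a `seg_fit_tbl` from [fit_all_models()].
#' @param ... unused.
#' @return A ggplot object.
#' @examples
#' autoplot(fit_all_models(published_observed("tetraploid_a")))
#' @export
autoplot.seg_fit_tbl <- function(object, ...) {
  threshold <- attr(object, "threshold") %||% 0.05
  crit <- stats::qchisq(1 - threshold, df = 1)
  long <- tidy(object)
  long$label <- factor(long$label, levels = rev(object$label))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$statistic, y = .data$label,
                                     fill = .data$statistic < crit)) +
    ggplot2::geom_col(width = 0.7, colour = "grey30", show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = crit, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey30", `FALSE` = "white")) +
    ggplot2::facet_wrap(~assay) +
    ggplot2::labs(
      x = sprintf("Pearson χ² (df = 1; dashed line: critical value %.2f)",
                  crit),
      y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
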