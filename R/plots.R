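#' Volcano-style plot of a mediation screen
#'
#' ACME estimates against Monte-Carlo significance, coloured by mediation
#' sign, mirroring the usual presentation of cis-mediator screens.
#'
#' @param object A `mediation_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mediation_screen <- function(object, ...) {
  dat <- as_tibble(object) |>
    filter(!is.na(.data$acme)) |>
    mutate(direction = ifelse(.data$sign >= 0, "positive", "negative"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$acme,
                                    y = -log10(.data$acme_p),
                                    colour = .data$direction,
                                    shape = .data$mediated)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "average causal mediation effect (ACME)",
                  y = expression(-log[10](p)),
                  colour = "mediation sign", shape = "mediated") +
    ggplot2::theme_minimal()
}

#' Boxplot of the co-expression contrast between pair groups
#'
#' @param object A `coexpression_contrast`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coexpression_contrast <- function(object, ...) {
  ggplot2::ggplot(object$observations,
                  ggplot2::aes(x = .data$group, y = .data$abs_r,
                               fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "|Pearson r| of pair expression") +
    ggplot2::theme_minimal()
}

#' Boxplot of Hi-C contact frequencies: QTL pairs vs random bins
#'
#' @param object A `hic_enrichment` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hic_enrichment <- function(object, ...) {
  ggplot2::ggplot(object$observations,
                  ggplot2::aes(x = .data$group, y = .data$freq,
                               fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3, show.legend = FALSE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "normalized contact frequency (non-zero)") +
    ggplot2::theme_minimal()
}

#' Hotspot target counts against their co-regulation significance
#'
#' @param hotspots Output of [coregulation_test()].
#' @return A ggplot object.
#' @export
plot_hotspots <- function(hotspots) {
  ggplot2::ggplot(hotspots,
                  ggplot2::aes(x = .data$n_targets,
                               y = -log10(.data$empirical_p))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "trans target genes per hotspot",
                  y = expression(-log[10](empirical~p))) +
    ggplot2::theme_minimal()
}
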