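# ggplot2 displays for the package's tabular results.

#' Plot a lineage-by-sample expression table
#'
#' Tile heatmap of rpm (log10 + 1 scale) with lineages as rows and samples as
#' columns — the at-a-glance view of diel/drought induction patterns.
#'
#' @param object An `expression_table` from
#'   [aggregate_lineage_abundance()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.expression_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$sample, y = .data$lineage,
                               fill = log10(.data$rpm + 1))) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$rpm)), size = 3) +
    ggplot2::scale_fill_viridis_c(name = "log10(rpm + 1)") +
    ggplot2::labs(x = "sample", y = "gene lineage") +
    ggplot2::theme_minimal()
}

#' Plot an AIC hypothesis ranking
#'
#' Dot plot of delta-AIC for each fitted model/foreground hypothesis, best at
#' the top; the dashed line marks the decisiveness threshold.
#'
#' @param ranked Tibble from [rank_hypotheses()].
#' @param decisive_delta Threshold drawn as a reference line (default 10).
#' @return A ggplot.
#' @export
plot_aic_ranking <- function(ranked, decisive_delta = 10) {
  d <- ranked
  d$label <- paste0(d$model, ifelse(d$foreground %in% c("-", NA), "",
                                    paste0(" (", d$foreground, ")")))
  d$label <- factor(d$label, levels = rev(d$label))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta_AIC, y = .data$label)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_vline(xintercept = decisive_delta, linetype = "dashed") +
    ggplot2::labs(x = expression(Delta * AIC), y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
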