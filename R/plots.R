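#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot SOM cluster prototypes
#'
#' One panel per cluster showing the prototype's normalized expression
#' across the nine samples in canonical order, the standard way
#' co-expression cluster shapes are displayed for this design.
#'
#' @param object An `endo_som` fit.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot endo_som
#' @export
autoplot.endo_som <- function(object, ...) {
  proto <- som_prototypes(object)
  sizes <- dplyr::count(object$assignment, .data$cluster)
  proto <- dplyr::left_join(proto, sizes, by = "cluster")
  proto$panel <- sprintf("cluster %d (n=%d)", proto$cluster,
                         ifelse(is.na(proto$n), 0L, proto$n))
  ggplot2::ggplot(proto, ggplot2::aes(.data$sample, .data$value,
                                      group = .data$cluster)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey70") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::geom_point(size = 0.8, colour = "#2166ac") +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = NULL, y = "normalized expression (z of log10 FPKM)") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Bar plot of a Venn partition
#'
#' @param venn Tibble from [venn_partition()] or [venn_counts()].
#' @return A ggplot.
#' @export
plot_venn <- function(venn) {
  ggplot2::ggplot(venn, ggplot2::aes(.data$category, .data$n)) +
    ggplot2::geom_col(fill = "#4393c3") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d (%d%%)", .data$n,
                                                    .data$percent)),
                       vjust = -0.3, size = 3) +
    ggplot2::labs(x = NULL, y = "transcripts") +
    ggplot2::theme_minimal()
}

#' Histogram of lncRNA/neighbour-gene correlations
#'
#' @param pairs Tibble from [pair_correlation()].
#' @param pos_threshold,neg_threshold Call thresholds drawn as dashed
#'   lines.
#' @return A ggplot.
#' @export
plot_neighbour_correlation <- function(pairs, pos_threshold = 0.8,
                                       neg_threshold = -0.8) {
  ggplot2::ggplot(pairs[!is.na(pairs$r), ], ggplot2::aes(.data$r)) +
    ggplot2::geom_histogram(binwidth = 0.1, boundary = 0, fill = "#4393c3") +
    ggplot2::geom_vline(xintercept = c(neg_threshold, pos_threshold),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "Pearson r (lncRNA vs neighbouring coding gene)",
                  y = "pairs") +
    ggplot2::theme_minimal()
}

#' Funnel plot of the lncRNA filter audit
#'
#' @param audit Audit tibble from [run_lncrna_pipeline()].
#' @return A ggplot.
#' @export
plot_filter_audit <- function(audit) {
  d <- dplyr::mutate(audit, stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(d, ggplot2::aes(.data$stage, .data$n_out)) +
    ggplot2::geom_col(fill = "#b2182b") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("-%d", .data$n_removed)),
                       vjust = -0.3, size = 3) +
    ggplot2::labs(x = NULL, y = "transcripts surviving") +
    ggplot2::theme_minimal()
}
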