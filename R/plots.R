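# ggplot2 quick-look figures for the main result types.

#' Bar chart of region-class TES fractions
#'
#' @param fig1 The `fig1_fractions` tibble of a [run_full()] result (or
#'   any tibble with `region_class`, `fraction` and optionally `gene_set`).
#' @return A ggplot object.
#' @export
plot_region_fractions <- function(fig1) {
  fig1 <- fig1 %>%
    mutate(region_class = factor(.data$region_class,
                                 levels = c("PROMOTER", "EXON", "INTRON")))
  p <- ggplot2::ggplot(fig1, ggplot2::aes(x = .data$region_class,
                                          y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "fraction of nucleotides in TES") +
    ggplot2::theme_minimal()
  if ("gene_set" %in% names(fig1)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$gene_set))
  }
  p
}

#' Grouped bars of per-TE-class fractions
#'
#' @param fig34 The `fig34_classes` tibble of a [run_full()] result.
#' @return A ggplot object.
#' @export
plot_te_class_fractions <- function(fig34) {
  ggplot2::ggplot(fig34, ggplot2::aes(x = .data$region_class,
                                      y = .data$fraction,
                                      fill = .data$te_class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "fraction of nucleotides", fill = "TE class") +
    ggplot2::theme_minimal() +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene_set))
}

#' Positional TATA match-frequency profile
#'
#' @param profile A [tata_positional_profile()] tibble.
#' @return A ggplot object.
#' @export
plot_tata_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$offset, y = .data$frequency)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::annotate("rect", xmin = -35, xmax = -25, ymin = -Inf, ymax = Inf,
                      alpha = 0.1, fill = "steelblue") +
    ggplot2::labs(x = "offset relative to TSS (nt)",
                  y = "match-start frequency") +
    ggplot2::theme_minimal()
}

#' Histogram of per-gene TES fractions
#'
#' @param hist_tbl A [histogram_fractions()] tibble.
#' @return A ggplot object.
#' @export
plot_fraction_histogram <- function(hist_tbl) {
  hist_tbl <- hist_tbl %>%
    mutate(bin = sprintf("[%.0f%%,%.0f%%%s", 100 * .data$bin_lo,
                         100 * .data$bin_hi,
                         ifelse(.data$bin_hi >= 1, "]", ")")))
  ggplot2::ggplot(hist_tbl, ggplot2::aes(x = factor(.data$bin, levels = .data$bin),
                                         y = .data$share)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "TES fraction of mature transcript", y = "share of genes") +
    ggplot2::theme_minimal()
}

#' Quick-look panel for a full pipeline run
#'
#' @param object A `lincte_run`.
#' @param ... Unused.
#' @return A ggplot object (the region-fraction panel).
#' @export
autoplot.lincte_run <- function(object, ...) {
  plot_region_fractions(object$fig1_fractions)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
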