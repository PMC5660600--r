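# ggplot2 views of the main result types.

#' @export
autoplot.attenuation_table <- function(object, ...) {
  df <- filter(as_tibble(object), is.finite(.data$score))
  has_class <- "gmm_class" %in% names(df)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$r_cnv_mrna,
                                        y = .data$r_cnv_protein)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::labs(x = "Pearson r (CNV, mRNA)", y = "Pearson r (CNV, protein)")
  if (has_class) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$gmm_class),
                                 alpha = 0.6, size = 0.8) +
      ggplot2::scale_colour_manual(values = c(attenuated = "#c0392b",
                                              background = "grey40"),
                                   name = NULL)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.6, size = 0.8)
  }
  p + ggplot2::theme_minimal()
}

#' Scatter of CNV-mRNA vs CNV-protein correlations
#'
#' Entities below the diagonal are attenuated: dosage reaches the transcript
#' but not the protein.
#'
#' @param tab An `attenuation_table` (per gene or per sample).
#' @return A ggplot object.
#' @export
plot_attenuation <- function(tab) autoplot.attenuation_table(tab)

#' @export
autoplot.enrichment_table <- function(object, fdr_max = 0.05, ...) {
  df <- as_tibble(object) |>
    filter(.data$fdr < fdr_max) |>
    arrange(.data$es)
  if (!nrow(df)) abort(sprintf("no set with FDR < %g", fdr_max))
  df$set <- factor(df$set, levels = df$set)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$es, y = .data$set)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = "Enrichment score", y = NULL) +
    ggplot2::theme_minimal()
}

#' Barplot of significantly enriched gene sets
#'
#' @param tab An `enrichment_table` from [gsea()].
#' @param fdr_max FDR cut-off for display.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(tab, fdr_max = 0.05) {
  autoplot.enrichment_table(tab, fdr_max = fdr_max)
}

#' Per-split AROC distribution of a signature benchmark
#'
#' @param bench A `signature_benchmark` from [benchmark_signature()].
#' @return A ggplot object.
#' @export
plot_benchmark <- function(bench) {
  stopifnot(inherits(bench, "signature_benchmark"))
  ggplot2::ggplot(tidy(bench), ggplot2::aes(x = .data$aroc)) +
    ggplot2::geom_histogram(bins = 30, fill = "#2c7fb8", colour = "white") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "Held-out AROC", y = "Splits") +
    ggplot2::theme_minimal()
}
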