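#' @importFrom rlang .data
NULL

#' Trait means dot chart
#'
#' One dot per (genotype, study) cell, colored by study — the exploratory
#' chart for judging between-environment variability of a trait.
#' Presentation only: every asserted number lives in the TSV tables.
#' @param summary an `fp_trait_summary`.
#' @return a ggplot object.
#' @export
plot_trait_means <- function(summary) {
  df <- as.data.frame(summary)
  df$genotype_id <- factor(df$genotype_id, levels = c_sort(unique(df$genotype_id)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$genotype_id, y = .data$mean_value,
                                   colour = .data$study_id)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "genotype", y = sprintf("mean %s per unit",
                                              attr(summary, "variable_id") %||% "value"),
                  colour = "study") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Stability line chart
#'
#' One segment per genotype from its worst to its best environment on the
#' cumulative-PBTT axis; rising segments (better where warmer and longer
#' days) in green, falling in red.
#' @param lines a [stability_lines()] result.
#' @return a ggplot object.
#' @export
plot_stability <- function(lines) {
  df <- as.data.frame(lines)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$pbtt_low, y = .data$value_low,
                                       xend = .data$pbtt_high, yend = .data$value_high,
                                       colour = .data$direction), alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(rising = "forestgreen",
                                            falling = "firebrick",
                                            flat = "grey50")) +
    ggplot2::labs(x = "cumulative PBTT", y = "mean trait value per unit") +
    ggplot2::theme_minimal()
}
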