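#' Plot a ranked enrichment screen
#'
#' -log10 raw p-value by rank, with the Bonferroni-significant miRNAs
#' highlighted and the familywise threshold drawn at `alpha / m`.
#'
#' @param object A `mirna_screen` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mirna_screen <- function(object, ...) {
  m <- attr(object, "m_tested")
  alpha <- attr(object, "alpha")
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = -log10(.data$p_value),
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::geom_hline(yintercept = -log10(alpha / m), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#b2182b", `FALSE` = "grey55"),
      name = "Bonferroni hit") +
    ggplot2::labs(x = "Rank", y = expression(-log[10] ~ "raw p")) +
    ggplot2::theme_minimal()
}

#' Plot group-by-phase means of a delta-Ct response
#'
#' The classic interaction plot behind a disease x cycle-phase factorial
#' ANOVA: per-cell means with standard-error bars, one line per group.
#' Shown on the delta-Ct scale (lower = higher expression).
#'
#' @param dct Delta-Ct tibble carrying `group` and `cycle_phase` columns.
#' @param assay Which assay to plot (default: first one present).
#' @return A ggplot object.
#' @export
plot_cycle_phase <- function(dct, assay = NULL) {
  assay <- assay %||% dct$assay_id[1]
  d <- dct[dct$assay_id == assay & !is.na(dct$delta_ct), ]
  cell <- dplyr::summarise(
    dplyr::group_by(d, .data$group, .data$cycle_phase),
    mean = mean(.data$delta_ct),
    se = stats::sd(.data$delta_ct) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  ggplot2::ggplot(cell, ggplot2::aes(x = .data$cycle_phase, y = .data$mean,
                                     colour = .data$group,
                                     group = .data$group)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.15)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(0.15)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      width = 0.1, position = ggplot2::position_dodge(0.15)) +
    ggplot2::labs(title = assay, x = "Cycle phase",
                  y = expression(Delta * "Ct (cycles)")) +
    ggplot2::theme_minimal()
}
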