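# Figure-style plots for score tables.

#' Developmental scatter of a score against age (Figure-2 style)
#'
#' @param score_table A [score_cohort()] table.
#' @param score Score name (its `_global` column is plotted).
#' @param colour_by Grouping column for colour (default `group`).
#' @return A ggplot.
#' @export
plot_development <- function(score_table, score = "task", colour_by = "group") {
  col <- paste0(score, "_global")
  ggplot2::ggplot(score_table,
                  ggplot2::aes(.data$age, .data[[col]],
                               colour = .data[[colour_by]])) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE) +
    ggplot2::labs(x = "age (years)", y = paste(score, "score"), colour = NULL)
}

#' Normative group comparison panel (Figure-4 style)
#'
#' Deviation z-scores against age, one facet per score, with linear trends
#' per group.
#'
#' @param nm_table Output of [apply_normative()].
#' @param scores Scores to include.
#' @return A ggplot.
#' @export
plot_nm_comparison <- function(nm_table, scores = ALL_SCORES) {
  cols <- paste0(scores, "_global_nm")
  long <- tidyr::pivot_longer(nm_table[, c("age", "group", cols)],
                              dplyr::all_of(cols),
                              names_to = "score", values_to = "z")
  long$score <- sub("_global_nm$", "", long$score)
  ggplot2::ggplot(long, ggplot2::aes(.data$age, .data$z, colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE) +
    ggplot2::facet_wrap(~score, scales = "free_y") +
    ggplot2::labs(x = "age (years)", y = "normative deviation (z)", colour = NULL)
}
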