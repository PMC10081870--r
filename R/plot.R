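#' Plot a di-PWM
#'
#' Heatmap of the 16 dinucleotide scores per column, with the per-column
#' score standard deviation (the selectivity signal driving core selection)
#' overlaid as a top strip, and the selected core interval framed.
#'
#' @param object A [dipwm].
#' @param min_cols Core width passed to [select_core()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dipwm <- function(object, min_cols = 10, ...) {
  core <- select_core(object, min_cols = min_cols)
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$dinucleotide,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::annotate("rect", xmin = core$a - 0.5, xmax = core$b + 0.5,
                      ymin = 0.5, ymax = 16.5, fill = NA,
                      colour = "black", linewidth = 0.6) +
    ggplot2::labs(
      title = sprintf("di-PWM %s (m = %d)", object$name, object$m),
      subtitle = sprintf("core columns %d..%d, mean column sd %.3g",
                         core$a, core$b, core$avg_stddev),
      x = "motif column (position pair)", y = NULL, fill = "score"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-column selectivity
#'
#' Column score standard deviations with the selected core interval shaded;
#' the view used to judge whether a matrix has nonselective runs.
#'
#' @param x A [dipwm].
#' @param min_cols Core width passed to [select_core()].
#' @return A ggplot object.
#' @export
plot_selectivity <- function(x, min_cols = 10) {
  core <- select_core(x, min_cols = min_cols)
  df <- tibble(position = seq_len(x$m - 1L), sd = column_score_sd(x))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$sd)) +
    ggplot2::annotate("rect", xmin = core$a - 0.5, xmax = core$b + 0.5,
                      ymin = -Inf, ymax = Inf, fill = "grey85") +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "motif column", y = "score standard deviation",
                  title = sprintf("column selectivity of %s", x$name)) +
    ggplot2::theme_minimal()
}

#' Plot a score distribution
#'
#' Tail probability (P-value) as a function of score, on a log scale.
#'
#' @param object A [score_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dipwm_score_dist <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$pvalue > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$pvalue)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "score", y = "Pr(score >= s)",
                  title = "di-PWM score tail distribution") +
    ggplot2::theme_minimal()
}

#' Plot occurrences along sequences
#'
#' One lane per sequence; occurrence positions against their scores,
#' colored by strand.
#'
#' @param occs Occurrence tibble from [search_dipwm()].
#' @return A ggplot object.
#' @export
plot_occurrences <- function(occs) {
  stopifnot(is.data.frame(occs))
  ggplot2::ggplot(occs, ggplot2::aes(x = .data$start, y = .data$score,
                                     colour = .data$strand)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_wrap(~seq_id, ncol = 1) +
    ggplot2::labs(x = "position (forward strand, 1-based)", y = "score") +
    ggplot2::theme_minimal()
}
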