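#' Bar plot of qRT-PCR relative expression
#'
#' Bar height is the mean of per-replicate 2^-deltaCt values; whiskers
#' are one standard error of the mean — the layout of the study's
#' validation figures.
#'
#' @param rel [rel_expression()] tibble (one or more genes).
#' @return A ggplot object.
#' @export
plot_rel_expression <- function(rel) {
  ggplot2::ggplot(rel, ggplot2::aes(x = .data$sample, y = .data$mean_rel,
                                    fill = .data$gene)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_rel - .data$sem,
                   ymax = .data$mean_rel + .data$sem),
      position = ggplot2::position_dodge(0.9), width = 0.25) +
    ggplot2::labs(x = NULL, y = expression(2^{-Delta * C[t]}),
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Bar plot of the most frequent annotation terms
#'
#' @param freq [term_frequency()] tibble.
#' @return A ggplot object.
#' @export
plot_term_frequency <- function(freq) {
  freq$term <- stats::reorder(freq$term, freq$rel_freq)
  ggplot2::ggplot(freq, ggplot2::aes(x = .data$rel_freq, y = .data$term)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "relative frequency", y = NULL) +
    ggplot2::theme_minimal()
}

#' Fold-difference ranking plot for one comparison
#'
#' Non-exclusive genes ranked by fold difference, coloured by direction;
#' the dashed line marks the highly-differentially-expressed threshold.
#'
#' @param records [compare_expression()] tibble.
#' @param threshold Fold threshold to mark (default 20).
#' @return A ggplot object.
#' @export
plot_fold_ranking <- function(records, threshold = 20) {
  d <- records[!records$exclusive, ]
  d <- d[order(-d$fold_diff), ]
  d$rank <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$fold_diff,
                                  colour = .data$direction)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "rank", y = "fold difference",
                  colour = "direction") +
    ggplot2::theme_minimal()
}
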