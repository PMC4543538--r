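#' MA plot with the fitted normalization trend
#'
#' One panel per array, showing M against A with the LOWESS trend (if the
#' `fitted` column from [lowess_normalize()] is present).
#'
#' @param ma MA tibble from [compute_ratios()] or [lowess_normalize()].
#' @param max_arrays Cap on the number of panels.
#' @return A ggplot object.
#' @export
plot_ma <- function(ma, max_arrays = 12) {
  check_columns(ma, c("M", "A", "replicate", "time_min"), "ma")
  ma <- dplyr::mutate(ma,
                      array = paste0(.data$replicate, " @", .data$time_min,
                                     "min"))
  keep <- utils::head(unique(ma$array), max_arrays)
  ma <- ma[ma$array %in% keep, ]
  p <- ggplot2::ggplot(ma, ggplot2::aes(x = .data$A, y = .data$M)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::facet_wrap(~array) +
    ggplot2::labs(x = "A (mean log2 intensity)", y = "M (log2 ratio)")
  if ("fitted" %in% names(ma)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$fitted),
                                colour = "red",
                                data = dplyr::arrange(ma, .data$A))
  }
  p
}

#' Plot inferred TF activity profiles with error bars
#'
#' Posterior mean trajectories with a +/- z sd ribbon, one facet per TF.
#'
#' @param object A `tf_activity_fit`.
#' @param z Ribbon half-width in posterior standard deviations.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tf_activity_fit <- function(object, z = 2, ...) {
  act <- object$activities
  ggplot2::ggplot(act, ggplot2::aes(x = .data$time_min, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - z * .data$sd,
                                      ymax = .data$mean + z * .data$sd),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::facet_wrap(~tf, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "inferred activity change")
}

#' Plot cross-condition comparison scores
#'
#' Bar chart of |r| scores per TF, with condition-specific (sentinel 2) and
#' unresponsive TFs shown in their own partitions.
#'
#' @param scores Tibble from [compare_conditions()] (optionally through
#'   [rank_tfs()]).
#' @param concordant_min,discordant_max Thresholds passed to [rank_tfs()]
#'   when `scores` lacks a `partition` column.
#' @return A ggplot object.
#' @export
plot_comparison <- function(scores, concordant_min = 0.8,
                            discordant_max = 0.3) {
  if (!"partition" %in% names(scores)) {
    scores <- rank_tfs(scores, concordant_min, discordant_max)
  }
  scores <- dplyr::mutate(scores, tf = factor(.data$tf, levels = rev(.data$tf)))
  ggplot2::ggplot(scores,
                  ggplot2::aes(x = .data$tf,
                               y = ifelse(is.na(.data$score), 0, .data$score),
                               fill = .data$partition)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = 3, colour = "grey40") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "comparison score (|r|; 2 = one condition only)",
                  fill = NULL)
}
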