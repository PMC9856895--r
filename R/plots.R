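# ggplot2 autoplot methods for the result objects.

#' Plot a RIP-seq target call
#'
#' Scatter of the two enrichment ratios (log10) for every detected gene,
#' with calibration thresholds as dashed lines and called targets
#' highlighted.
#'
#' @param object A `rip_targets` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rip_targets <- function(object, ...) {
  df <- dplyr::filter(object$table, .data$detected)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$ratio_ip_input, y = .data$ratio_ip_mock,
    colour = .data$passes
  )) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = object$thresholds$min_ratio_ip_input,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = object$thresholds$min_ratio_ip_mock,
                        linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "CPM ratio IP / Input", y = "CPM ratio IP / mock IP",
      colour = "called", title = "Control-calibrated RIP-seq target call"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a randomization distribution
#'
#' Histogram of the permutation statistics with the observed statistic
#' marked.
#'
#' @param object A `randomization_test` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.randomization_test <- function(object, ...) {
  df <- tibble(stat = object$perm_stats)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$statistic_observed,
                        colour = "red") +
    ggplot2::labs(
      x = sprintf("%s under label permutation", object$statistic),
      y = "permutations",
      title = sprintf("alpha_R = %.4g (%s, %d permutations%s)",
                      object$alpha_R, object$sides, object$n_permutations,
                      if (object$exhaustive) ", exhaustive" else "")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a CPE census as a motif map
#'
#' One horizontal track per sequence with a tick at each motif hit,
#' coloured by CPE class — the classic 3'UTR isoform diagram.
#'
#' @param object A `cpe_census` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cpe_census <- function(object, ...) {
  hits <- attr(object, "hits")
  ggplot2::ggplot(hits, ggplot2::aes(
    x = .data$start, y = .data$seq_id, colour = .data$cpe_class
  )) +
    ggplot2::geom_point(shape = "|", size = 6) +
    ggplot2::labs(x = "position (nt, 0-based)", y = NULL,
                  colour = "CPE class", title = "CPE motif map") +
    ggplot2::theme_minimal()
}

#' Plot per-replicate normalized levels
#'
#' @param object A `relative_level` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.relative_level <- function(object, ...) {
  ggplot2::ggplot(object$levels, ggplot2::aes(
    x = .data$genotype, y = .data$level
  )) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3,
                          linewidth = 0.3) +
    ggplot2::labs(
      y = "normalized level (chemi / total protein)", x = NULL,
      title = sprintf("ratio %s/%s = %.3g (p = %.3g)", object$mut,
                      object$wt, object$ratio_mut_over_wt, object$p_value)
    ) +
    ggplot2::theme_minimal()
}
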