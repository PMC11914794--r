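#' Plot screen calls per pool
#'
#' Dot plot of net SFC per 10^6 PBMC, one point per patient, faceted by
#' cytokine, with the positivity threshold as a dashed line — the standard
#' view of a pool-level ELISpot/Fluorospot screen.
#'
#' @param calls Screen calls from [call_screen()].
#' @param pool_labels Stimuli to show (defaults to all non-control calls).
#' @param threshold Positivity cutoff drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_screen <- function(calls, pool_labels = NULL, threshold = 100) {
  df <- filter(calls, !is.na(.data$positive))
  if (!is.null(pool_labels)) df <- filter(df, .data$stimulus %in% pool_labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stimulus, y = .data$net_sfc)) +
    ggplot2::geom_jitter(ggplot2::aes(color = .data$positive),
                         width = 0.15, height = 0, size = 2) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$cytokine)) +
    ggplot2::labs(x = NULL, y = expression("net SFC / 10"^6 * " PBMC"),
                  color = "positive") +
    ggplot2::theme_bw()
}

#' Plot a percentile-rank comparison
#'
#' Jittered per-candidate percentile ranks for positive vs negative
#' candidates with group medians, the Fig-6-style view of one
#' prioritization metric.
#'
#' @param object A `rank_comparison` from [compare_metric_ranks()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rank_comparison <- function(object, ...) {
  df <- bind_rows(
    tibble(group = "positive", pctile = object$positive),
    tibble(group = "negative", pctile = object$negative)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$pctile)) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.7) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.4, linewidth = 0.3) +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(
      x = NULL, y = sprintf("%s percentile rank", object$metric),
      subtitle = sprintf("Mann-Whitney two-sided p = %.3g%s", object$p_value,
                         if (object$significant) " *" else " (ns)")
    ) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
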