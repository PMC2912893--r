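#' Plot efficiency estimates against transformed-CI length
#'
#' Diagnostic scatter of the per-primer efficiency estimate (horizontal)
#' against the length of its transformed confidence interval (vertical, log
#' scale). Imprecise estimates stand out vertically regardless of their
#' efficiency value, which is the point of using CI length — not efficiency
#' itself — as the reliability criterion.
#'
#' @param object An `efficiency_estimates` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot efficiency_estimates
#' @export
autoplot.efficiency_estimates <- function(object, ...) {
  df <- filter(object, !is.na(.data$efficiency), !is.na(.data$ci_length))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$efficiency, y = .data$ci_length)) +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Estimated efficiency E",
                  y = "Transformed CI length (log scale)")
}

#' Plot the efficiency clusters
#'
#' Individually estimated efficiencies in increasing order, colored by
#' cluster, with each cluster's pooled efficiency drawn as a horizontal
#' segment.
#'
#' @param object An `efficiency_clusters` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot efficiency_clusters
#' @export
autoplot.efficiency_clusters <- function(object, ...) {
  df <- object$assignment |>
    mutate(efficiency = efficiency_from_slope(pmin(.data$beta1, -1e-12)),
           index = row_number(),
           group = factor(.data$group))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$efficiency,
                                   colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$group_efficiency), linewidth = 0.4) +
    ggplot2::labs(x = "Primer (sorted by individual slope)",
                  y = "Efficiency", colour = "Cluster")
}

#' Plot sorted CoV curves per correction scheme
#'
#' One descending curve of per-primer AFC coefficients of variation per
#' efficiency-correction scheme; uniformly lower curves indicate more
#' accurate assumed efficiencies.
#'
#' @param object A `cov_comparison` tibble from [compare_schemes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cov_comparison
#' @export
autoplot.cov_comparison <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rank, y = .data$cov,
                                       colour = .data$scheme)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Primer rank (descending CoV)",
                  y = "Coefficient of variation of AFC",
                  colour = "Scheme")
}

#' Plot all dilution curves of a table
#'
#' CT against log2(dilution), one line per primer — useful before/after the
#' purge to see non-linear and sporadic curves disappear.
#'
#' @param table A [dilution_table()].
#' @param primers Optional subset of primer ids.
#' @return A ggplot object.
#' @export
plot_dilution_curves <- function(table, primers = NULL) {
  df <- filter(table, !is.na(.data$ct))
  if (!is.null(primers)) df <- filter(df, .data$primer %in% primers)
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$dilution), y = .data$ct,
                                   group = .data$primer)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "log2(dilution)", y = "CT (cycles)")
}
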