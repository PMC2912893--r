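#' Stage 1: missing-value screen
#'
#' Primers whose dilution curve retains fewer than `min_points` detectable
#' CT values cannot support a linear fit and are marked for removal (with 4
#' dilution levels this is the "2 or more missing values" rule).
#'
#' @param table A [dilution_table()].
#' @param min_points Minimum valid points (default 3).
#' @return A tibble `primer`, `n_valid`, `removed`.
#' @export
filter_missing <- function(table, min_points = 3) {
  table |>
    group_by(primer = factor(.data$primer, levels = primer_ids(table))) |>
    summarise(n_valid = sum(!is.na(.data$ct)), .groups = "drop") |>
    mutate(primer = as.character(.data$primer),
           removed = .data$n_valid < min_points)
}

#' Stage 2: slope-significance screen
#'
#' A usable standard curve must show a negative and statistically significant
#' dilution slope. Primers whose two-sided slope-test p-value exceeds `alpha`,
#' or whose fitted slope is non-negative, are marked for removal. Keeping
#' only negative significant slopes also guarantees `beta_upper < 0` for the
#' matched confidence level, so every surviving primer has a defined
#' transformed interval.
#'
#' @param fits A `primer_fits` tibble (rows with `NA` statistics are treated
#'   as removable: they carry no usable fit).
#' @param alpha Significance level (default 0.05).
#' @return A tibble `primer`, `p_value`, `beta1`, `removed`.
#' @export
filter_slope <- function(fits, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  fits |>
    mutate(removed = is.na(.data$beta1) | .data$beta1 >= 0 |
             is.na(.data$p_value) | .data$p_value > alpha) |>
    select("primer", "p_value", "beta1", "removed")
}

#' Stage 3: transformed-CI-length outlier screen (1.5 x IQR rule)
#'
#' The length of the transformed efficiency confidence interval measures the
#' precision of an efficiency estimate. Primers whose CI length exceeds the
#' upper Tukey fence `Q3 + multiplier * IQR` of the surviving lengths are
#' flagged as unreliable. Undefined intervals (slope interval reaching zero)
#' are treated as infinitely long and always flagged. With fewer than 4
#' primers the quartiles are too unstable: a warning is issued and nothing
#' is removed.
#'
#' @param estimates An `efficiency_estimates` tibble restricted to primers
#'   surviving the earlier stages.
#' @param multiplier Positive IQR multiplier (default 1.5).
#' @param quantile_type Quantile convention passed to [stats::quantile()]
#'   (default 7, linear interpolation between order statistics).
#' @return A tibble `primer`, `ci_length`, `removed`, with the fence in
#'   attribute `ci_upper_fence`.
#' @export
filter_ci_outliers <- function(estimates, multiplier = 1.5, quantile_type = 7) {
  stopifnot(is.numeric(multiplier), multiplier > 0)
  len <- ifelse(is.na(estimates$ci_length), Inf, estimates$ci_length)
  out <- tibble(primer = estimates$primer, ci_length = estimates$ci_length)
  if (nrow(estimates) < 4) {
    warn("Fewer than 4 primers at the CI-outlier stage; quartiles unstable, no removals.")
    out$removed <- FALSE
    attr(out, "ci_upper_fence") <- NA_real_
    return(out)
  }
  finite_len <- len[is.finite(len)]
  q <- quantile(finite_len, c(0.25, 0.75), type = quantile_type, names = FALSE)
  fence <- q[2] + multiplier * (q[2] - q[1])
  out$removed <- len > fence
  attr(out, "ci_upper_fence") <- fence
  out
}

#' Three-stage reliability purge
#'
#' Applies, in order: the missing-value screen, the slope-significance
#' screen, and the transformed-CI-length outlier screen. Each primer receives
#' the first applicable status — `REMOVED_MISSING`, `REMOVED_SLOPE`,
#' `REMOVED_CI_OUTLIER` — or `KEPT`.
#'
#' @param table A [dilution_table()].
#' @param alpha Slope-test significance level (default 0.05).
#' @param ci_level Confidence level for the transformed interval (default
#'   `1 - alpha`, which guarantees defined intervals for all slope-stage
#'   survivors).
#' @param iqr_multiplier IQR multiplier for the outlier fence (default 1.5).
#' @param quantile_type Quantile convention (default 7).
#' @param min_points Minimum valid points per fit (default 3).
#' @return A tibble of class `reliability_report`: `primer`, `status`
#'   (factor), `n_valid`, `beta1`, `p_value`, `efficiency`, `ci_length`.
#'   Attributes: `alpha`, `ci_level`, `iqr_multiplier`, `ci_upper_fence`.
#' @examples
#' sim <- simulate_qpcr_array(seed = 1)
#' rel <- assess_reliability(sim$table)
#' table(rel$status)
#' @export
assess_reliability <- function(table, alpha = 0.05, ci_level = 1 - alpha,
                               iqr_multiplier = 1.5, quantile_type = 7,
                               min_points = 3) {
  stopifnot(alpha > 0, alpha < 1, ci_level > 0, ci_level < 1)
  stage1 <- filter_missing(table, min_points = min_points)
  fits <- fit_primers(table, min_points = min_points)
  est <- estimate_efficiency(fits, level = ci_level)
  stage2 <- filter_slope(fits, alpha = alpha)

  status <- setNames(rep("KEPT", nrow(stage1)), stage1$primer)
  status[stage1$primer[stage1$removed]] <- "REMOVED_MISSING"
  s2 <- stage2$primer[stage2$removed]
  status[setdiff(s2, names(status)[status != "KEPT"])] <- "REMOVED_SLOPE"

  survivors <- names(status)[status == "KEPT"]
  stage3 <- filter_ci_outliers(
    est[est$primer %in% survivors, , drop = FALSE],
    multiplier = iqr_multiplier, quantile_type = quantile_type
  )
  status[stage3$primer[stage3$removed]] <- "REMOVED_CI_OUTLIER"

  out <- stage1 |>
    select("primer", "n_valid") |>
    left_join(select(est, "primer", "beta1", "p_value", "efficiency",
                     "ci_length"), by = "primer") |>
    mutate(status = factor(status[.data$primer],
                           levels = c("KEPT", "REMOVED_MISSING",
                                      "REMOVED_SLOPE", "REMOVED_CI_OUTLIER"))) |>
    select("primer", "status", "n_valid", "beta1", "p_value",
           "efficiency", "ci_length")
  attr(out, "alpha") <- alpha
  attr(out, "ci_level") <- ci_level
  attr(out, "iqr_multiplier") <- iqr_multiplier
  attr(out, "ci_upper_fence") <- attr(stage3, "ci_upper_fence")
  class(out) <- unique(c("reliability_report", class(out)))
  out
}

#' Primers kept by the purge
#'
#' @param report A `reliability_report` from [assess_reliability()].
#' @return Character vector of kept primer ids.
#' @export
kept_primers <- function(report) {
  report$primer[report$status == "KEPT"]
}

#' @export
print.reliability_report <- function(x, ...) {
  counts <- table(x$status)
  cat(sprintf(
    "<reliability_report: %d primers | kept %d, missing %d, slope %d, CI outlier %d; fence %.4g>\n",
    nrow(x), counts["KEPT"], counts["REMOVED_MISSING"], counts["REMOVED_SLOPE"],
    counts["REMOVED_CI_OUTLIER"], attr(x, "ci_upper_fence")))
  NextMethod()
}
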