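#' Fit the per-primer log-dilution regression
#'
#' For each primer, ordinary least squares of CT on log2(dilution) over the
#' non-missing points: `ct = beta0 + beta1 * log2(dilution) + eps`. Base-2
#' logs are used so that a unit slope (`beta1 = -1`) corresponds to perfect
#' per-cycle doubling (`E = 2`). Primers with fewer than `min_points` valid
#' points cannot support the fit (with 4 dilution levels this is the
#' "2 or more missing values" rule) and are returned with `NA` statistics.
#'
#' A primer whose CT values are identical across all valid dilutions carries
#' no linear trend; such a fit is reported with `beta1 = 0`, `p_value = 1`
#' and `r_squared = 0`.
#'
#' @param table A [dilution_table()].
#' @param min_points Minimum number of non-missing points for a fit
#'   (default 3, which keeps at least one residual degree of freedom).
#' @return A tibble of class `primer_fits`, one row per primer, with columns
#'   `primer`, `n` (valid points), `beta0`, `beta1` (cycles per log2-dilution
#'   unit), `se_beta1`, `t_stat`, `p_value` (two-sided, `n - 2` df),
#'   `r_squared`, `rss`, and a list-column `residuals` (per-point residuals
#'   in cycles, in decreasing-dilution order).
#' @examples
#' tab <- simulate_dilution_table(n_primers = 4, seed = 1)$table
#' fit_primers(tab)
#' @export
fit_primers <- function(table, min_points = 3) {
  stopifnot(min_points >= 3)
  fits <- table |>
    mutate(x = log2(.data$dilution)) |>
    group_by(primer = factor(.data$primer, levels = primer_ids(table))) |>
    summarise(fit = list(ols_summary(.data$x[!is.na(.data$ct)],
                                     .data$ct[!is.na(.data$ct)],
                                     min_points)),
              .groups = "drop") |>
    mutate(primer = as.character(.data$primer)) |>
    tidyr::unnest_wider("fit") |>
    mutate(residuals = purrr::map(.data$residuals,
                                  function(r) if (is.list(r)) r[[1]] else r))
  class(fits) <- unique(c("primer_fits", class(fits)))
  fits
}

#' Fit a single primer
#'
#' Scalar counterpart of [fit_primers()] for one primer id.
#'
#' @inheritParams fit_primers
#' @param primer_id A primer present in `table`.
#' @return A one-row `primer_fits` tibble; statistics are `NA` when fewer
#'   than `min_points` valid points are available (missing-value rule).
#' @export
fit_primer <- function(table, primer_id, min_points = 3) {
  if (!primer_id %in% table$primer) {
    abort(paste0("Unknown primer: ", primer_id), class = "qpcreff_key_error")
  }
  fit_primers(filter(table, .data$primer == primer_id), min_points = min_points)
}

# Closed-form least squares of y on x. Returns the full per-primer summary;
# all-NA when n < min_points. x values must be distinct (guaranteed for a
# validated dilution grid, asserted defensively).
ols_summary <- function(x, y, min_points) {
  n <- length(y)
  na <- list(n = n, beta0 = NA_real_, beta1 = NA_real_, se_beta1 = NA_real_,
             t_stat = NA_real_, p_value = NA_real_, r_squared = NA_real_,
             rss = NA_real_, residuals = list(numeric(0)))
  if (n < min_points) return(na)
  if (length(unique(x)) < 2) {
    abort("Degenerate design: all dilution levels identical among valid points.",
          class = "qpcreff_degenerate_error")
  }
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  sxy <- sum((x - xb) * (y - yb))
  syy <- sum((y - yb)^2)
  beta1 <- sxy / sxx
  beta0 <- yb - beta1 * xb
  res <- y - beta0 - beta1 * x
  rss <- sum(res^2)
  df <- n - 2
  sigma2 <- rss / df
  se <- sqrt(sigma2 / sxx)
  if (syy <= 0) {
    # flat response: no linear trend, by convention p = 1, R^2 = 0
    return(list(n = n, beta0 = beta0, beta1 = 0, se_beta1 = 0,
                t_stat = NA_real_, p_value = 1, r_squared = 0, rss = 0,
                residuals = list(res)))
  }
  t_stat <- if (se > 0) beta1 / se else sign(beta1) * Inf
  p <- if (se > 0) 2 * pt(-abs(t_stat), df) else 0
  list(n = n, beta0 = beta0, beta1 = beta1, se_beta1 = se,
       t_stat = t_stat, p_value = p, r_squared = 1 - rss / syy, rss = rss,
       residuals = list(res))
}

#' Confidence interval for the dilution slope
#'
#' `beta1 +/- t_{(1 - level)/2, n - 2} * se(beta1)`, the standard
#' normality-based interval with `n - 2` degrees of freedom (1 df for 3
#' dilution points, 2 df for 4). A perfect fit (`se = 0`) collapses to a
#' zero-length interval.
#'
#' @param fits A `primer_fits` tibble from [fit_primers()].
#' @param level Confidence level in (0, 1) (default 0.95).
#' @return `fits` with columns `beta_lower`, `beta_upper` added.
#' @export
slope_confidence_interval <- function(fits, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    abort("`level` must be a single probability in (0, 1).",
          class = "qpcreff_parameter_error")
  }
  tq <- suppressWarnings(qt(1 - (1 - level) / 2, df = fits$n - 2))
  mutate(fits,
         beta_lower = .data$beta1 - tq * .data$se_beta1,
         beta_upper = .data$beta1 + tq * .data$se_beta1)
}

#' Amplification efficiency from a dilution slope
#'
#' The slope of CT on log2(dilution) maps to the per-cycle amplification
#' factor through `E = 2^(-1/beta1)`, defined for `beta1 < 0` and strictly
#' increasing there; `beta1 = -1` gives perfect doubling, `E = 2`.
#'
#' @param beta1 Slope(s) in cycles per log2-dilution unit; must be `< 0`
#'   (`NA` values pass through).
#' @return Efficiency value(s), dimensionless, `> 0`.
#' @examples
#' efficiency_from_slope(-1) # 2
#' @export
efficiency_from_slope <- function(beta1) {
  if (any(beta1 >= 0, na.rm = TRUE)) {
    abort("Efficiency is defined only for negative slopes (beta1 < 0).",
          class = "qpcreff_domain_error")
  }
  2^(-1 / beta1)
}

#' Transform a slope interval to an efficiency interval
#'
#' Because the slope-to-efficiency map is strictly increasing on negative
#' slopes, a slope interval `(beta_lower, beta_upper)` with
#' `beta_upper < 0` maps to the efficiency interval
#' `(2^(-1/beta_lower), 2^(-1/beta_upper))`. When `beta_upper >= 0` the
#' interval crosses the singularity at zero and the transformed interval is
#' undefined (`NA`).
#'
#' @param beta_lower,beta_upper Slope interval endpoints
#'   (`beta_lower <= beta_upper`); vectorized.
#' @return A tibble with columns `e_lower`, `e_upper` (`NA` when undefined).
#' @export
transform_interval <- function(beta_lower, beta_upper) {
  stopifnot(all(beta_lower <= beta_upper, na.rm = TRUE))
  ok <- !is.na(beta_upper) & beta_upper < 0
  tibble(
    e_lower = ifelse(ok, 2^(-1 / beta_lower), NA_real_),
    e_upper = ifelse(ok, 2^(-1 / beta_upper), NA_real_)
  )
}

#' Efficiency estimates with transformed confidence intervals
#'
#' Combines the per-primer fits with the slope confidence interval and its
#' efficiency transformation. The transformed interval length
#' (`e_upper - e_lower`) quantifies the precision of the efficiency estimate
#' and drives the outlier stage of the reliability filter.
#'
#' @inheritParams slope_confidence_interval
#' @return A tibble of class `efficiency_estimates`: `primer`, `n`, `beta1`,
#'   `se_beta1`, `t_stat`, `p_value`, `r_squared`, `efficiency`,
#'   `beta_lower`, `beta_upper`, `e_lower`, `e_upper`, `ci_length`.
#'   `efficiency` is `NA` for non-negative slopes; `e_lower`/`e_upper`/
#'   `ci_length` are `NA` when the slope interval reaches zero.
#' @examples
#' tab <- simulate_dilution_table(n_primers = 6, seed = 2)$table
#' estimate_efficiency(fit_primers(tab))
#' @export
estimate_efficiency <- function(fits, level = 0.95) {
  out <- slope_confidence_interval(fits, level = level)
  ei <- transform_interval(out$beta_lower, out$beta_upper)
  out <- mutate(out,
    efficiency = ifelse(!is.na(.data$beta1) & .data$beta1 < 0,
                        2^(-1 / .data$beta1), NA_real_),
    e_lower = ei$e_lower,
    e_upper = ei$e_upper,
    ci_length = .data$e_upper - .data$e_lower
  )
  out <- select(out, -"residuals", -"beta0", -"rss")
  attr(out, "level") <- level
  class(out) <- unique(c("efficiency_estimates", class(out)))
  out
}
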