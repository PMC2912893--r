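#' Bartlett's test of equal residual variance across primers
#'
#' Tests whether the residual variability of the per-primer dilution fits is
#' homogeneous. Strong heterogeneity indicates that some aberrant efficiency
#' estimates stem from primer-specific reliability problems rather than
#' shared experimental error; run before and after the purge, the test shows
#' whether the purge restored homoscedasticity. Primers with zero residual
#' variance (exact fits) are excluded with a warning, as their log variance
#' is undefined.
#'
#' @param fits A `primer_fits` tibble; only rows with at least one residual
#'   degree of freedom (`n >= 3`) enter the test.
#' @return A one-row tibble: `statistic`, `p_value`, `df`, `n_groups`.
#' @export
bartlett_residuals <- function(fits) {
  res <- fits$residuals[!is.na(fits$beta1) & fits$n >= 3]
  keep <- vapply(res, function(r) var(r) > 0, logical(1))
  if (any(!keep)) {
    warn(sprintf("%d primer(s) with zero residual variance excluded from Bartlett's test.",
                 sum(!keep)))
  }
  res <- res[keep]
  if (length(res) < 2) {
    abort("Bartlett's test needs residuals from at least 2 primers.")
  }
  bt <- bartlett.test(res)
  tibble(statistic = unname(bt$statistic), p_value = bt$p.value,
         df = unname(bt$parameter), n_groups = length(res))
}

#' Shapiro-Wilk normality test of pooled residuals
#'
#' Tests whether the residuals of all fitted dilution curves, pooled, are
#' consistent with a single normal distribution — a prerequisite for the
#' ANOVA-based slope comparisons. Requires at least 3 pooled residuals;
#' otherwise a warning is issued and `NA`s returned.
#'
#' @inheritParams bartlett_residuals
#' @return A one-row tibble: `statistic`, `p_value`, `n_residuals`.
#' @export
shapiro_residuals <- function(fits) {
  pooled <- unlist(fits$residuals[!is.na(fits$beta1)])
  if (length(pooled) < 3) {
    warn("Fewer than 3 pooled residuals; Shapiro-Wilk test skipped.")
    return(tibble(statistic = NA_real_, p_value = NA_real_,
                  n_residuals = length(pooled)))
  }
  sw <- shapiro.test(pooled)
  tibble(statistic = unname(sw$statistic), p_value = sw$p.value,
         n_residuals = length(pooled))
}

#' F-test for heterogeneity of dilution slopes
#'
#' Nested-model comparison over the kept primers: the restricted model fits
#' a separate intercept per primer but one common dilution slope; the full
#' model fits a separate slope per primer. The statistic
#' `F = ((RSS_r - RSS_f)/(P - 1)) / (RSS_f/(N - 2P))` with `P` primers and
#' `N` valid points is referred to an F distribution with `(P - 1, N - 2P)`
#' degrees of freedom. A significant result shows that slope (hence
#' efficiency) differences are not attributable to residual error alone.
#'
#' @param table A [dilution_table()].
#' @param kept Character vector of primer ids to include (default: all
#'   primers with >= 3 valid points).
#' @return A one-row tibble: `statistic`, `p_value`, `df1`, `df2`,
#'   `rss_restricted`, `rss_full`.
#' @export
slope_heterogeneity_test <- function(table, kept = NULL) {
  mom <- primer_moments(table, kept)
  P <- nrow(mom)
  if (P < 2) abort("Need at least 2 primers with >= 3 valid points.")
  N <- sum(mom$n)
  df2 <- N - 2 * P
  if (df2 <= 0) {
    abort("Insufficient residual degrees of freedom (N - 2P <= 0).",
          class = "qpcreff_df_error")
  }
  rss_full <- sum(mom$rss)
  rss_restricted <- pooled_slope_rss(mom)$rss
  f <- ((rss_restricted - rss_full) / (P - 1)) / (rss_full / df2)
  tibble(statistic = f, p_value = pf(f, P - 1, df2, lower.tail = FALSE),
         df1 = P - 1, df2 = df2,
         rss_restricted = rss_restricted, rss_full = rss_full)
}

#' Residual diagnostics for the pooling decision
#'
#' Convenience wrapper running Bartlett's test before and after the purge,
#' the Shapiro-Wilk test on the purged residuals, and the slope-heterogeneity
#' F-test on the kept primers.
#'
#' @param table A [dilution_table()].
#' @param report A `reliability_report` from [assess_reliability()].
#' @return A named list of one-row tibbles:
#'   `bartlett_pre`, `bartlett_post`, `shapiro`, `interaction`.
#' @export
qpcr_diagnostics <- function(table, report) {
  kept <- kept_primers(report)
  fits_all <- fit_primers(table)
  fits_kept <- fits_all[fits_all$primer %in% kept, , drop = FALSE]
  list(
    bartlett_pre = bartlett_residuals(fits_all),
    bartlett_post = bartlett_residuals(fits_kept),
    shapiro = shapiro_residuals(fits_kept),
    interaction = slope_heterogeneity_test(table, kept)
  )
}
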