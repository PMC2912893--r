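#' Efficiency-adjusted CT values
#'
#' Rescales observed threshold cycles to the cycle count the reaction would
#' have needed at perfect doubling: `ct_star = ct * log2(E)`, so that
#' `2^ct_star = E^ct` is the true fold quantity. The accompanying fold
#' difference `2^(ct - ct_star) = 2^ct / E^ct` measures how far the naive
#' perfect-efficiency reading deviates from the corrected one: it is 1 at
#' `E = 2`, above 1 for sub-perfect efficiency and below 1 for `E > 2`.
#'
#' @param ct Observed CT value(s) in cycles, `> 0`.
#' @param efficiency Amplification efficiency per cycle, `> 1` (recycled
#'   against `ct`).
#' @return A tibble with columns `ct`, `efficiency`, `ct_star`,
#'   `fold_difference`.
#' @examples
#' adjust_ct(28.5, 1.8) # ct_star ~ 24.2
#' @export
adjust_ct <- function(ct, efficiency) {
  if (any(efficiency <= 1, na.rm = TRUE)) {
    abort("Efficiency must be > 1 for CT adjustment.",
          class = "qpcreff_domain_error")
  }
  if (any(ct <= 0, na.rm = TRUE)) {
    abort("CT values must be positive.", class = "qpcreff_domain_error")
  }
  ct_star <- ct * log2(efficiency)
  tibble(ct = ct, efficiency = efficiency, ct_star = ct_star,
         fold_difference = 2^(ct - ct_star))
}

#' Relative expression ratio between two reactions
#'
#' Initial target amount of reaction A relative to reaction B:
#' `E_B^ct_B / E_A^ct_A` (a higher CT means less starting template). With a
#' common efficiency `E` this reduces to `E^(ct_B - ct_A)`, and in general it
#' equals `2^(ct_star_B - ct_star_A)` in adjusted cycles.
#'
#' @param ct_a,ct_b Observed CT values in cycles.
#' @param e_a,e_b Amplification efficiencies, `> 1`.
#' @return Numeric ratio (amount of A : amount of B).
#' @examples
#' expression_ratio(24, 2, 28.5, 1.8) # ~ 1: no expression difference
#' @export
expression_ratio <- function(ct_a, e_a, ct_b, e_b) {
  a <- adjust_ct(ct_a, e_a)
  b <- adjust_ct(ct_b, e_b)
  2^(b$ct_star - a$ct_star)
}

#' Adjusted fold-change profile across a dilution series
#'
#' For replicate reactions of the same template at different known dilutions,
#' the adjusted fold change `AFC = E^ct * d` (the estimated fold quantity
#' rescaled by the relative concentration `d`) should be constant when the
#' assumed efficiency matches the true one; a misspecified `E` disperses the
#' AFC values. The dispersion is summarized by the coefficient of variation
#' (CoV): standard deviation of the AFC values divided by their mean.
#'
#' @param table A [dilution_table()].
#' @param primer_id A primer with at least 2 valid points.
#' @param efficiency Assumed amplification efficiency, `> 1`.
#' @param sd_type `"sample"` (n - 1 denominator, default) or
#'   `"population"` for the CoV's standard deviation.
#' @return A tibble `primer`, `dilution`, `ct`, `afc` with the CoV in
#'   attribute `cov` (also returned by [afc_cov()]).
#' @export
afc_profile <- function(table, primer_id, efficiency, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(efficiency) != 1 || efficiency <= 1) {
    abort("`efficiency` must be a single value > 1.", class = "qpcreff_domain_error")
  }
  rows <- filter(table, .data$primer == primer_id, !is.na(.data$ct))
  if (nrow(rows) < 2) {
    abort("AFC profile needs >= 2 valid dilution points.",
          class = "qpcreff_insufficient_data_error")
  }
  # computed on the log scale for numerical range, then exponentiated
  log2_afc <- rows$ct * log2(efficiency) + log2(rows$dilution)
  out <- tibble(primer = primer_id, dilution = rows$dilution, ct = rows$ct,
                afc = 2^log2_afc)
  s <- sd(out$afc)
  if (sd_type == "population") s <- s * sqrt((nrow(out) - 1) / nrow(out))
  attr(out, "cov") <- s / mean(out$afc)
  out
}

#' Coefficient of variation of the AFC profile
#'
#' @inheritParams afc_profile
#' @return The CoV (sd/mean of the AFC values), a non-negative scalar; 0 iff
#'   all AFC values are equal.
#' @export
afc_cov <- function(table, primer_id, efficiency, sd_type = c("sample", "population")) {
  attr(afc_profile(table, primer_id, efficiency, sd_type = sd_type), "cov")
}

#' Compare efficiency-correction schemes by AFC dispersion
#'
#' For each primer and each correction scheme — `perfect` (assume `E = 2`
#' throughout), `global` (one array-wide mean of the individual estimates),
#' `cluster` (the primer's group efficiency), `individual` (its own
#' estimate) — computes the CoV of the AFC values across the dilution
#' series. Within each scheme primers are ranked by descending CoV, giving
#' directly plottable dispersion curves: a scheme whose assumed efficiencies
#' are closer to the truth yields a uniformly lower curve.
#'
#' @param table A [dilution_table()].
#' @param estimates An `efficiency_estimates` tibble (supplies the
#'   individual efficiencies and, via their mean over `kept`, the global
#'   scheme).
#' @param cluster_model An `efficiency_clusters` object over the same kept
#'   primers.
#' @param kept Character vector of primer ids to score (default: the
#'   cluster model's primers).
#' @param sd_type Passed to [afc_cov()].
#' @return A tibble of class `cov_comparison`: `scheme`, `rank`, `primer`,
#'   `efficiency`, `cov`, sorted by descending `cov` within scheme.
#' @export
compare_schemes <- function(table, estimates, cluster_model, kept = NULL,
                            sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  kept <- kept %||% cluster_model$assignment$primer
  ind <- setNames(estimates$efficiency, estimates$primer)[kept]
  if (anyNA(ind)) {
    abort("Individual efficiency missing for some kept primers.")
  }
  clu <- setNames(cluster_efficiencies(cluster_model)$efficiency,
                  cluster_efficiencies(cluster_model)$primer)[kept]
  schemes <- list(
    perfect = setNames(rep(2, length(kept)), kept),
    global = setNames(rep(mean(ind), length(kept)), kept),
    cluster = clu,
    individual = ind
  )
  out <- purrr::imap(schemes, function(eff, name) {
    tibble(
      scheme = name,
      primer = kept,
      efficiency = unname(eff),
      cov = vapply(kept, function(p) afc_cov(table, p, eff[[p]], sd_type = sd_type), 0)
    )
  }) |>
    bind_rows() |>
    group_by(.data$scheme) |>
    arrange(dplyr::desc(.data$cov), .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup() |>
    select("scheme", "rank", "primer", "efficiency", "cov") |>
    mutate(scheme = factor(.data$scheme,
                           levels = c("perfect", "global", "cluster", "individual")))
  class(out) <- unique(c("cov_comparison", class(out)))
  out
}

#' Efficiency-adjusted CT report for a table
#'
#' Applies [adjust_ct()] to every valid CT cell of the given primers using a
#' per-primer efficiency map.
#'
#' @param table A [dilution_table()].
#' @param efficiencies A data frame `primer`, `efficiency` (e.g. from
#'   [cluster_efficiencies()]) or a named numeric vector.
#' @param scheme Label recorded in the output's `scheme` column.
#' @return A tibble `primer`, `scheme`, `efficiency`, `dilution`, `ct`,
#'   `ct_star`, `fold_difference`.
#' @export
adjust_table <- function(table, efficiencies, scheme = "custom") {
  if (is.numeric(efficiencies) && !is.null(names(efficiencies))) {
    efficiencies <- tibble(primer = names(efficiencies),
                           efficiency = unname(efficiencies))
  }
  stopifnot(all(c("primer", "efficiency") %in% names(efficiencies)))
  rows <- table |>
    filter(!is.na(.data$ct), .data$primer %in% efficiencies$primer) |>
    left_join(select(efficiencies, "primer", "efficiency"), by = "primer")
  adj <- adjust_ct(rows$ct, rows$efficiency)
  tibble(primer = rows$primer, scheme = scheme, efficiency = rows$efficiency,
         dilution = rows$dilution, ct = rows$ct, ct_star = adj$ct_star,
         fold_difference = adj$fold_difference)
}
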