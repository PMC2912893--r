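# Per-primer sufficient statistics for grouped-slope fitting: within-primer
# centered sums over valid points of x = log2(dilution), y = ct.
primer_moments <- function(table, primers = NULL) {
  tab <- filter(table, !is.na(.data$ct))
  if (!is.null(primers)) {
    missing_p <- setdiff(primers, table$primer)
    if (length(missing_p) > 0) {
      abort(paste0("Unknown primer(s): ", paste(missing_p, collapse = ", ")),
            class = "qpcreff_key_error")
    }
    tab <- filter(tab, .data$primer %in% primers)
  }
  ord <- if (is.null(primers)) primer_ids(table) else primers
  mom <- tab |>
    mutate(x = log2(.data$dilution)) |>
    group_by(primer = factor(.data$primer, levels = ord)) |>
    summarise(
      n = dplyr::n(),
      ybar = mean(.data$ct),
      sxx = sum((.data$x - mean(.data$x))^2),
      sxy = sum((.data$x - mean(.data$x)) * (.data$ct - mean(.data$ct))),
      syy = sum((.data$ct - mean(.data$ct))^2),
      .groups = "drop"
    ) |>
    mutate(primer = as.character(.data$primer)) |>
    filter(.data$n >= 3)
  if (any(mom$sxx <= 0)) {
    abort("Degenerate design: a primer has no dilution-level spread.",
          class = "qpcreff_degenerate_error")
  }
  mom |>
    mutate(beta1 = .data$sxy / .data$sxx,
           rss = .data$syy - .data$sxy^2 / .data$sxx)
}

# One pooled slope across all rows of `mom`, intercepts per primer.
pooled_slope_rss <- function(mom) {
  gamma <- sum(mom$sxy) / sum(mom$sxx)
  list(gamma = gamma, rss = sum(mom$syy) - sum(mom$sxy)^2 / sum(mom$sxx))
}

#' Grouped-slope fit for one set of primers
#'
#' Least-squares fit of the model with a separate intercept per primer and a
#' single shared dilution slope over the member primers. The closed form
#' pools within-primer centered cross-products:
#' `gamma = sum(Sxy_i) / sum(Sxx_i)`, with residual sum of squares
#' `sum(Syy_i) - (sum Sxy_i)^2 / sum(Sxx_i)`.
#'
#' @param table A [dilution_table()].
#' @param members Character vector of member primer ids (each with >= 3
#'   valid points).
#' @return A list with `gamma` (pooled slope, cycles per log2-dilution
#'   unit), `efficiency` (`2^(-1/gamma)`, `NA` if `gamma >= 0`) and `rss`.
#' @export
group_fit_rss <- function(table, members) {
  if (length(members) == 0) abort("`members` must be non-empty.")
  mom <- primer_moments(table, members)
  if (nrow(mom) < length(unique(members))) {
    abort("All member primers need >= 3 valid points.")
  }
  fit <- pooled_slope_rss(mom)
  fit$efficiency <- if (fit$gamma < 0) 2^(-1 / fit$gamma) else NA_real_
  fit
}

# Segment-cost machinery: primers sorted by individual slope; prefix sums
# make each contiguous segment's grouped RSS an O(1) lookup.
segment_cost_fn <- function(mom) {
  cx <- cumsum(mom$sxx); cy <- cumsum(mom$syy); cz <- cumsum(mom$sxy)
  function(i, j) {
    sxx <- cx[j] - if (i > 1) cx[i - 1] else 0
    syy <- cy[j] - if (i > 1) cy[i - 1] else 0
    sxy <- cz[j] - if (i > 1) cz[i - 1] else 0
    max(syy - sxy^2 / sxx, 0)
  }
}

segment_gamma_fn <- function(mom) {
  cx <- cumsum(mom$sxx); cz <- cumsum(mom$sxy)
  function(i, j) {
    (cz[j] - if (i > 1) cz[i - 1] else 0) / (cx[j] - if (i > 1) cx[i - 1] else 0)
  }
}

#' Optimal k-group partition of primers by dilution slope
#'
#' Partitions the kept primers into `k` groups, each fitted with its own
#' pooled slope (and per-primer intercepts), minimizing the total residual
#' sum of squares — equivalently maximizing the grouped model's R^2. Because
#' groups differ only through a scalar slope, the search is restricted to
#' partitions contiguous in the order of the individual slope estimates,
#' over which an exact dynamic program finds the global optimum. Cost ties
#' (within relative tolerance 1e-9) are broken toward the partition with the
#' most balanced group sizes, then toward the lexicographically smallest
#' boundary set.
#'
#' @param table A [dilution_table()].
#' @param kept Character vector of primer ids to cluster (default: all
#'   primers with >= 3 valid points).
#' @param k Number of groups, `1 <= k <= length(kept)`.
#' @return An object of class `efficiency_clusters`: a list with `k`,
#'   `assignment` (tibble `primer`, `beta1`, `group`, `group_slope`,
#'   `group_efficiency`; groups numbered in increasing slope order),
#'   `groups` (tibble `group`, `slope`, `efficiency`, `size`), `rss`,
#'   `r_squared`, `N`, `P`.
#' @examples
#' sim <- simulate_dilution_table(n_primers = 8, efficiency = c(1.8, 2.0),
#'                                residual_sd = 0.02, seed = 3)
#' optimal_partition(sim$table, k = 2)
#' @export
optimal_partition <- function(table, kept = NULL, k) {
  mom <- primer_moments(table, kept)
  P <- nrow(mom)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > P) {
    abort(sprintf("`k` must be in 1..%d.", P), class = "qpcreff_parameter_error")
  }
  k <- as.integer(k)
  mom <- arrange(mom, .data$beta1, .data$primer)
  cost <- segment_cost_fn(mom)

  # DP over (last index j, number of groups g); tie-break on total squared
  # group size, then smaller boundary vector (via smaller split point).
  tol <- 1e-9
  D <- matrix(Inf, nrow = P, ncol = k)     # best cost
  B <- matrix(Inf, nrow = P, ncol = k)     # sum of squared sizes at best
  PRE <- matrix(NA_integer_, nrow = P, ncol = k)  # start index of last segment
  for (j in 1:P) {
    D[j, 1] <- cost(1, j); B[j, 1] <- j^2; PRE[j, 1] <- 1L
  }
  if (k > 1) {
    for (g in 2:k) {
      for (j in g:P) {
        for (i in g:j) { # last segment = i..j
          cand <- D[i - 1, g - 1] + cost(i, j)
          cand_b <- B[i - 1, g - 1] + (j - i + 1)^2
          better <- cand < D[j, g] - tol * (1 + abs(cand)) ||
            (abs(cand - D[j, g]) <= tol * (1 + abs(cand)) &&
               (cand_b < B[j, g] ||
                  (cand_b == B[j, g] && !is.na(PRE[j, g]) && i < PRE[j, g])))
          if (better) {
            D[j, g] <- cand; B[j, g] <- cand_b; PRE[j, g] <- i
          }
        }
      }
    }
  }
  # reconstruct segment starts
  starts <- integer(k); j <- P
  for (g in k:1) {
    starts[g] <- PRE[j, g]
    j <- starts[g] - 1L
  }
  ends <- c(starts[-1] - 1L, P)
  gamma_of <- segment_gamma_fn(mom)
  seg <- tibble(
    group = seq_len(k),
    start = starts, end = ends,
    slope = vapply(seq_len(k), function(g) gamma_of(starts[g], ends[g]), 0),
    rss = vapply(seq_len(k), function(g) cost(starts[g], ends[g]), 0),
    size = ends - starts + 1L
  )
  seg$efficiency <- ifelse(seg$slope < 0, 2^(-1 / seg$slope), NA_real_)
  assignment <- tibble(
    primer = mom$primer,
    beta1 = mom$beta1,
    group = rep(seg$group, seg$size),
    group_slope = rep(seg$slope, seg$size),
    group_efficiency = rep(seg$efficiency, seg$size)
  )
  rss <- sum(seg$rss)
  tss <- grand_tss(table, mom$primer)
  structure(list(
    k = k,
    assignment = assignment,
    groups = select(seg, "group", "slope", "efficiency", "size"),
    rss = rss,
    r_squared = 1 - rss / tss,
    N = sum(mom$n),
    P = P
  ), class = "efficiency_clusters")
}

# Total sum of squares of CT about the grand mean, over valid points of the
# given primers (the baseline for the grouped model's R^2).
grand_tss <- function(table, primers) {
  y <- table$ct[table$primer %in% primers & !is.na(table$ct)]
  sum((y - mean(y))^2)
}

#' Select the number of efficiency clusters by nested F-tests
#'
#' Starting from a single shared slope (`k = 1`), repeatedly fits the
#' optimal partitions with `k` and `k + 1` groups and tests whether the
#' extra group significantly reduces the residual sum of squares:
#' `F = (rss_k - rss_{k+1}) / (rss_{k+1} / df)` with
#' `df = N - (P + k + 1)` referred to `F(1, df)`. While `p < alpha`
#' the larger model is accepted; the first non-significant step stops the
#' search. A perfect fit (RSS below `epsilon`) and the `k_max` cap also
#' terminate. Note the F-test is applied to the RSS-optimal partition at
#' each step, so the nominal p-value ignores selection over partitions;
#' this mirrors the procedure's definition rather than endorsing its
#' calibration.
#'
#' @inheritParams optimal_partition
#' @param alpha Acceptance level for each step (default 0.05).
#' @param k_max Hard cap on the number of groups (default 15).
#' @param epsilon Perfect-fit guard: absolute RSS threshold; default
#'   `1e-12` times the total CT sum of squares about the grand mean.
#' @return An `efficiency_clusters` object for the selected `k`, with the
#'   step-by-step record in `$trace` (tibble `k`, `rss`, `rss_next`,
#'   `statistic`, `p_value`, `accepted`).
#' @examples
#' sim <- simulate_dilution_table(n_primers = 10, efficiency = c(1.8, 2.05),
#'                                residual_sd = 0.05, seed = 4)
#' mod <- select_clusters(sim$table)
#' mod$k
#' @export
select_clusters <- function(table, kept = NULL, alpha = 0.05, k_max = 15,
                            epsilon = NULL) {
  stopifnot(alpha > 0, alpha < 1, k_max >= 1)
  mom <- primer_moments(table, kept)
  P <- nrow(mom)
  if (P < 2) abort("Need at least 2 primers to cluster.")
  kept_ids <- mom$primer
  tss <- grand_tss(table, kept_ids)
  eps <- epsilon %||% (1e-12 * tss)
  N <- sum(mom$n)

  trace <- tibble(k = integer(), rss = double(), rss_next = double(),
                  statistic = double(), p_value = double(), accepted = logical())
  model <- optimal_partition(table, kept_ids, k = 1)
  repeat {
    k <- model$k
    if (model$rss <= eps || k >= min(P, k_max)) break
    df <- N - (P + k + 1)
    if (df <= 0) {
      warn("No residual degrees of freedom left; stopping cluster growth.")
      break
    }
    nxt <- optimal_partition(table, kept_ids, k = k + 1)
    f <- (model$rss - nxt$rss) / (nxt$rss / df)
    p <- pf(f, 1, df, lower.tail = FALSE)
    accepted <- is.na(p) || p < alpha   # rss_next == 0 gives F = Inf, p = 0
    trace <- bind_rows(trace, tibble(
      k = k, rss = model$rss, rss_next = nxt$rss,
      statistic = f, p_value = p, accepted = accepted
    ))
    if (!accepted) break
    model <- nxt
  }
  model$trace <- trace
  model$alpha <- alpha
  model
}

#' Per-primer cluster efficiencies
#'
#' Maps each primer to its group's efficiency `E_g = 2^(-1/gamma_g)`, the
#' efficiency implied by the group's fitted pooled slope.
#'
#' @param model An `efficiency_clusters` object.
#' @return A tibble `primer`, `efficiency`.
#' @export
cluster_efficiencies <- function(model) {
  select(model$assignment, "primer", efficiency = "group_efficiency")
}

#' @export
print.efficiency_clusters <- function(x, ...) {
  cat(sprintf("<efficiency_clusters: k = %d, P = %d primers, RSS = %.4g, R^2 = %.4f>\n",
              x$k, x$P, x$rss, x$r_squared))
  print(x$groups)
  invisible(x)
}

#' @rdname tidy
#' @param x An `efficiency_clusters` object.
#' @param ... Unused.
#' @method tidy efficiency_clusters
#' @export
tidy.efficiency_clusters <- function(x, ...) x$assignment

#' Broom-style tidiers for cluster models
#'
#' `tidy()` returns the per-primer assignment; `glance()` a one-row model
#' summary.
#'
#' @name tidy
NULL

#' @rdname tidy
#' @method glance efficiency_clusters
#' @export
glance.efficiency_clusters <- function(x, ...) {
  tibble(k = x$k, P = x$P, N = x$N, rss = x$rss, r_squared = x$r_squared)
}
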