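# Independent reference computations used to cross-check the package's
# implementations, plus small fixture builders.

# Closed-form simple least squares from raw sums (independent of both lm()
# and the package's fitting path in structure: no centering shortcuts).
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y); syy <- sum(y^2)
  beta1 <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  beta0 <- (sy - beta1 * sx) / n
  res <- y - beta0 - beta1 * x
  rss <- sum(res^2)
  se <- sqrt(rss / (n - 2) / (sxx - sx^2 / n))
  tstat <- beta1 / se
  list(beta0 = beta0, beta1 = beta1, se = se, t = tstat,
       p = 2 * stats::pt(-abs(tstat), n - 2),
       r2 = 1 - rss / (syy - sy^2 / n), rss = rss)
}

# Type-7 quantile by explicit linear interpolation between order statistics.
quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Textbook Bartlett statistic over groups of residuals.
bartlett_oracle <- function(groups) {
  k <- length(groups)
  ni <- vapply(groups, length, 0L)
  vi <- vapply(groups, stats::var, 0)
  N <- sum(ni)
  sp2 <- sum((ni - 1) * vi) / (N - k)
  stat <- ((N - k) * log(sp2) - sum((ni - 1) * log(vi))) /
    (1 + (sum(1 / (ni - 1)) - 1 / (N - k)) / (3 * (k - 1)))
  list(statistic = stat, p = stats::pchisq(stat, k - 1, lower.tail = FALSE))
}

# Exhaustive minimum grouped-slope RSS over all contiguous partitions of the
# slope-sorted primers into k segments.
brute_force_partition <- function(table, kept, k) {
  fits <- fit_primers(table)
  fits <- fits[fits$primer %in% kept & !is.na(fits$beta1), ]
  ord <- fits$primer[order(fits$beta1, fits$primer)]
  P <- length(ord)
  compositions <- function(P, k) {
    if (k == 1) return(list(P))
    out <- list()
    for (first in 1:(P - k + 1)) {
      for (rest in compositions(P - first, k - 1)) {
        out[[length(out) + 1]] <- c(first, rest)
      }
    }
    out
  }
  best <- Inf
  best_sizes <- NULL
  for (sizes in compositions(P, k)) {
    idx <- rep(seq_len(k), sizes)
    rss <- sum(vapply(seq_len(k),
                      function(g) group_fit_rss(table, ord[idx == g])$rss, 0))
    if (rss < best - 1e-12) {
      best <- rss
      best_sizes <- sizes
    }
  }
  list(rss = best, sizes = best_sizes, order = ord)
}

rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
    }
  }
  agree / choose(n, 2)
}

# Build a dilution table from a named list of per-primer CT vectors.
make_table <- function(ct_by_primer, levels = c(1, 0.1, 0.01, 0.001),
                       ct_cutoff = NULL) {
  stopifnot(all(lengths(ct_by_primer) == length(levels)))
  df <- tibble::tibble(
    primer = rep(names(ct_by_primer), each = length(levels)),
    dilution = rep(levels, length(ct_by_primer)),
    ct = unlist(ct_by_primer, use.names = FALSE)
  )
  dilution_table(df, ct_cutoff = ct_cutoff)
}

# A noise-free standard curve for a given efficiency and intercept.
perfect_curve <- function(efficiency, beta0 = 20, levels = c(1, 0.1, 0.01, 0.001)) {
  beta0 - log2(levels) / log2(efficiency)
}
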