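#' Simulate a serial-dilution CT table with known ground truth
#'
#' Generates per-primer standard curves under the linear model
#' `ct = beta0 + beta1 * log2(dilution) + eps`, with
#' `beta1 = -1/log2(E_true)` (the slope a reaction with per-cycle
#' amplification factor `E_true` produces) and Gaussian residuals. Three
#' kinds of defective primers can be planted: `missing` (all CT values above
#' the censoring cutoff, hence entirely `NA`), `flat` (zero dilution slope),
#' and `noisy` (residual standard deviation inflated by `noisy_factor`).
#' CT values above `ct_cutoff` are censored to `NA`, exactly as in real
#' data. The same seed reproduces the same table.
#'
#' With `calibrate_noise = TRUE` each clean/noisy primer's residual vector is
#' rescaled so its realized regression residual standard deviation equals the
#' nominal value exactly. This removes the (chi-distributed, 2 df) dispersion
#' of the realized noise scale, making transformed-CI lengths an essentially
#' deterministic function of the true efficiency — which guarantees that
#' noise-inflated primers are separable from clean ones by the 1.5xIQR fence
#' regardless of seed. Plain Gaussian draws (`FALSE`, the default) are the
#' right choice for coverage and calibration studies.
#'
#' @param n_primers Total number of primers (clean + planted defects).
#' @param dilution_levels Relative concentrations in (0, 1], strictly
#'   decreasing (default `c(1, 0.1, 0.01, 0.001)`).
#' @param efficiency True per-cycle efficiencies (> 1) for the clean
#'   primers; recycled across them in blocks, so a length-7 vector plants 7
#'   efficiency groups.
#' @param intercept_range Range (cycles) for the uniform draw of `beta0`,
#'   the undiluted-template CT.
#' @param residual_sd Residual standard deviation in cycles (default 0.08).
#' @param n_missing,n_flat,n_noisy Planted-defect counts (default 0); their
#'   sum must not exceed `n_primers`.
#' @param noisy_factor Residual-sd inflation for noisy primers (default 25).
#' @param ct_cutoff Censoring threshold in cycles (default 40).
#' @param calibrate_noise Fix the realized residual scale (see Details).
#' @param seed Optional integer seed (`set.seed` at entry).
#' @return A list of class `qpcr_simulation`: `table` (a
#'   [dilution_table()]) and `truth` (tibble `primer`, `kind`
#'   (clean/missing/flat/noisy), `group`, `true_efficiency`, `true_slope`,
#'   `true_intercept`).
#' @examples
#' sim <- simulate_dilution_table(n_primers = 12, efficiency = c(1.8, 2),
#'                                n_missing = 1, seed = 1)
#' table(sim$truth$kind)
#' @export
simulate_dilution_table <- function(n_primers = 96,
                                    dilution_levels = c(1, 0.1, 0.01, 0.001),
                                    efficiency = 1.9,
                                    intercept_range = c(16, 24),
                                    residual_sd = 0.08,
                                    n_missing = 0, n_flat = 0, n_noisy = 0,
                                    noisy_factor = 25,
                                    ct_cutoff = 40,
                                    calibrate_noise = FALSE,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_primers >= 1, length(dilution_levels) >= 2,
            all(dilution_levels > 0), all(dilution_levels <= 1),
            all(efficiency > 1), residual_sd >= 0, noisy_factor >= 1,
            n_missing >= 0, n_flat >= 0, n_noisy >= 0)
  n_defect <- n_missing + n_flat + n_noisy
  if (n_defect > n_primers) {
    abort("Planted defect counts exceed n_primers.",
          class = "qpcreff_parameter_error")
  }
  levels <- sort(dilution_levels, decreasing = TRUE)
  x <- log2(levels)
  n_lev <- length(levels)
  n_clean <- n_primers - n_defect

  ids <- sprintf("p%03d", seq_len(n_primers))
  kind <- sample(c(rep("clean", n_clean), rep("missing", n_missing),
                   rep("flat", n_flat), rep("noisy", n_noisy)))

  # clean primers get efficiencies in contiguous blocks of (roughly) equal
  # size, one block per supplied efficiency value
  block <- rep(seq_along(efficiency),
               diff(round(seq(0, n_clean, length.out = length(efficiency) + 1))))
  e_true <- rep(NA_real_, n_primers)
  group <- rep(NA_integer_, n_primers)
  e_true[kind == "clean"] <- efficiency[block]
  group[kind == "clean"] <- block
  # noisy primers follow a mid-range efficiency curve
  e_true[kind == "noisy"] <- efficiency[ceiling(length(efficiency) / 2)]

  beta0 <- runif(n_primers, intercept_range[1], intercept_range[2])
  beta1 <- ifelse(is.na(e_true), 0, -1 / log2(e_true))
  sd_i <- ifelse(kind == "noisy", residual_sd * noisy_factor, residual_sd)

  draw_residuals <- function(s) {
    eps <- rnorm(n_lev, 0, s)
    if (calibrate_noise && s > 0 && n_lev >= 3) {
      r <- stats::lm.fit(cbind(1, x), eps)$residuals
      s_hat <- sqrt(sum(r^2) / (n_lev - 2))
      if (s_hat > 0) eps <- eps * s / s_hat
    }
    eps
  }

  ct <- matrix(NA_real_, n_primers, n_lev)
  for (i in seq_len(n_primers)) {
    ct[i, ] <- switch(kind[i],
      clean = beta0[i] + beta1[i] * x + draw_residuals(sd_i[i]),
      noisy = beta0[i] + beta1[i] * x + draw_residuals(sd_i[i]),
      flat = beta0[i] + rnorm(n_lev, 0, sd_i[i]),
      missing = ct_cutoff + 1 + runif(n_lev, 0, 2)
    )
  }
  ct[ct <= 0] <- 0.01  # CT is a cycle count; clamp pathological draws

  tab <- tibble(
    primer = rep(ids, each = n_lev),
    dilution = rep(levels, n_primers),
    ct = as.vector(t(ct))
  )
  truth <- tibble(primer = ids, kind = kind, group = group,
                  true_efficiency = e_true,
                  true_slope = ifelse(kind %in% c("clean", "noisy"), beta1, 0),
                  true_intercept = beta0)
  structure(
    list(table = dilution_table(tab, ct_cutoff = ct_cutoff), truth = truth),
    class = "qpcr_simulation"
  )
}

#' Simulate a 96-primer low-density array scenario
#'
#' The package's reference synthetic dataset: 96 primers at dilutions
#' 1, 0.1, 0.01, 0.001 with 7 planted efficiency groups spanning
#' E = 1.72-2.14 (78 clean primers), residual sd 0.08 cycles, and planted
#' defects — 3 fully censored, 8 flat, 7 noise-inflated — so the purge's
#' expected outcome (96 -> remove 3, 8, 7 -> keep 78) is known by
#' construction. Noise calibration is on (see
#' [simulate_dilution_table()]), which guarantees the defect/clean
#' separation at the CI-outlier fence.
#'
#' @param seed Optional integer seed.
#' @param ... Overrides passed to [simulate_dilution_table()].
#' @return A `qpcr_simulation` list (`table`, `truth`).
#' @export
simulate_qpcr_array <- function(seed = NULL, ...) {
  args <- list(
    n_primers = 96,
    efficiency = c(1.72, 1.81, 1.86, 1.89, 1.94, 2.03, 2.14),
    residual_sd = 0.08,
    n_missing = 3, n_flat = 8, n_noisy = 7,
    calibrate_noise = TRUE,
    seed = seed
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(simulate_dilution_table, args)
}

#' @export
print.qpcr_simulation <- function(x, ...) {
  cat(sprintf("<qpcr_simulation: %d primers (%s)>\n",
              nrow(x$truth),
              paste(names(table(x$truth$kind)), table(x$truth$kind),
                    sep = "=", collapse = ", ")))
  invisible(x)
}
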