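#' Run the full efficiency-analysis workflow
#'
#' Executes the complete pipeline on a serial-dilution CT table: read and
#' censor, fit per-primer standard curves, estimate efficiencies with
#' transformed confidence intervals, purge unreliable primers (missing
#' values, insignificant slopes, CI-length outliers), run the residual
#' diagnostics, cluster the kept primers into efficiency groups, and produce
#' efficiency-adjusted CT values plus the AFC/CoV scheme comparison. When
#' `out_dir` is given, all result tables are written as CSV alongside a JSON
#' run summary.
#'
#' @param input A [dilution_table()], a data frame coercible to one, or a
#'   file path for [read_dilution_table()].
#' @param layout Passed to [read_dilution_table()] when `input` is a path.
#' @param ct_cutoff Censoring threshold in cycles (default 40).
#' @param alpha Slope-test significance level (default 0.05).
#' @param ci_level Confidence level for transformed intervals (default
#'   `1 - alpha`).
#' @param iqr_multiplier IQR multiplier for the CI-outlier fence (default 1.5).
#' @param cluster_alpha Acceptance level of the cluster-growth F-test
#'   (default 0.05).
#' @param k_max Cap on the number of clusters (default 15).
#' @param scheme Efficiency scheme for the adjusted-CT report: `"cluster"`
#'   (default), `"individual"`, `"global"` or `"perfect"`.
#' @param out_dir Optional output directory for the CSV reports and
#'   `summary.json`.
#' @return A list of class `qpcr_workflow`: `table`, `fits`, `estimates`,
#'   `reliability`, `diagnostics`, `clusters`, `adjusted`, `cov_comparison`,
#'   `summary` (the run-summary list), `parameters`.
#' @examples
#' sim <- simulate_qpcr_array(seed = 1)
#' wf <- run_qpcr_workflow(sim$table)
#' wf$summary$counts
#' @export
run_qpcr_workflow <- function(input, layout = "auto", ct_cutoff = 40,
                              alpha = 0.05, ci_level = 1 - alpha,
                              iqr_multiplier = 1.5, cluster_alpha = 0.05,
                              k_max = 15,
                              scheme = c("cluster", "individual", "global", "perfect"),
                              out_dir = NULL) {
  scheme <- match.arg(scheme)
  table <- if (is.character(input)) {
    read_dilution_table(input, layout = layout, ct_cutoff = ct_cutoff)
  } else {
    dilution_table(as_tibble(input), ct_cutoff = ct_cutoff)
  }

  fits <- fit_primers(table)
  estimates <- estimate_efficiency(fits, level = ci_level)
  reliability <- assess_reliability(table, alpha = alpha, ci_level = ci_level,
                                    iqr_multiplier = iqr_multiplier)
  kept <- kept_primers(reliability)
  if (length(kept) == 0) {
    abort("No primers survive the reliability purge.",
          class = "qpcreff_workflow_error")
  }
  diagnostics <- qpcr_diagnostics(table, reliability)
  clusters <- select_clusters(table, kept, alpha = cluster_alpha, k_max = k_max)
  cov_cmp <- compare_schemes(table, estimates, clusters, kept = kept)

  eff_map <- switch(scheme,
    cluster = cluster_efficiencies(clusters),
    individual = tibble(primer = kept,
                        efficiency = setNames(estimates$efficiency,
                                              estimates$primer)[kept]),
    global = tibble(primer = kept,
                    efficiency = mean(setNames(estimates$efficiency,
                                               estimates$primer)[kept])),
    perfect = tibble(primer = kept, efficiency = 2)
  )
  adjusted <- adjust_table(table, eff_map, scheme = scheme)

  counts <- as.list(table(reliability$status))
  summary <- list(
    schema_version = "1.0",
    parameters = list(ct_cutoff = ct_cutoff, alpha = alpha,
                      ci_level = ci_level, iqr_multiplier = iqr_multiplier,
                      cluster_alpha = cluster_alpha, k_max = k_max,
                      scheme = scheme),
    counts = list(
      total = nrow(reliability),
      removed_missing = counts$REMOVED_MISSING,
      removed_slope = counts$REMOVED_SLOPE,
      removed_ci_outlier = counts$REMOVED_CI_OUTLIER,
      kept = counts$KEPT
    ),
    ci_upper_fence = attr(reliability, "ci_upper_fence"),
    k_selected = clusters$k,
    groups = clusters$groups,
    diagnostics = list(
      bartlett_pre = as.list(diagnostics$bartlett_pre),
      bartlett_post = as.list(diagnostics$bartlett_post),
      shapiro = as.list(diagnostics$shapiro),
      interaction = as.list(diagnostics$interaction)
    )
  )

  out <- structure(list(
    table = table, fits = fits, estimates = estimates,
    reliability = reliability, diagnostics = diagnostics,
    clusters = clusters, adjusted = adjusted, cov_comparison = cov_cmp,
    summary = summary,
    parameters = summary$parameters
  ), class = "qpcr_workflow")

  if (!is.null(out_dir)) write_workflow(out, out_dir)
  out
}

#' Write all workflow reports to a directory
#'
#' @param workflow A `qpcr_workflow` object.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_workflow <- function(workflow, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_report(workflow$estimates, file.path(out_dir, "efficiency_report.csv"))
  rel <- workflow$reliability
  rel$ci_upper_fence <- attr(rel, "ci_upper_fence")
  write_report(rel, file.path(out_dir, "purge_report.csv"))
  write_report(tidy(workflow$clusters), file.path(out_dir, "cluster_report.csv"))
  write_report(workflow$clusters$trace, file.path(out_dir, "trace_report.csv"))
  write_report(workflow$adjusted, file.path(out_dir, "adjusted_report.csv"))
  write_report(workflow$cov_comparison, file.path(out_dir, "cov_report.csv"))
  summary <- workflow$summary
  summary$groups <- as.data.frame(summary$groups)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.qpcr_workflow <- function(x, ...) {
  cts <- x$summary$counts
  cat(sprintf(
    paste0("<qpcr_workflow: %d primers -> removed %d missing, %d slope, ",
           "%d CI outlier -> kept %d; k = %d clusters>\n"),
    cts$total, cts$removed_missing %||% 0, cts$removed_slope %||% 0,
    cts$removed_ci_outlier %||% 0, cts$kept %||% 0, x$summary$k_selected))
  invisible(x)
}

#' @rdname tidy
#' @method glance qpcr_workflow
#' @export
glance.qpcr_workflow <- function(x, ...) {
  cts <- x$summary$counts
  tibble(
    total = cts$total,
    removed_missing = cts$removed_missing %||% 0L,
    removed_slope = cts$removed_slope %||% 0L,
    removed_ci_outlier = cts$removed_ci_outlier %||% 0L,
    kept = cts$kept %||% 0L,
    k = x$summary$k_selected,
    mean_efficiency = mean(x$estimates$efficiency[
      x$estimates$primer %in% kept_primers(x$reliability)]),
    bartlett_pre_p = x$diagnostics$bartlett_pre$p_value,
    bartlett_post_p = x$diagnostics$bartlett_post$p_value,
    shapiro_p = x$diagnostics$shapiro$p_value,
    interaction_p = x$diagnostics$interaction$p_value
  )
}
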