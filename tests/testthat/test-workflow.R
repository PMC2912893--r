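test_that("the end-to-end workflow reports stage counts matching the planted truth", {
  sim <- simulate_qpcr_array(seed = 71)
  out_dir <- withr::local_tempdir()
  wf <- run_qpcr_workflow(sim$table, out_dir = out_dir)

  expect_equal(wf$summary$counts$total, 96)
  expect_equal(wf$summary$counts$removed_missing, 3L)
  expect_equal(wf$summary$counts$kept, 78L)
  expect_equal(wf$summary$counts$removed_slope + wf$summary$counts$removed_ci_outlier,
               15L) # 8 flat + 7 noisy, split between the two stages
  expect_setequal(kept_primers(wf$reliability),
                  sim$truth$primer[sim$truth$kind == "clean"])

  files <- c("efficiency_report.csv", "purge_report.csv", "cluster_report.csv",
             "trace_report.csv", "adjusted_report.csv", "cov_report.csv",
             "summary.json")
  expect_true(all(file.exists(file.path(out_dir, files))))
  js <- jsonlite::read_json(file.path(out_dir, "summary.json"))
  expect_equal(js$counts$kept, 78)
  expect_equal(js$k_selected, wf$clusters$k)
  expect_true(is.numeric(js$diagnostics$interaction$p_value))

  g <- glance(wf)
  expect_equal(g$kept, 78L)
  expect_equal(g$mean_efficiency, 1.913, tolerance = 0.02)
})

test_that("reruns with the same input produce byte-identical reports", {
  sim <- simulate_qpcr_array(seed = 72, n_primers = 24, n_missing = 1,
                             n_flat = 2, n_noisy = 2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_qpcr_workflow(sim$table, out_dir = d1)
  run_qpcr_workflow(sim$table, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("a purge that removes everything aborts the workflow", {
  tab <- make_table(list(f1 = c(25, 25.1, 24.9, 25.0),
                         f2 = c(30, 30.1, 29.9, 30.0),
                         f3 = c(22, 21.9, 22.1, 22.0),
                         f4 = c(27, 27.05, 26.95, 27.0)))
  expect_error(suppressWarnings(run_qpcr_workflow(tab)),
               class = "qpcreff_workflow_error")
})

test_that("malformed input fails before any report is written", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.csv")
  writeLines(c("primer,dilution,ct", "a,1,20", "a,1,21", "a,0.1,23"), bad)
  out_dir <- file.path(dir, "out")
  expect_error(run_qpcr_workflow(bad, out_dir = out_dir),
               class = "qpcreff_format_error")
  expect_false(dir.exists(out_dir))
})

test_that("the command-line interface reproduces in-process results", {
  cli <- file.path(find.package("qpcreff"), "exec", "qpcreff")
  expect_true(file.exists(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  dir <- withr::local_tempdir()
  tab_csv <- file.path(dir, "table.csv")
  truth_csv <- file.path(dir, "truth.csv")

  out <- system2(rscript, c(cli, "simulate", "--n-primers", "16",
                            "--efficiencies", "1.8,2.0", "--n-missing", "1",
                            "--n-flat", "1", "--n-noisy", "1",
                            "--seed", "73", "--out", tab_csv,
                            "--truth", truth_csv),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(tab_csv))

  cli_dir <- file.path(dir, "cli_out")
  status <- system2(rscript, c(cli, "run", "--input", tab_csv,
                               "--out-dir", cli_dir),
                    stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(cli_dir, "summary.json")))

  # identical results from the library path on the same table
  lib_dir <- file.path(dir, "lib_out")
  run_qpcr_workflow(tab_csv, out_dir = lib_dir)
  for (f in list.files(cli_dir)) {
    expect_identical(readLines(file.path(cli_dir, f)),
                     readLines(file.path(lib_dir, f)), label = f)
  }

  # adjust subcommand applies a fixed efficiency table
  eff_csv <- file.path(dir, "eff.csv")
  adj_csv <- file.path(dir, "adj.csv")
  est <- estimate_efficiency(fit_primers(read_dilution_table(tab_csv)))
  write_report(est[!is.na(est$efficiency), c("primer", "efficiency")], eff_csv)
  system2(rscript, c(cli, "adjust", "--input", tab_csv,
                     "--efficiencies", eff_csv, "--out", adj_csv),
          stdout = TRUE, stderr = TRUE)
  got <- read_report(adj_csv)
  expect_equal(got$ct_star, got$ct * log2(got$efficiency), tolerance = 1e-9)

  # unknown subcommands exit non-zero
  bad <- suppressWarnings(
    system2(rscript, c(cli, "frobnicate"), stdout = NULL, stderr = NULL))
  expect_true(bad != 0)
})

test_that("plot builders return ggplot objects", {
  sim <- simulate_dilution_table(n_primers = 8, efficiency = c(1.8, 2.0),
                                 residual_sd = 0.05, seed = 74)
  est <- estimate_efficiency(fit_primers(sim$table))
  mod <- select_clusters(sim$table)
  cmp <- compare_schemes(sim$table, est, mod)
  expect_s3_class(autoplot(est), "ggplot")
  expect_s3_class(autoplot(mod), "ggplot")
  expect_s3_class(autoplot(cmp), "ggplot")
  expect_s3_class(plot_dilution_curves(sim$table), "ggplot")
})
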