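test_that("a perfect doubling curve fits a unit slope with R^2 = 1", {
  tab <- make_table(list(p = perfect_curve(2, beta0 = 20)))
  fit <- fit_primers(tab)
  expect_equal(fit$beta1, -1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$se_beta1, 0, tolerance = 1e-9)
  expect_equal(sum(fit$residuals[[1]]), 0, tolerance = 1e-9)
})

test_that("fits agree with the closed-form least-squares oracle", {
  x <- log2(c(1, 0.1, 0.01, 0.001))
  y <- c(20.1, 23.3, 26.7, 29.9)
  oracle <- ols_oracle(x, y)
  fit <- fit_primers(make_table(list(p = y)))
  expect_equal(fit$beta1, oracle$beta1, tolerance = 1e-9)
  expect_equal(fit$beta0, oracle$beta0, tolerance = 1e-9)
  expect_equal(fit$se_beta1, oracle$se, tolerance = 1e-9)
  expect_equal(fit$p_value, oracle$p, tolerance = 1e-9)
  expect_equal(fit$r_squared, oracle$r2, tolerance = 1e-9)
  expect_equal(fit$beta1, -0.98738, tolerance = 1e-4)

  # randomized tables, against lm() as an independent algorithm
  set.seed(42)
  for (i in 1:20) {
    n <- sample(3:6, 1)
    xs <- sort(runif(n, -10, 0))
    ys <- 20 - xs + rnorm(n, 0, 0.5)
    tab <- dilution_table(tibble::tibble(primer = "p", dilution = 2^xs, ct = ys))
    fit <- fit_primers(tab)
    ref <- stats::lm(ys ~ xs)
    expect_equal(fit$beta1, unname(stats::coef(ref)[2]), tolerance = 1e-9)
    expect_equal(fit$se_beta1, unname(sqrt(diag(stats::vcov(ref)))[2]),
                 tolerance = 1e-9)
  }
})

test_that("too many missing values yield no fit; unknown primers are errors", {
  fit <- fit_primers(make_table(list(p = c(24.0, 27.3, NA, NA))))
  expect_true(is.na(fit$beta1))
  expect_equal(fit$n, 2)
  fit3 <- fit_primers(make_table(list(p = c(24.0, 27.3, 30.1, NA))))
  expect_false(is.na(fit3$beta1)) # 3 valid points still fit
  expect_error(fit_primer(make_table(list(p = 1:4 * 3)), "nope"),
               class = "qpcreff_key_error")
})

test_that("slope confidence intervals use the t quantile with n - 2 df", {
  fits <- tibble::tibble(primer = "p", n = 4, beta1 = -1, se_beta1 = 0.05)
  ci <- slope_confidence_interval(fits, level = 0.95)
  expect_equal(ci$beta_lower, -1 - 4.302653 * 0.05, tolerance = 1e-6)
  expect_equal(ci$beta_upper, -1 + 4.302653 * 0.05, tolerance = 1e-6)

  # zero standard error collapses the interval
  ci0 <- slope_confidence_interval(
    tibble::tibble(primer = "p", n = 4, beta1 = -1, se_beta1 = 0))
  expect_equal(ci0$beta_lower, ci0$beta_upper)

  # symmetry about beta1 for arbitrary inputs
  set.seed(7)
  f <- tibble::tibble(primer = letters[1:10], n = sample(3:6, 10, TRUE),
                      beta1 = rnorm(10), se_beta1 = runif(10))
  ci <- slope_confidence_interval(f, 0.9)
  expect_equal(ci$beta_upper - f$beta1, f$beta1 - ci$beta_lower, tolerance = 1e-12)

  expect_error(slope_confidence_interval(fits, level = 1.2),
               class = "qpcreff_parameter_error")
})

test_that("the slope-to-efficiency map hits its anchors and is monotone", {
  expect_identical(efficiency_from_slope(-1), 2)
  expect_equal(efficiency_from_slope(-1.1792), 1.8, tolerance = 1e-3)
  # near-zero slopes blow up to astronomic efficiencies
  e <- efficiency_from_slope(-0.0192)
  expect_gt(e, 1e15)
  expect_lt(e, 1e16)
  expect_error(efficiency_from_slope(0.5), class = "qpcreff_domain_error")
  expect_error(efficiency_from_slope(0), class = "qpcreff_domain_error")

  set.seed(1)
  b <- sort(-runif(100, 0.01, 3))
  expect_true(all(diff(efficiency_from_slope(b)) > 0))
})

test_that("slope intervals transform to efficiency intervals only below zero", {
  expect_equal(transform_interval(-1, -1), tibble::tibble(e_lower = 2, e_upper = 2))
  ti <- transform_interval(-1.2, -0.8)
  expect_equal(ti$e_lower, 2^(1 / 1.2), tolerance = 1e-9)
  expect_equal(ti$e_upper, 2^(1 / 0.8), tolerance = 1e-9)
  expect_equal(round(c(ti$e_lower, ti$e_upper), 4), c(1.7818, 2.3784))
  expect_lt(ti$e_lower, ti$e_upper)

  expect_true(all(is.na(transform_interval(-0.5, 0.1))))
  expect_true(all(is.na(transform_interval(-0.5, 0))))
})

test_that("a 99% transformed interval contains the 95% interval", {
  tab <- simulate_dilution_table(n_primers = 20, efficiency = 1.9,
                                 residual_sd = 0.1, seed = 5)$table
  fits <- fit_primers(tab)
  e95 <- estimate_efficiency(fits, 0.95)
  e99 <- estimate_efficiency(fits, 0.99)
  expect_true(all(e99$e_lower <= e95$e_lower + 1e-12))
  expect_true(all(e99$e_upper >= e95$e_upper - 1e-12))
})

test_that("fitted efficiency converges to the true value as noise vanishes", {
  sim <- simulate_dilution_table(n_primers = 10, efficiency = c(1.8, 2.1),
                                 residual_sd = 1e-6, seed = 9)
  est <- estimate_efficiency(fit_primers(sim$table))
  truth <- sim$truth$true_efficiency[match(est$primer, sim$truth$primer)]
  expect_true(all(abs(est$efficiency - truth) < 1e-4))
})
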