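test_that("grouped-slope fits reduce to the individual fit for one member", {
  sim <- simulate_dilution_table(n_primers = 4, efficiency = 1.85,
                                 residual_sd = 0.2, seed = 31)
  fits <- fit_primers(sim$table)
  for (p in fits$primer) {
    g <- group_fit_rss(sim$table, p)
    expect_equal(g$gamma, fits$beta1[fits$primer == p], tolerance = 1e-12)
    expect_equal(g$rss, fits$rss[fits$primer == p], tolerance = 1e-12)
  }
})

test_that("a shared-slope pair fits exactly; unequal slopes cost extra RSS", {
  tab <- make_table(list(a = perfect_curve(2, 20), b = perfect_curve(2, 24)))
  g <- group_fit_rss(tab, c("a", "b"))
  expect_equal(g$gamma, -1, tolerance = 1e-12)
  expect_equal(g$rss, 0, tolerance = 1e-12)
  expect_equal(g$efficiency, 2, tolerance = 1e-12)

  tab2 <- make_table(list(a = perfect_curve(2, 20), b = perfect_curve(1.8, 20)))
  g2 <- group_fit_rss(tab2, c("a", "b"))
  ind <- sum(fit_primers(tab2)$rss)
  expect_gt(g2$rss, ind + 1e-6) # pooling truly different slopes costs RSS

  # general check against a dummy-coded least-squares fit
  sim <- simulate_dilution_table(n_primers = 6, efficiency = c(1.8, 2.1),
                                 residual_sd = 0.15, seed = 32)
  df <- sim$table[!is.na(sim$table$ct), ]
  df$x <- log2(df$dilution)
  ref <- stats::lm(ct ~ primer + x, data = df)
  g3 <- group_fit_rss(sim$table, primer_ids(sim$table))
  expect_equal(g3$gamma, unname(stats::coef(ref)["x"]), tolerance = 1e-9)
  expect_equal(g3$rss, sum(stats::resid(ref)^2), tolerance = 1e-9)
})

test_that("the k = 1 partition equals the common-slope model of the diagnostics", {
  sim <- simulate_dilution_table(n_primers = 7, efficiency = c(1.8, 2.0),
                                 residual_sd = 0.1, seed = 33)
  m1 <- optimal_partition(sim$table, k = 1)
  het <- slope_heterogeneity_test(sim$table)
  expect_equal(m1$rss, het$rss_restricted, tolerance = 1e-10)
})

test_that("well-separated slope groups are recovered at k = 2", {
  sim <- simulate_dilution_table(n_primers = 6,
                                 efficiency = c(2^(1 / 1.25), 2),
                                 residual_sd = 0.02, seed = 34)
  m <- optimal_partition(sim$table, k = 2)
  joined <- merge(m$assignment, sim$truth, by = "primer")
  expect_equal(length(unique(paste(joined$group.x, joined$group.y))), 2)
  expect_equal(sort(m$groups$size), c(3L, 3L))
})

test_that("the dynamic program equals brute-force enumeration", {
  set.seed(35)
  for (i in 1:5) {
    P <- sample(6:12, 1)
    sim <- simulate_dilution_table(n_primers = P,
                                   efficiency = runif(3, 1.7, 2.2),
                                   residual_sd = 0.15)
    for (k in 2:min(4, P)) {
      m <- optimal_partition(sim$table, k = k)
      bf <- brute_force_partition(sim$table, primer_ids(sim$table), k)
      expect_equal(m$rss, bf$rss, tolerance = 1e-9)
    }
  }
})

test_that("RSS decreases and R^2 increases with k; slopes stay ordered", {
  sim <- simulate_dilution_table(n_primers = 12, efficiency = c(1.75, 1.9, 2.1),
                                 residual_sd = 0.1, seed = 36)
  models <- lapply(1:6, function(k) optimal_partition(sim$table, k = k))
  rss <- vapply(models, function(m) m$rss, 0)
  r2 <- vapply(models, function(m) m$r_squared, 0)
  expect_true(all(diff(rss) <= 1e-10))
  expect_true(all(diff(r2) >= -1e-10))
  for (m in models) {
    expect_true(all(diff(m$groups$slope) > 0))
    expect_true(all(m$groups$size >= 1))
    # group efficiencies inherit the strict slope ordering
    expect_true(all(diff(m$groups$efficiency) > 0))
  }
  expect_error(optimal_partition(sim$table, k = 13),
               class = "qpcreff_parameter_error")
})

test_that("cluster selection is invariant to primer input order", {
  sim <- simulate_dilution_table(n_primers = 9, efficiency = c(1.8, 2.0),
                                 residual_sd = 0.05, seed = 37)
  tab <- sim$table
  set.seed(38)
  shuffled <- dilution_table(tab[sample(nrow(tab)), ])
  m1 <- select_clusters(tab)
  m2 <- select_clusters(shuffled)
  expect_equal(m1$k, m2$k)
  a1 <- dplyr::arrange(m1$assignment, primer)
  a2 <- dplyr::arrange(m2$assignment, primer)
  expect_equal(a1$group, a2$group)
  expect_equal(m1$rss, m2$rss, tolerance = 1e-12)
})

test_that("noise-free single-slope data stop at k = 1 via the perfect-fit guard", {
  sim <- simulate_dilution_table(n_primers = 6, efficiency = 2,
                                 residual_sd = 0, seed = 39)
  m <- select_clusters(sim$table)
  expect_equal(m$k, 1)
  expect_equal(nrow(m$trace), 0)
})

test_that("separated two-group data split correctly at the first accepted step", {
  set.seed(40)
  correct_first_split <- replicate(50, {
    sim <- simulate_dilution_table(n_primers = 8,
                                   efficiency = c(2^(1 / 1.25), 2),
                                   residual_sd = 0.05)
    m2 <- optimal_partition(sim$table, k = 2)
    joined <- merge(m2$assignment, sim$truth, by = "primer")
    sel <- select_clusters(sim$table)
    all(tapply(joined$group.y, joined$group.x,
               function(g) length(unique(g)) == 1)) && sel$k >= 2
  })
  expect_gt(mean(correct_first_split), 0.95)
})

test_that("cluster efficiencies come from the pooled group slope", {
  sim <- simulate_dilution_table(n_primers = 5, efficiency = c(1.8, 2.05),
                                 residual_sd = 0.05, seed = 41)
  m <- select_clusters(sim$table)
  ce <- cluster_efficiencies(m)
  expect_setequal(ce$primer, primer_ids(sim$table))
  for (g in m$groups$group) {
    members <- m$assignment$primer[m$assignment$group == g]
    pooled <- group_fit_rss(sim$table, members)
    expect_equal(unique(ce$efficiency[ce$primer %in% members]),
                 pooled$efficiency, tolerance = 1e-12)
    if (length(members) == 1) {
      ind <- estimate_efficiency(fit_primers(sim$table))
      expect_equal(pooled$efficiency,
                   ind$efficiency[ind$primer == members], tolerance = 1e-12)
    }
  }
  # tidiers expose the assignment and the fit summary
  expect_equal(nrow(tidy(m)), m$P)
  expect_equal(glance(m)$k, m$k)
})
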