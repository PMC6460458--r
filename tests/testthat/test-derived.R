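test_that("half-life and mean residence obey the first-order identities", {
  rates <- 10^seq(-4, 1, length.out = 21)
  expect_equal(half_life(rates), log(2) * mean_residence(rates),
               tolerance = 1e-12)
  expect_equal(half_life(log(2)), 1)
  expect_equal(half_life(log(2) / 9.5), 9.5)
  expect_equal(half_life(2) * 2, half_life(1))
  expect_equal(mean_residence(log(2) / 3.8), 3.8 / log(2))
  expect_error(half_life(0), "rate must be")
  expect_error(mean_residence(-1), "rate must be")
})

test_that("canonical parameters reproduce the headline biology", {
  p <- canonical_parameters()
  expect_equal(mean_residence(p$mu0) / 24, 5.5)   # skin residence, days
  pk <- peak_migration(p)
  expect_equal(pk$time, 26)
  expect_equal(pk$fold, 10, tolerance = 1e-12)
  s <- kinetic_summary(p)
  expect_equal(s$half_life_dln_alum, 9.5)
  expect_equal(s$half_life_dln_saline, 3.8)
  expect_equal(s$transit_time, 2.6)
})

test_that("the pulse peak matches a grid search and degrades gracefully", {
  p <- rate_parameters(mu0 = 0.004, alpha = 0.002, m = 1 / 30, tau = 2,
                       delta_alum = 0.1, delta_saline = 0.2)
  pk <- peak_migration(p)
  grid <- seq(0, 300, by = 0.01)
  r <- migration_rate(grid, p, "alum")
  expect_lt(abs(grid[which.max(r)] - pk$time), 0.011)
  expect_lt(abs(max(r) / p$mu0 - pk$fold), 1e-3 * pk$fold)
  p0 <- rate_parameters(mu0 = 0.004, alpha = 0, m = 0, tau = 2,
                        delta_alum = 0.1, delta_saline = 0.2)
  expect_identical(peak_migration(p0), list(time = NA_real_, fold = 1))
})

test_that("labelling time follows first-order influx replacement", {
  expect_equal(time_to_fraction_labeled(0.95, 1), log(20))
  expect_equal(time_to_fraction_labeled(0.5, 10), 10 * log(2))
  expect_lt(time_to_fraction_labeled(1e-9, 1), 1e-6)
  # agrees with numerical inversion of f(t) = 1 - exp(-t/T)
  for (f in c(0.25, 0.6, 0.95)) {
    t_num <- stats::uniroot(function(t) 1 - exp(-t / 7) - f, c(0, 500),
                            tol = 1e-12)$root
    expect_equal(time_to_fraction_labeled(f, 7), t_num, tolerance = 1e-9)
  }
  # strictly increasing in f, linear in T
  fs <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(time_to_fraction_labeled(fs, 3)) > 0))
  expect_equal(time_to_fraction_labeled(0.8, 12),
               12 * time_to_fraction_labeled(0.8, 1))
  expect_error(time_to_fraction_labeled(1, 1), "strictly between")
  expect_error(time_to_fraction_labeled(0.5, 0), "T must be")
})
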