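p <- canonical_parameters()

test_that("migration rate follows the basal + pulse law", {
  expect_equal(migration_rate(c(0, 10, 50, 200), p, "saline"),
               rep(p$mu0, 4))
  expect_equal(migration_rate(0, p, "alum"), p$mu0)
  # pulse peaks at 1/m at 10-fold the basal rate
  expect_equal(migration_rate(1 / p$m, p, "alum"), 10 * p$mu0,
               tolerance = 1e-12)
  grid <- seq(0, 200, by = 0.01)
  r <- migration_rate(grid, p, "alum")
  expect_lt(abs(grid[which.max(r)] - 1 / p$m), 0.011)
  expect_true(all(r >= p$mu0))
  expect_error(migration_rate(-1, p, "alum"), "t must be")
})

test_that("cumulative hazard matches quadrature and is additive", {
  expect_identical(cumulative_migration(5, 5, p, "alum"), 0)
  p0 <- rate_parameters(mu0 = p$mu0, alpha = 0, m = 0, tau = p$tau,
                        delta_alum = p$delta_alum,
                        delta_saline = p$delta_saline)
  expect_equal(cumulative_migration(3, 17, p0, "alum"), p$mu0 * 14)
  expect_equal(cumulative_migration(0, 48, p, "alum"),
               trapz_migration(0, 48, p, "alum"), tolerance = 1e-8)
  expect_equal(cumulative_migration(0, 20, p, "alum") +
                 cumulative_migration(20, 48, p, "alum"),
               cumulative_migration(0, 48, p, "alum"), tolerance = 1e-12)
  expect_error(cumulative_migration(10, 5, p, "alum"), "t2 must be")
})

test_that("skin pool decays as the exponential of the hazard", {
  expect_equal(skin_timecourse(12, 800, 12, p, "alum"), 800)
  # saline e-folding time is the mean residence 1/mu0
  expect_equal(skin_timecourse(12 + 1 / p$mu0, 800, 12, p, "saline"),
               800 / exp(1), tolerance = 1e-12)
  tt <- seq(12, 90, by = 0.5)
  sal <- skin_timecourse(tt, 800, 12, p, "saline")
  alu <- skin_timecourse(tt, 800, 12, p, "alum")
  expect_true(all(diff(sal) < 0) && all(diff(alu) < 0))
  expect_true(all(alu[-1] < sal[-1]))
  expect_error(skin_timecourse(5, 800, 12, p, "alum"), "t must be")
})

test_that("dLN solver agrees with the constant-rate closed form", {
  horizons <- 12 + c(5, 12, 24, 48, 72)
  got <- dln_timecourse(horizons, 1000, 12, p, "saline")
  want <- dln_constant_mu(horizons, 1000, 12, p$mu0, p$delta_saline, p$tau)
  expect_equal(got, want, tolerance = 1e-6)
  expect_identical(dln_timecourse(12 + p$tau, 1000, 12, p, "alum"), 0)
  expect_error(dln_timecourse(5, 1000, 12, p, "alum"), "t must be")
})

test_that("dLN solver agrees with a fine-grid Riemann oracle (pulsed rate)", {
  for (tt in c(24, 36, 48)) {
    got <- dln_timecourse(tt, 1000, 12, p, "alum")
    want <- riemann_dln(tt, 1000, 12, p, "alum", p$delta_alum, p$tau)
    expect_equal(got, want, tolerance = 1e-5)
  }
})

test_that("closed form handles the mu = delta degeneracy smoothly", {
  expect_identical(dln_constant_mu(12 + 2.6, 100, 12, 0.1, 0.1, 2.6), 0)
  expect_lt(dln_constant_mu(40, 100, 12, 0.05, 1e6, 2.6), 1e-4)
  lim <- dln_constant_mu(12 + 2.6 + 10, 100, 12, 0.1, 0.1, 2.6)
  expect_equal(lim, 100 * 0.1 * 10 * exp(-1), tolerance = 1e-12)
  near <- dln_constant_mu(12 + 2.6 + 10, 100, 12, 0.1, 0.1 + 1e-7, 2.6)
  expect_equal(lim, near, tolerance = 1e-5)
})

test_that("mass is conserved when there is no lymph-node loss", {
  eps <- 1e-12  # effectively lossless dLN
  pc <- rate_parameters(mu0 = p$mu0, alpha = p$alpha, m = p$m, tau = p$tau,
                        delta_alum = eps, delta_saline = eps)
  x0 <- 1000; tpc <- 12
  for (tt in c(13, 20, 36, 60)) {
    skin <- skin_timecourse(tt, x0, tpc, pc, "alum")
    dln <- dln_timecourse(tt, x0, tpc, pc, "alum")
    lo <- max(tpc, tt - pc$tau)
    transit <- stats::integrate(function(s)
      migration_rate(s, pc, "alum") * skin_timecourse(s, x0, tpc, pc, "alum"),
      lo, tt, rel.tol = 1e-11)$value
    expect_equal(skin + transit + dln, x0, tolerance = 1e-6)
  }
})

test_that("predictions vary continuously with every parameter", {
  base <- dln_timecourse(30, 1000, 12, p, "alum")
  for (nm in c("mu0", "alpha", "m", "tau", "delta_alum")) {
    q <- p
    q[[nm]] <- q[[nm]] * (1 + 1e-9)
    pert <- dln_timecourse(30, 1000, 12, q, "alum")
    expect_lt(abs(pert / base - 1), 1e-6)
  }
})

test_that("a zero pulse amplitude reduces alum to saline", {
  p0 <- rate_parameters(mu0 = p$mu0, alpha = 0, m = 0, tau = p$tau,
                        delta_alum = 0.1, delta_saline = 0.1)
  tt <- seq(12, 72, by = 4)
  expect_identical(dln_timecourse(tt, 500, 12, p0, "alum"),
                   dln_timecourse(tt, 500, 12, p0, "saline"))
  expect_identical(skin_timecourse(tt, 500, 12, p0, "alum"),
                   skin_timecourse(tt, 500, 12, p0, "saline"))
})

test_that("design predictions line up with the site time courses", {
  d1 <- pc_design("alum", 12, 12, sites = "skin")
  expect_equal(predict_observations(d1, p, 750)$expected, 750)
  d2 <- pc_design("alum", 12, 12 + p$tau / 2, sites = "dln")
  expect_equal(predict_observations(d2, p, 750)$expected, 0)
  d3 <- pc_design("alum", 12, c(24, 36, 48, 72))
  got <- predict_observations(d3, p, 1000)
  expect_equal(nrow(got), 8)
  dln_rows <- got[got$site == "dln", ]
  expect_equal(dln_rows$expected,
               dln_timecourse(c(24, 36, 48, 72), 1000, 12, p, "alum"))
})
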