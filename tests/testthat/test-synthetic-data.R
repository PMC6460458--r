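test_that("canonical parameters round-trip the published estimates", {
  p <- canonical_parameters()
  expect_equal(p$delta_alum, log(2) / 9.5)
  expect_equal(p$delta_saline, log(2) / 3.8)
  expect_equal(p$tau, 2.6)
  expect_equal(p$mu0, 1 / 132)
  expect_equal(p$alpha, 9 * (1 / 132) * (1 / 26) * exp(1))
  # pulse calibration: maximal alum rate is 10x basal (checked by grid search)
  grid <- seq(0, 200, by = 0.01)
  expect_equal(max(migration_rate(grid, p, "alum")) / p$mu0, 10,
               tolerance = 1e-6)
})

test_that("standard schedules cover the three photoswitch families", {
  des <- study_designs()
  expect_length(des, 18)
  expect_true(all(vapply(des, function(d)
    min(d$harvest_times) >= d$t_pc && d$n_replicates == 4 &&
      setequal(d$sites, c("skin", "dln")), TRUE)))
  ids <- vapply(des, `[[`, "", "id")
  expect_false(anyDuplicated(ids) > 0)
  fixed <- des[[which(ids == "alum_fixed_pc12")]]
  expect_equal(fixed$t_pc, 12)
  expect_equal(fixed$harvest_times, c(24, 36, 48, 72))
  sliding <- des[grepl("alum_sliding", ids)]
  expect_equal(vapply(sliding, `[[`, 0.0, "t_pc"), c(12, 24, 36, 60))
  expect_equal(unlist(lapply(sliding, `[[`, "harvest_times")),
               c(24, 36, 48, 72))
  expect_equal(sort(unique(vapply(des, `[[`, "", "condition"))),
               c("alum", "saline"))
})

test_that("recruitment inflates the photoconvertible pool under alum only", {
  cv <- recruitment_curve()
  expect_equal(recruitment_pool(0, cv, "alum"), cv$r0)
  expect_equal(recruitment_pool(0, cv, "saline"), cv$r0)
  expect_equal(recruitment_pool(37, cv, "saline"), cv$r0)
  # maximum at t_pc = 1/b, by calculus and by grid search
  grid <- seq(0, 120, by = 0.01)
  pool <- recruitment_pool(grid, cv, "alum")
  expect_lt(abs(grid[which.max(pool)] - 1 / cv$b), 0.011)
  expect_equal(max(pool), cv$r0 + cv$beta * exp(-1) / cv$b, tolerance = 1e-9)
  # default calibration: 3-fold rise peaking at 18 h
  expect_equal(recruitment_pool(18, cv, "alum"), 1500)
  expect_gt(recruitment_pool(6, cv, "alum"), recruitment_pool(6, cv, "saline"))
})

test_that("noiseless simulation reproduces model expectations exactly", {
  p <- canonical_parameters()
  des <- dense_designs()
  ds <- simulate_dataset(des, p, noise = noise_model(cv = 0), seed = 9)
  for (d in des) {
    exp_df <- predict_observations(d, p,
                                   recruitment_pool(d$t_pc, recruitment_curve(),
                                                    d$condition))
    sub <- ds[ds$design_id == d$id & ds$replicate == 1, ]
    key <- paste(sub$site, sub$t_harvest)
    expect_equal(sub$count,
                 exp_df$expected[match(key, paste(exp_df$site, exp_df$t_harvest))])
  }
})

test_that("simulation is a pure function of its seed", {
  a <- simulate_dataset(study_designs(), seed = 31)
  b <- simulate_dataset(study_designs(), seed = 31)
  expect_identical(a, b)
  c <- simulate_dataset(study_designs(), seed = 32)
  expect_false(identical(a$count, c$count))
  # generating truth is embedded and round-trips
  tr <- attr(a, "truth")
  expect_equal(tr$params, canonical_parameters())
  expect_equal(tr$seed, 31)
  expect_named(tr$x0, vapply(study_designs(), `[[`, "", "id"))
})

test_that("multiplicative noise is mean-one with the requested CV", {
  d <- pc_design("alum", 12, 24, n_replicates = 1000, sites = "dln")
  ds <- simulate_dataset(list(d), noise = noise_model(cv = 0.2), seed = 77)
  expected <- predict_observations(
    d, canonical_parameters(),
    recruitment_pool(12, recruitment_curve(), "alum"))$expected
  expect_lt(abs(mean(ds$count) / expected - 1), 0.02)
  cv_hat <- stats::sd(ds$count) / mean(ds$count)
  expect_lt(abs(cv_hat / 0.2 - 1), 0.10)
})
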