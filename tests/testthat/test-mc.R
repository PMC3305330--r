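# Small, fast Monte Carlo runs; the quantitative SPT comparison at
# production sizes lives in test-acceptance.R.

test_that("random sequential initialization is feasible, seeded, overlap-free", {
  m <- uniform_mixture(1, concentration = 0.01)
  cfg <- init_configuration(20, m, target_n = 50, seed = 11)
  expect_s3_class(cfg, "disk_configuration")
  expect_equal(nrow(cfg$centers), 50)
  # re-validating through the constructor asserts the no-overlap invariant
  expect_silent(disk_configuration(cfg$box_side, cfg$centers, cfg$radii))
  cfg2 <- init_configuration(20, m, target_n = 50, seed = 11)
  expect_identical(cfg$centers, cfg2$centers)
  cfg3 <- init_configuration(20, m, target_n = 50, seed = 12)
  expect_false(identical(cfg$centers, cfg3$centers))
  # phi = 0.9 infeasible for random insertion
  expect_error(init_configuration(10, m, target_n = 29, seed = 1),
               "packing fraction")
})

test_that("metropolis sampling preserves the no-overlap invariant", {
  m <- crowder_mixture(c(0.8, 1.4), c(2, 1), concentration = 0.01)
  cfg <- init_configuration(18, m, target_n = 30, seed = 3)
  run <- run_metropolis(cfg, mc_settings(n_sweeps = 60, n_equilibration = 30,
                                         seed = 5, sample_interval = 10))
  expect_gte(length(run$samples), 5)
  for (s in run$samples) {
    expect_silent(disk_configuration(s$box_side, s$centers, s$radii))
    expect_true(all(s$centers >= 0 & s$centers < s$box_side))
  }
  expect_gt(run$acceptance_rate, 0.1)
  # fixed seed => bit-reproducible trajectory
  run2 <- run_metropolis(cfg, mc_settings(n_sweeps = 60, n_equilibration = 30,
                                          seed = 5, sample_interval = 10))
  expect_identical(run$samples[[6]]$centers, run2$samples[[6]]$centers)
})

test_that("zero-radius disks behave as an ideal gas: every move accepted", {
  m <- uniform_mixture(1e-300, concentration = 0.01) # effectively points
  cfg <- init_configuration(10, m, target_n = 40, seed = 2)
  cfg$radii[] <- 0
  run <- run_metropolis(cfg, mc_settings(n_sweeps = 40, n_equilibration = 0,
                                         max_step = 0.5, seed = 9,
                                         sample_interval = 10))
  expect_equal(run$acceptance_rate, 1)
})

test_that("widom insertion: exact limits and error guards", {
  # empty box: insertion always succeeds
  empty <- disk_configuration(10, matrix(numeric(0), ncol = 2), numeric(0))
  w <- widom_insertion_probability(list(empty), 1, n_insertions = 50, seed = 1)
  expect_equal(w$p_hat, 1)
  expect_equal(w$mu_ex, 0)
  # minimum-image violation
  m <- uniform_mixture(1, concentration = 0.01)
  cfg <- init_configuration(12, m, target_n = 10, seed = 4)
  expect_error(widom_insertion_probability(list(cfg), 5.5),
               "minimum-image")
  # determinism
  wa <- widom_insertion_probability(list(cfg), 0.5, n_insertions = 200, seed = 8)
  wb <- widom_insertion_probability(list(cfg), 0.5, n_insertions = 200, seed = 8)
  expect_identical(wa$p_hat, wb$p_hat)
})

test_that("point-particle insertion recovers the free-area fraction 1 - phi", {
  m <- uniform_mixture(1, concentration = 0.2 / pi)
  L <- 25
  n <- round(0.2 * L^2 / pi)
  cfg <- init_configuration(L, m, target_n = n, seed = 21)
  phi <- pi * n / L^2
  run <- run_metropolis(cfg, mc_settings(n_sweeps = 300, n_equilibration = 150,
                                         seed = 22, sample_interval = 10))
  w <- widom_insertion_probability(run, 0, n_insertions = 1500, seed = 23)
  expect_lt(abs(w$p_hat - (1 - phi)), 3 * w$stderr + 1e-9)
})

test_that("pair structure builds up with density at contact", {
  # denser fluids have lower insertion probability than the ideal estimate
  L <- 20
  m <- uniform_mixture(1, concentration = 0.01)
  mus <- vapply(c(0.1, 0.3), function(phi) {
    n <- round(phi * L^2 / pi)
    cfg <- init_configuration(L, m, target_n = n, seed = 31)
    run <- run_metropolis(cfg, mc_settings(n_sweeps = 200,
                                           n_equilibration = 100,
                                           seed = 32, sample_interval = 10))
    widom_insertion_probability(run, 1, n_insertions = 1000, seed = 33)$mu_ex
  }, numeric(1))
  expect_gt(mus[2], 2 * mus[1]) # super-linear growth of mu_ex with phi
})

test_that("exact single-crowder free area matches the grid oracle", {
  expect_equal(exact_free_area_one_crowder(10, 2, 1), 64 - 9 * pi)
  expect_equal(exact_free_area_one_crowder(10, 0, 0), 100)
  expect_error(exact_free_area_one_crowder(10, 4, 1.2), "band")
  closed <- exact_free_area_one_crowder(10, 2, 1)
  coarse <- grid_free_area(10, 2, 1, n_grid = 300)
  fine <- grid_free_area(10, 2, 1, n_grid = 1500)
  expect_lt(abs(fine - closed) / closed, 1e-3)
  # Riemann-sum convergence: finer grid is closer
  expect_lt(abs(fine - closed), abs(coarse - closed))
})
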