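test_that("geometry deltas are the area/circumference differences", {
  ch <- mscl_channel()
  d <- geometry_deltas(ch)
  expect_equal(d$delta_area, pi * (3.5^2 - 2.4^2))
  expect_equal(d$delta_circumference, 2 * pi * 1.1)
  same <- channel_geometry(3, 3)
  expect_equal(unlist(geometry_deltas(same)), c(delta_area = 0,
                                                delta_circumference = 0))
  flipped <- channel_geometry(3.5, 2.4)
  expect_equal(geometry_deltas(flipped)$delta_area, -d$delta_area)
  expect_equal(geometry_deltas(flipped)$delta_circumference,
               -d$delta_circumference)
})

test_that("MscL worked example reproduces the reference gating energies", {
  ch <- mscl_channel()
  m <- mscl_mixture()
  ca_ig <- gating_energy_constant_area(ch, m, "ideal_gas")
  ca_spt <- gating_energy_constant_area(ch, m, "spt")
  ct_ig <- gating_energy_constant_tension(ch, m, model = "ideal_gas")
  ct_spt <- gating_energy_constant_tension(ch, m, model = "spt")
  expect_equal(round(ca_ig$crowding_energy, 1), 4.3)
  expect_equal(round(ca_spt$crowding_energy, 1), 15.2)
  expect_equal(round(ct_ig$crowding_energy, 1), 1.1)
  expect_equal(round(ct_spt$crowding_energy, 1), 2.2)
  expect_equal(round(gating_tension_shift(ca_ig), 2), 0.21)
  expect_equal(round(gating_tension_shift(ca_spt), 2), 0.74)
  expect_equal(round(gating_tension_shift(ct_ig), 2), 0.05)
  expect_equal(round(gating_tension_shift(ct_spt), 2), 0.11)
  # at phi = 0.5 the constant-tension SPT/IG ratio is exactly 2
  expect_equal(ct_spt$crowding_energy / ct_ig$crowding_energy, 2)
  # constant-area ratio sits between the line (x2) and surface (x4) factors
  ratio_ca <- ca_spt$crowding_energy / ca_ig$crowding_energy
  expect_gt(ratio_ca, 2)
  expect_lt(ratio_ca, 4)
})

test_that("gating energies vanish without crowders and flip sign on closing", {
  ch <- mscl_channel()
  empty <- uniform_mixture(1, concentration = 0)
  expect_equal(gating_energy_constant_area(ch, empty, "spt")$crowding_energy, 0)
  expect_equal(gating_energy_constant_tension(ch, empty,
                                              model = "spt")$crowding_energy, 0)
  m <- mscl_mixture()
  closing <- channel_geometry(3.5, 2.4)
  for (mod in c("ideal_gas", "spt")) {
    expect_equal(gating_energy_constant_area(closing, m, mod)$crowding_energy,
                 -gating_energy_constant_area(ch, m, mod)$crowding_energy)
  }
})

test_that("constant-tension crowding term uses only the line tension", {
  ch <- mscl_channel()
  m <- crowder_mixture(c(0.7, 1.6), c(2, 1), area_fraction = 0.4)
  d <- geometry_deltas(ch)
  for (mod in c("ideal_gas", "spt")) {
    res <- gating_energy_constant_tension(ch, m, applied_tension = 0.8,
                                          model = mod)
    tau <- crowding_tensions(m, mod)$line_tension
    expect_equal(res$crowding_energy, tau * d$delta_circumference)
    expect_equal(res$loading_energy, -0.8 * d$delta_area)
    expect_equal(res$total, tau * d$delta_circumference - 0.8 * d$delta_area)
  }
  # crowders of vanishing size at fixed c: line term goes to zero
  for (r in c(0.5, 0.1, 0.01)) {
    tiny <- uniform_mixture(r, concentration = 0.1)
    e <- gating_energy_constant_tension(ch, tiny, model = "spt")$crowding_energy
    expect_lt(e, 0.1 * 2 * pi * 1.1 * r / (1 - 0.1 * pi * r^2) + 1e-12)
  }
  e_seq <- vapply(c(0.5, 0.1, 0.01, 0.001), function(r) {
    gating_energy_constant_tension(ch, uniform_mixture(r, concentration = 0.1),
                                   model = "spt")$crowding_energy
  }, numeric(1))
  expect_true(all(diff(e_seq) < 0))
  expect_lt(e_seq[length(e_seq)], 1e-2)
})

test_that("SPT constant-area energy always exceeds the ideal-gas one", {
  ch <- mscl_channel()
  for (phi in c(0.1, 0.3, 0.5, 0.7)) {
    m <- uniform_mixture(1, area_fraction = phi)
    expect_gt(gating_energy_constant_area(ch, m, "spt")$crowding_energy,
              gating_energy_constant_area(ch, m, "ideal_gas")$crowding_energy)
  }
})

test_that("gating-tension shift is the crowding energy per unit area change", {
  ch <- mscl_channel()
  m <- mscl_mixture()
  res <- gating_energy_constant_area(ch, m, "spt")
  d <- geometry_deltas(ch)
  expect_equal(gating_tension_shift(res), res$crowding_energy / d$delta_area)
  degenerate <- gating_energy_constant_area(channel_geometry(2, 2), m, "spt")
  expect_error(gating_tension_shift(degenerate), "zero area change")
})

test_that("open probability is a sigmoid with the predicted midpoint", {
  ch <- mscl_channel()
  m <- mscl_mixture()
  s0 <- 1.0
  # no crowders: midpoint exactly at the bare gating tension
  expect_equal(open_probability(s0, s0, ch), 0.5)
  sig <- seq(0, 3, by = 0.01)
  p <- open_probability(sig, s0, ch, m, "spt")
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(diff(p) >= 0)) # saturates to 0/1 in the tails
  near <- seq(0.8, 1.5, by = 0.01) # strictly increasing across the transition
  expect_true(all(diff(open_probability(near, s0, ch, m, "spt")) > 0))
  expect_gt(open_probability(50, s0, ch, m, "spt"), 1 - 1e-10)
  # midpoint shift identity: sigma_mid - sigma*_0 == gating-tension shift
  for (mod in c("ideal_gas", "spt")) {
    res <- gating_energy_constant_tension(ch, m, model = mod)
    shift <- gating_tension_shift(res)
    expect_equal(open_probability(s0 + shift, s0, ch, m, mod), 0.5,
                 tolerance = 1e-14)
  }
})

test_that("three-step constant-tension route matches the closed form as O(1/A)", {
  ch <- mscl_channel()
  m <- mscl_mixture()
  r1 <- constant_tension_decomposition_check(ch, m, 0.5, reference_area = 1e4)
  r2 <- constant_tension_decomposition_check(ch, m, 0.5, reference_area = 1e6)
  r3 <- constant_tension_decomposition_check(ch, m, 0.5, reference_area = 1e8)
  expect_lt(abs(r2), 0.01)
  # O(1/A): each 100x area reduces the residual ~100x
  expect_equal(r1 / r2, 100, tolerance = 0.1)
  expect_equal(r2 / r3, 100, tolerance = 0.1)
  # without crowders only the loading terms remain and cancel exactly
  empty <- uniform_mixture(1, concentration = 0)
  expect_equal(constant_tension_decomposition_check(ch, empty, 0.7, 1e5), 0)
})
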