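test_that("molar absorptivity applies Beer-Lambert pointwise", {
  a <- spectrum(c(320, 330, 340), c(0.03, 0.05, 0.02), kind = "absorbance")
  eps <- molar_absorptivity(a, 5e-6, 1)
  expect_equal(eps$value[2], 1.0e4)
  # all-zero absorbance maps to all-zero epsilon
  z <- molar_absorptivity(spectrum(c(320, 330), c(0, 0), kind = "absorbance"),
                          5e-6)
  expect_equal(z$value, c(0, 0))
  # doubling the concentration halves epsilon everywhere
  half <- molar_absorptivity(a, 1e-5, 1)
  expect_equal(half$value, eps$value / 2)
  expect_error(molar_absorptivity(a, 0), "positive")
  expect_error(molar_absorptivity(spectrum(c(1, 2), c(1, 2)), 1e-5),
               "absorbance")
})

test_that("overlap integral matches the narrow-band closed form", {
  # emission concentrated at a single grid point of a uniform grid:
  # J reduces to eps(330) * lambda^4
  wl <- seq(300, 360, by = 1)
  fv <- ifelse(wl == 330, 1000, 0)
  donor <- spectrum(wl, fv, kind = "emission")
  eps <- spectrum(wl, rep(1.0e4, length(wl)), kind = "absorbance",
                  units = "L/mol/cm")
  J <- overlap_integral(donor, eps)
  expect_equal(J, 1.0e4 * (330e-7)^4, tolerance = 1e-12)
})

test_that("overlap integral is invariant to donor scaling and zero epsilon", {
  tr <- synthetic_truth(noise_sd_relative = 0)
  pair <- gen_spectra_pair(tr)
  eps <- molar_absorptivity(pair$absorbance, 5e-6)
  J <- overlap_integral(pair$emission, eps)
  scaled <- spectrum(pair$emission$wavelength_nm, 7.3 * pair$emission$value,
                     kind = "emission")
  expect_equal(overlap_integral(scaled, eps), J, tolerance = 1e-12)
  eps0 <- spectrum(eps$wavelength_nm, rep(0, length(eps$wavelength_nm)),
                   kind = "absorbance")
  expect_equal(overlap_integral(pair$emission, eps0), 0)
})

test_that("disjoint donor and acceptor ranges are rejected", {
  donor <- spectrum(c(300, 310, 320), c(1, 2, 1), kind = "emission")
  eps <- spectrum(c(400, 410), c(1e4, 1e4), kind = "absorbance")
  expect_error(overlap_integral(donor, eps), "no spectral overlap")
})

test_that("overlap integral agrees with a brute-force fine-grid oracle", {
  tr <- synthetic_truth(noise_sd_relative = 0)
  pair <- gen_spectra_pair(tr)
  eps <- molar_absorptivity(pair$absorbance, 5e-6)
  J <- overlap_integral(pair$emission, eps)
  J_oracle <- overlap_oracle(pair$emission, eps)
  expect_lt(abs(J - J_oracle) / J_oracle, 1e-3)
  # grid-spacing change alters J by < 0.1%
  pair2 <- gen_spectra_pair(tr, emission_grid_nm = seq(290, 460, by = 0.5),
                            absorbance_grid_nm = seq(250, 450, by = 1))
  eps2 <- molar_absorptivity(pair2$absorbance, 5e-6)
  expect_lt(abs(overlap_integral(pair2$emission, eps2) - J) / J, 1e-3)
})

test_that("the critical radius matches the reported chain values", {
  r0 <- forster_radius(1.26e-15)
  expect_equal(r0, 1.74, tolerance = 0.005 / 1.74)
  expect_equal(forster_radius(0), 0)
  # power law: quadrupling the quantum yield scales R0 by 4^(1/6)
  c4 <- fret_constants(quantum_yield = 4 * 0.118)
  expect_equal(forster_radius(1.26e-15, c4) / r0, 4^(1 / 6),
               tolerance = 1e-12)
  # monotone increasing in J
  js <- 10^seq(-17, -13, by = 0.5)
  expect_true(all(diff(vapply(js, forster_radius, numeric(1))) > 0))
})

test_that("transfer efficiency follows E = 1 - F/F0", {
  expect_equal(transfer_efficiency(100, 100), 0)
  expect_equal(transfer_efficiency(94.7, 100), 0.053)
  expect_equal(transfer_efficiency(1e-9, 100), 1, tolerance = 1e-10)
  expect_error(transfer_efficiency(101, 100), "negative")
  expect_error(transfer_efficiency(0, 100), "positive")
})

test_that("donor-acceptor distance matches the reported values and is monotone", {
  r0 <- forster_radius(1.26e-15)
  r <- donor_acceptor_distance(0.053, r0)
  expect_equal(r, 2.81, tolerance = 0.005 / 2.81)
  # E = 0.5 is the definition of the critical distance
  expect_equal(donor_acceptor_distance(0.5, 1.74), 1.74, tolerance = 1e-12)
  # strictly decreasing in E at fixed R0
  es <- seq(0.05, 0.95, by = 0.05)
  rs <- vapply(es, donor_acceptor_distance, numeric(1), r0 = 1.74)
  expect_true(all(diff(rs) < 0))
  expect_error(donor_acceptor_distance(0, 1.74), "undefined")
  expect_error(donor_acceptor_distance(1, 1.74), "undefined")
})

test_that("efficiency and distance invert each other around R0", {
  # chain consistency: E -> r -> E returns the start to 1e-9 relative
  set.seed(5)
  for (i in 1:25) {
    J <- 10^runif(1, -17, -14)
    r0 <- forster_radius(J)
    E <- runif(1, 0.01, 0.99)
    r <- donor_acceptor_distance(E, r0)
    expect_lt(abs(efficiency_from_distance(r, r0) - E) / E, 1e-9)
  }
})

test_that("validity report encodes the 8 nm and static-band conditions", {
  ok <- check_forster_conditions(2.81, 1.74)
  expect_true(ok$within_8nm)
  expect_true(ok$static_band)
  expect_equal(ok$ratio, 2.81 / 1.74)
  expect_false(check_forster_conditions(9.0, 1.74)$within_8nm)
  expect_false(check_forster_conditions(0.5, 1.74)$static_band)
})

test_that("fret_chain runs the full Forster cascade end to end", {
  tr <- synthetic_truth(noise_sd_relative = 0)
  pair <- gen_spectra_pair(tr)
  res <- fret_chain(pair$emission, pair$absorbance,
                    acceptor_conc_molar = 5e-6, f = 94.7, f0 = 100)
  expect_equal(res$efficiency, 0.053)
  expect_equal(res$r_nm,
               donor_acceptor_distance(0.053, forster_radius(res$J)))
  expect_true(res$conditions$within_8nm)
})
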