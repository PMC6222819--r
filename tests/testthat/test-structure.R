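test_that("mean residue ellipticity applies the standard normalization", {
  pc <- protein_constants(molecular_weight = 80000, residue_count = 708,
                          cd_path_length_cm = 0.1,
                          concentration_g_per_L = 0.5)
  expect_equal(mre(10, pc), 10 * 80000 / (10 * 708 * 0.1 * 0.5))
  expect_equal(mre(0, pc), 0)
  # linear in theta, inverse-linear in concentration
  expect_equal(mre(c(1, 2, 4), pc), mre(1, pc) * c(1, 2, 4))
  pc2 <- protein_constants(concentration_g_per_L = 1)
  expect_equal(mre(10, pc2),
               mre(10, protein_constants(concentration_g_per_L = 2)) * 2)
  # spectrum in, converted spectrum out
  tr <- spectrum(c(200, 211, 240), c(-5, -12, -7), kind = "cd")
  out <- mre(tr, pc)
  expect_s3_class(out, "spectrum")
  expect_equal(out$value, mre(tr$value, pc))
  expect_error(mre(spectrum(c(1, 2), c(1, 2)), pc), "'cd'")
  expect_error(protein_constants(concentration_g_per_L = 0), "positive")
  expect_error(protein_constants(residue_count = 1.5), "integer")
})

sync_fixture <- function(centers, heights, wl = seq(250, 320, by = 0.2)) {
  Map(function(ctr, h) spectrum(wl, h * exp(-(wl - ctr)^2 / (2 * 8^2))),
      centers, heights)
}

test_that("synchronous-fluorescence summary reports shifts and quenching", {
  conc <- c(0, 1e-6, 2e-6)
  # identical spectra: no shift, no quench
  same <- sync_fixture(rep(287.4, 3), rep(370, 3))
  tab <- sync_shift_summary(same, conc, 60)
  expect_equal(tab$shift_nm, c(0, 0, 0))
  expect_equal(tab$quench, c(0, 0, 0))
  expect_equal(unique(tab$channel), "tryptophan")
  # peak drifting 287.4 -> 287.8 nm is resolved as +0.4 nm
  drift <- sync_fixture(c(287.4, 287.6, 287.8), rep(120, 3))
  tab <- sync_shift_summary(drift, conc, 15)
  expect_equal(tab$shift_nm[3], 0.4, tolerance = 1e-9)
  expect_equal(unique(tab$channel), "tyrosine")
  # intensities falling 370 -> 270 report a quench of 100
  quench <- sync_fixture(rep(279.4, 3), c(370, 320, 270))
  tab <- sync_shift_summary(quench, conc, 60)
  expect_equal(tab$quench[3], 100, tolerance = 1e-9)
  expect_error(sync_shift_summary(drift, conc, 30), "15.*60")
  expect_error(sync_shift_summary(drift[1], 0, 15), ">= 2")
  expect_error(sync_shift_summary(drift, c(1e-6, 2e-6, 3e-6), 15),
               "ligand-free")
})

test_that("EEM peak picking recovers labeled fluorophore peaks off the ridges", {
  # axes include the reported positions exactly
  g <- gen_eem(peaks = data.frame(ex = c(280, 225), em = c(332, 331),
                                  height = c(468.0, 239.5), width = c(10, 10)),
               excitation_nm = seq(200, 350, by = 5),
               emission_nm = seq(200, 500, by = 1))
  pk <- eem_peaks(g)
  a <- pk[pk$label == "peakA", ]
  expect_equal(a$excitation_nm, 280)
  expect_equal(a$emission_nm, 332)
  expect_equal(a$intensity, 468.0, tolerance = 1e-3)
  b <- pk[pk$label == "peakB", ]
  expect_equal(b$excitation_nm, 225)
  expect_equal(b$emission_nm, 331)
  expect_true(all(c("rayleigh1", "rayleigh2") %in% pk$label))
})

test_that("scatter ridges are masked out of the fluorophore peaks", {
  # a ridge along em = ex only
  g <- gen_eem(peaks = data.frame(ex = numeric(0), em = numeric(0),
                                  height = numeric(0), width = numeric(0)),
               rayleigh_height = 500)
  pk <- eem_peaks(g)
  expect_true("rayleigh1" %in% pk$label)
  expect_false(any(pk$label %in% c("peakA", "peakB")))
  # no reported fluorophore peak ever sits on a masked ridge
  for (seed in 1:5) {
    gn <- gen_eem(noise_sd = 3, seed = seed)
    pn <- eem_peaks(gn)
    fl <- pn[pn$label %in% c("peakA", "peakB", "other"), ]
    if (nrow(fl)) {
      expect_true(all(abs(fl$emission_nm - fl$excitation_nm) > 10))
      expect_true(all(abs(fl$emission_nm - 2 * fl$excitation_nm) > 10))
    }
  }
})

test_that("an all-zero EEM yields no peaks", {
  z <- eem_grid(seq(200, 350, 5), seq(200, 500, 5),
                matrix(0, 31, 61))
  expect_equal(nrow(eem_peaks(z)), 0)
})

test_that("hydrophobicity slopes are recovered exactly on clean lines", {
  h <- hydrophobicity_slope(c(0, 1), c(0, 3.791))
  expect_equal(h$s0, 3.791)
  d <- gen_ans_series(2.836, noise_sd_relative = 0)
  h2 <- hydrophobicity_slope(d$concentration, d$relative_f,
                             emission_peak_nm = 500)
  expect_equal(h2$s0, 2.836, tolerance = 1e-12)
  expect_equal(h2$r_squared, 1)
  expect_error(hydrophobicity_slope(c(1, 1), c(1, 2)),
               "strictly increasing")
  expect_error(hydrophobicity_slope(1, 1), ">= 2")
})

test_that("noisy hydrophobicity recovery stays within 5% in the median", {
  s0 <- vapply(1:200, function(i) {
    d <- gen_ans_series(2.836, noise_sd_relative = 0.02, seed = i)
    hydrophobicity_slope(d$concentration, d$relative_f)$s0
  }, numeric(1))
  expect_lt(abs(median(s0) - 2.836) / 2.836, 0.05)
})

test_that("the hydrophobicity drop between systems is reported as a percentage", {
  ref <- hydrophobicity_slope(c(0, 1), c(0, 3.791))
  trt <- hydrophobicity_slope(c(0, 1), c(0, 2.836))
  expect_equal(hydrophobicity_change_percent(ref, trt),
               100 * (1 - 2.836 / 3.791))
})
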