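sv_series <- function(ksv, f0 = 390, temperature = 300,
                      conc = seq(0, 5e-6, by = 5e-7)) {
  titration_series(conc, f0 / (1 + ksv * conc), temperature)
}

test_that("Stern-Volmer fit recovers exact synthetic constants", {
  for (ksv in c(6.88e4, 5.14e4, 4.74e4)) {
    q <- stern_volmer_fit(sv_series(ksv))
    expect_lt(abs(q$ksv - ksv) / ksv, 1e-10)
    expect_lt(abs(q$intercept - 1), 1e-10)
    expect_length(q$flags, 0)
  }
})

test_that("Kq is exactly Ksv / tau0", {
  q <- stern_volmer_fit(sv_series(5.14e4), tau0 = 1e-8)
  expect_equal(q$kq, q$ksv / 1e-8)
  expect_lt(abs(q$kq - 5.14e12) / 5.14e12, 1e-10)
  # ratio invariant across random constants and lifetimes
  set.seed(11)
  for (i in 1:10) {
    ksv <- runif(1, 1e3, 1e6)
    tau <- 10^runif(1, -9, -7)
    q <- stern_volmer_fit(sv_series(ksv), tau0 = tau)
    expect_equal(q$kq * tau, q$ksv)
  }
})

test_that("constant intensity yields zero slope and a no-quenching flag", {
  s <- titration_series(seq(0, 5e-6, by = 5e-7), rep(390, 11), 300)
  q <- stern_volmer_fit(s)
  expect_equal(q$ksv, 0)
  expect_true("no quenching" %in% q$flags)
})

test_that("an intercept far from one is flagged", {
  conc <- seq(0, 5e-6, by = 5e-7)
  # titrated points follow F0/F = 1.2 + Ksv[Q]: the ratio line does not
  # extrapolate through 1 at zero dose
  f <- c(390, 390 / (1.2 + 5e4 * conc[-1]))
  q <- stern_volmer_fit(titration_series(conc, f, 300))
  expect_true("intercept deviates from 1" %in% q$flags)
})

test_that("Stern-Volmer preconditions are enforced", {
  expect_error(stern_volmer_fit(
    titration_series(c(0, 1e-6, 2e-6), c(3, 2, 1), 300)), ">= 3 nonzero")
  expect_error(stern_volmer_fit(sv_series(5e4), tau0 = 0), "positive")
})

test_that("mechanism classification follows the temperature/Kq rules", {
  mk <- function(ksv, temp, tau0 = 1e-8)
    stern_volmer_fit(sv_series(ksv, temperature = temp), tau0 = tau0)
  # study conditions: Ksv falls with T, Kq far above the diffusion limit
  paper <- list(mk(6.88e4, 290), mk(5.14e4, 300), mk(4.74e4, 310))
  expect_equal(classify_mechanism(paper)$mechanism, "static")
  # increasing Ksv with collisional-scale Kq: dynamic
  dyn <- list(mk(1e3, 290, tau0 = 1e-6), mk(2e3, 300, tau0 = 1e-6))
  expect_true(all(vapply(dyn, `[[`, numeric(1), "kq") <= 2e10))
  expect_equal(classify_mechanism(dyn)$mechanism, "dynamic")
  # decreasing Ksv but Kq below the limit: indeterminate
  ind <- list(mk(2e3, 290, tau0 = 1e-6), mk(1e3, 300, tau0 = 1e-6))
  cl <- classify_mechanism(ind)
  expect_equal(cl$mechanism, "indeterminate")
  expect_match(cl$reason, "decreasing")
  expect_error(classify_mechanism(list(mk(5e4, 300))), ">=2 temperatures")
})

test_that("double-log fit inverts the binding isotherm exactly", {
  conc <- seq(0, 5e-6, by = 5e-7)
  ka <- 2.551e4
  n <- 1.316
  f <- 390 / (1 + ka * conc^n)
  f[1] <- 390
  b <- double_log_fit(titration_series(conc, f, 300))
  expect_lt(abs(b$ka - ka) / ka, 1e-10)
  expect_lt(abs(b$n_sites - n), 1e-10)
})

test_that("with one site the double-log constant equals the Stern-Volmer constant", {
  s <- sv_series(6.88e4)
  ksv <- stern_volmer_fit(s)$ksv
  b <- double_log_fit(s)
  expect_lt(abs(b$ka - ksv) / ksv, 1e-8)
  expect_lt(abs(b$n_sites - 1), 1e-8)
})

test_that("unquenched points are dropped with a warning; too few points error", {
  conc <- seq(0, 5e-6, by = 5e-7)
  f <- 390 / (1 + 6.88e4 * conc)
  f[2] <- 390  # F = F0 at the first nonzero dose
  expect_warning(b <- double_log_fit(titration_series(conc, f, 300)),
                 "F >= F0")
  expect_equal(b$n_points, 9L)
  flat <- titration_series(conc, rep(390, 11), 300)
  expect_warning(expect_error(double_log_fit(flat), "fewer than 3"),
                 "F >= F0")
})

test_that("noise-free generator/fitter round trips reach machine precision", {
  tr <- synthetic_truth(ksv_by_T = c("300" = 6.88e4), ka = 6.88e4,
                        n_sites = 1, noise_sd_relative = 0)
  q <- stern_volmer_fit(gen_quench_titration(tr, 300))
  expect_lt(abs(q$ksv - 6.88e4) / 6.88e4, 1e-10)
  tr2 <- synthetic_truth(noise_sd_relative = 0)
  b <- double_log_fit(gen_quench_titration(tr2, 300))
  expect_lt(abs(b$ka - tr2$ka) / tr2$ka, 1e-10)
  expect_lt(abs(b$n_sites - tr2$n_sites), 1e-10)
})

test_that("noisy recovery medians stay within the regression tolerances", {
  # observable quenching conditions: Ksv-scale constant, single site, 1% noise
  tr <- synthetic_truth(ksv_by_T = c("290" = 6.88e4), ka = 6.88e4,
                        n_sites = 1, noise_sd_relative = 0.01)
  ka <- n <- ksv <- numeric(200)
  for (i in 1:200) {
    s <- gen_quench_titration(tr, 290, seed = i)
    b <- suppressWarnings(double_log_fit(s))
    ka[i] <- b$ka
    n[i] <- b$n_sites
    ksv[i] <- stern_volmer_fit(s)$ksv
  }
  expect_lt(abs(median(ka) - 6.88e4) / 6.88e4, 0.10)
  expect_lt(abs(median(n) - 1), 0.1)
  # fitted Ksv distribution is centered on truth
  expect_lt(abs(median(ksv) - 6.88e4) / 6.88e4, 0.02)
})
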