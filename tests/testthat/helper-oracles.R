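# Independent oracles used to cross-check package computations.  These
# deliberately use different algorithms from the implementation.

# Slope/intercept of an ordinary least-squares line, from the covariance
# formulas (not lm).
ols_line <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - b * mean(x), slope = b)
}

# Complex concentration at mass-action equilibrium by bisection on
# (A - ab)(B - ab)/ab = Kd (not the quadratic formula).
bisect_complex <- function(A, B, Kd, iter = 200) {
  if (A == 0 || B == 0) return(0)
  g <- function(ab) (A - ab) * (B - ab) / ab - Kd
  lo <- 0
  hi <- min(A, B)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Brute-force overlap integral: rectangle rule on a fine grid with both
# spectra linearly interpolated; absorptivity zero outside its range.
overlap_oracle <- function(donor, eps, dx = 0.01) {
  xs <- seq(min(donor$wavelength_nm), max(donor$wavelength_nm), by = dx)
  fv <- approx(donor$wavelength_nm, donor$value, xout = xs)$y
  ev <- approx(eps$wavelength_nm, eps$value, xout = xs, rule = 1)$y
  ev[is.na(ev)] <- 0
  sum(fv * ev * (xs * 1e-7)^4 * dx) / sum(fv * dx)
}

# Writes delimited lines to a temp file and returns its path.
write_tmp <- function(lines) {
  p <- tempfile(fileext = ".csv")
  writeLines(lines, p)
  p
}
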