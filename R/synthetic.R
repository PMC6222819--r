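# Seeded synthetic-data generators with known ground truth.  Each generator
# is the right-inverse of its fitting operation at zero noise, so every
# stage of the pipeline can be validated by parameter recovery.

#' Ground-truth parameter set for synthetic titrations
#'
#' Collects every parameter the generators need, with defaults matching the
#' bovine lactoferrin / tetracycline study conditions: Stern-Volmer
#' constants falling from 6.88e4 to 4.74e4 L/mol over 290-310 K, an
#' association constant of 2.551e4 L/mol with 1.316 apparent sites at
#' 300 K, binding enthalpy -87.56 kJ/mol and entropy +70.45 J/mol/K, a
#' thermophoresis Kd of 35,200 nM, ANS hydrophobicity slopes 3.791
#' (reference) and 2.836 (treated), and a tryptophan emission band at
#' 332.2 nm.
#'
#' @param ksv_by_T Named numeric: Stern-Volmer constant (L/mol) per
#'   temperature (K).
#' @param ka Association constant, L/mol.
#' @param n_sites Apparent number of binding sites.
#' @param dH Binding enthalpy, J/mol.
#' @param dS Binding entropy, J/mol/K.
#' @param kd Dissociation constant, mol/L.
#' @param s0 Named numeric: ANS slope per system.
#' @param f0 Ligand-free fluorescence intensity, a.u.
#' @param emission_center_nm,emission_width_nm Gaussian emission band
#'   center and standard deviation, nm.
#' @param absorbance_bands List of `c(center, width, peak)` triplets (nm,
#'   nm, AU) describing the acceptor absorption spectrum.
#' @param noise_sd_relative Relative standard deviation of multiplicative
#'   Gaussian measurement noise (0 = exact).
#' @param seed Default integer seed for all stochastic draws.
#' @return A list of class `"synthetic_truth"`.
#' @export
synthetic_truth <- function(ksv_by_T = c("290" = 6.88e4, "300" = 5.14e4,
                                         "310" = 4.74e4),
                            ka = 2.551e4, n_sites = 1.316,
                            dH = -87560, dS = 70.45,
                            kd = 3.52e-5,
                            s0 = c(reference = 3.791, treated = 2.836),
                            f0 = 390,
                            emission_center_nm = 332.2,
                            emission_width_nm = 25,
                            absorbance_bands = list(c(276, 18, 0.04),
                                                    c(360, 22, 0.05)),
                            noise_sd_relative = 0.01,
                            seed = 1L) {
  if (any(c(ksv_by_T, ka, n_sites, kd, f0, emission_center_nm,
            emission_width_nm) <= 0))
    stop("physical truth parameters must be positive", call. = FALSE)
  if (noise_sd_relative < 0) stop("noise sd must be >= 0", call. = FALSE)
  structure(list(ksv_by_T = ksv_by_T, ka = ka, n_sites = n_sites,
                 dH = dH, dS = dS, kd = kd, s0 = s0, f0 = f0,
                 emission_center_nm = emission_center_nm,
                 emission_width_nm = emission_width_nm,
                 absorbance_bands = absorbance_bands,
                 noise_sd_relative = noise_sd_relative,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

# Local seeding that restores the caller's RNG state on exit.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  expr
}

#' Generate a quenching titration with known constants
#'
#' Emits F = F0 / (1 + Ka \[Q\]^n), which reduces to the Stern-Volmer form
#' F0/F = 1 + Ksv \[Q\] when n = 1, then applies multiplicative Gaussian
#' noise at the truth's relative standard deviation.  When `n_sites` is 1
#' and the truth carries a Stern-Volmer constant for the requested
#' temperature, that per-temperature constant is used; otherwise `ka`.
#'
#' @param truth A [synthetic_truth()].
#' @param temperature_K Temperature of the series, K.
#' @param conc_molar Ligand concentration grid starting at 0 (default the
#'   11-point 0-5e-6 mol/L ladder used in the study conditions).
#' @param seed Integer seed (default taken from `truth`).
#' @return A [titration_series()].
#' @export
gen_quench_titration <- function(truth, temperature_K = 300,
                                 conc_molar = seq(0, 5e-6, by = 5e-7),
                                 seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (conc_molar[1] != 0)
    stop("concentration grid must start at 0", call. = FALSE)
  key <- as.character(temperature_K)
  strength <- if (truth$n_sites == 1 && key %in% names(truth$ksv_by_T))
    unname(truth$ksv_by_T[key]) else truth$ka
  f <- truth$f0 / (1 + strength * conc_molar^truth$n_sites)
  f[1] <- truth$f0
  # Noise perturbs the titrated points only: the ligand-free anchor is the
  # replicate-averaged reference scan, and noise on it would enter every
  # F0/F ratio as a correlated error.
  if (truth$noise_sd_relative > 0)
    f[-1] <- with_seed(seed,
      f[-1] * (1 + stats::rnorm(length(f) - 1L, 0, truth$noise_sd_relative)))
  titration_series(conc_molar, f, temperature_K,
                   label = sprintf("synthetic %g K", temperature_K))
}

#' Generate association constants from a (dH, dS) pair
#'
#' Ka(T) = exp(-dH/(R T) + dS/R), optionally perturbed by lognormal noise,
#' so that a van't Hoff fit of the zero-noise output returns (dH, dS)
#' exactly.
#'
#' @param truth A [synthetic_truth()].
#' @param temperature_K Distinct positive temperatures, K.
#' @param noise_sd_log Standard deviation of additive Gaussian noise on
#'   ln Ka (0 = exact).
#' @param seed Integer seed.
#' @return Named numeric vector of Ka (L/mol) by temperature.
#' @export
gen_ka_by_temperature <- function(truth, temperature_K = c(290, 300, 310),
                                  noise_sd_log = 0, seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (any(temperature_K <= 0) || anyDuplicated(temperature_K))
    stop("temperatures must be positive and distinct", call. = FALSE)
  lnka <- -truth$dH / (GAS_CONSTANT * temperature_K) + truth$dS / GAS_CONSTANT
  if (noise_sd_log > 0)
    lnka <- with_seed(seed,
      lnka + stats::rnorm(length(lnka), 0, noise_sd_log))
  stats::setNames(exp(lnka), as.character(temperature_K))
}

#' Generate a thermophoresis dose-response curve
#'
#' Response = baseline + amplitude x exact bound fraction, plus additive
#' Gaussian noise scaled by `amplitude` (so the truth's
#' `noise_sd_relative` is relative to the full binding signal).  The
#' default dose ladder is fifteen two-fold dilutions from 2 mM down to
#' 122.07 nM, the conventional thermophoresis capillary series.
#'
#' @param truth A [synthetic_truth()].
#' @param A_total Labeled-species concentration, mol/L (default 200 nM).
#' @param top_dose Highest titrant dose, mol/L.
#' @param n_doses Number of doses in the ladder.
#' @param dilution Dilution factor between adjacent doses.
#' @param baseline,amplitude Affine map from bound fraction to signal.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `dose_molar`, `response`
#'   (increasing dose order).
#' @export
gen_mst_curve <- function(truth, A_total = 2e-7, top_dose = 2e-3,
                          n_doses = 15, dilution = 2,
                          baseline = 800, amplitude = 40,
                          seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  dose <- top_dose / dilution^((n_doses - 1):0)
  fb <- fraction_bound(A_total, dose, truth$kd)$bound_fraction
  resp <- baseline + amplitude * fb
  if (truth$noise_sd_relative > 0)
    resp <- with_seed(seed,
      resp + stats::rnorm(length(resp), 0,
                          truth$noise_sd_relative * abs(amplitude)))
  data.frame(dose_molar = dose, response = resp)
}

# Gaussian band on a wavelength grid.
gauss_band <- function(wl, center, width, height)
  height * exp(-(wl - center)^2 / (2 * width^2))

#' Generate a donor-emission / acceptor-absorbance spectrum pair
#'
#' The donor emission is a Gaussian band at the truth's center (default
#' 332.2 nm, tryptophan); the acceptor absorbance is a sum of Gaussian
#' bands (default including the 360 nm band a bound tetracycline acquires).
#' The two grids are deliberately spaced differently so the overlap
#' integral must interpolate.
#'
#' @param truth A [synthetic_truth()].
#' @param emission_grid_nm Donor wavelength grid.
#' @param absorbance_grid_nm Acceptor wavelength grid.
#' @param seed Integer seed.
#' @return A list with elements `emission` and `absorbance`, both
#'   `"spectrum"` objects.
#' @export
gen_spectra_pair <- function(truth,
                             emission_grid_nm = seq(290, 460, by = 1),
                             absorbance_grid_nm = seq(250, 450, by = 2),
                             seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  emi <- gauss_band(emission_grid_nm, truth$emission_center_nm,
                    truth$emission_width_nm, truth$f0)
  abs_v <- rowSums(vapply(truth$absorbance_bands, function(b)
    gauss_band(absorbance_grid_nm, b[1], b[2], b[3]),
    numeric(length(absorbance_grid_nm))))
  if (truth$noise_sd_relative > 0) {
    noised <- with_seed(seed, {
      e <- emi * (1 + stats::rnorm(length(emi), 0, truth$noise_sd_relative))
      a <- abs_v * (1 + stats::rnorm(length(abs_v), 0, truth$noise_sd_relative))
      list(e = e, a = a)
    })
    emi <- noised$e
    abs_v <- pmax(noised$a, 0)
  }
  list(emission = spectrum(emission_grid_nm, emi, kind = "emission"),
       absorbance = spectrum(absorbance_grid_nm, abs_v, kind = "absorbance"))
}

#' Generate an excitation-emission matrix with scatter ridges
#'
#' Places Gaussian fluorophore peaks on the grid together with first- and
#' second-order Rayleigh scatter ridges (along emission = excitation and
#' emission = 2 x excitation), plus optional additive noise.  Defaults
#' reproduce the lactoferrin landscape: a tryptophan/tyrosine peak of
#' height 468.0 at 280/332 nm and a backbone peak of 239.5 at 225/331 nm
#' on 5 nm axes.
#'
#' @param peaks `data.frame` with columns `ex`, `em`, `height`, `width`
#'   (nm, nm, a.u., nm).
#' @param excitation_nm,emission_nm Grid axes.
#' @param rayleigh_height,rayleigh_width Ridge amplitude and Gaussian
#'   cross-section width, nm.
#' @param noise_sd Additive Gaussian noise standard deviation, a.u.
#' @param seed Integer seed.
#' @return An [eem_grid()].
#' @export
gen_eem <- function(peaks = data.frame(ex = c(280, 225), em = c(332, 331),
                                       height = c(468.0, 239.5),
                                       width = c(12, 12)),
                    excitation_nm = seq(200, 350, by = 5),
                    emission_nm = seq(200, 500, by = 5),
                    rayleigh_height = 1000, rayleigh_width = 4,
                    noise_sd = 0, seed = 1L) {
  M <- matrix(0, length(excitation_nm), length(emission_nm))
  for (k in seq_len(nrow(peaks)))
    M <- M + outer(excitation_nm, emission_nm, function(x, m)
      peaks$height[k] *
        exp(-((x - peaks$ex[k])^2 + (m - peaks$em[k])^2) /
              (2 * peaks$width[k]^2)))
  M <- M + outer(excitation_nm, emission_nm, function(x, m)
    rayleigh_height * exp(-(m - x)^2 / (2 * rayleigh_width^2)) +
      0.5 * rayleigh_height * exp(-(m - 2 * x)^2 / (2 * rayleigh_width^2)))
  if (noise_sd > 0)
    M <- with_seed(seed,
      M + matrix(stats::rnorm(length(M), 0, noise_sd), nrow(M)))
  eem_grid(excitation_nm, emission_nm, M)
}

#' Generate an ANS hydrophobicity titration
#'
#' Relative fluorescence rising linearly with protein concentration at
#' slope S0, with multiplicative Gaussian noise.
#'
#' @param s0 True slope.
#' @param concentration Protein concentration grid.
#' @param intercept Intercept of the line.
#' @param noise_sd_relative Relative noise standard deviation.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `concentration`, `relative_f`.
#' @export
gen_ans_series <- function(s0, concentration = seq(0, 10, length.out = 11),
                           intercept = 0, noise_sd_relative = 0, seed = 1L) {
  rf <- intercept + s0 * concentration
  if (noise_sd_relative > 0)
    rf <- with_seed(seed,
      rf * (1 + stats::rnorm(length(rf), 0, noise_sd_relative)))
  data.frame(concentration = concentration, relative_f = rf)
}
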