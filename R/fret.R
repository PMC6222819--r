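# Forster resonance energy transfer: overlap integral, critical radius,
# transfer efficiency and donor-acceptor distance.

#' Photophysical constants for the Forster chain
#'
#' @param kappa2 Dipole orientation factor K^2 (default 2/3, the isotropic
#'   dynamic-averaging value).
#' @param refractive_index Refractive index of the medium (default 1.336,
#'   aqueous buffer).
#' @param quantum_yield Donor fluorescence quantum yield in (0, 1]
#'   (default 0.118, reported for lactoferrin tryptophans).
#' @return A list of class `"fret_constants"`.
#' @export
fret_constants <- function(kappa2 = 2 / 3, refractive_index = 1.336,
                           quantum_yield = 0.118) {
  if (kappa2 <= 0 || refractive_index <= 0)
    stop("kappa2 and refractive_index must be positive", call. = FALSE)
  if (quantum_yield <= 0 || quantum_yield > 1)
    stop("quantum_yield must lie in (0, 1]", call. = FALSE)
  structure(list(kappa2 = kappa2, refractive_index = refractive_index,
                 quantum_yield = quantum_yield),
            class = "fret_constants")
}

#' Molar absorptivity from a measured absorbance trace
#'
#' Applies the Beer-Lambert law pointwise: epsilon(lambda) = A(lambda) /
#' (c l), with the acceptor concentration and cuvette path supplied by the
#' caller.
#'
#' @param absorbance A `"spectrum"` of kind `"absorbance"` (AU).
#' @param acceptor_conc_molar Acceptor concentration, mol/L, > 0.
#' @param path_cm Optical path length in cm (default 1).
#' @return A `"spectrum"` of kind `"absorbance"` holding epsilon(lambda) in
#'   L/mol/cm (recorded in its `units` field).
#' @export
molar_absorptivity <- function(absorbance, acceptor_conc_molar, path_cm = 1) {
  stopifnot(inherits(absorbance, "spectrum"))
  if (absorbance$kind != "absorbance")
    stop("molar_absorptivity needs a spectrum of kind 'absorbance'",
         call. = FALSE)
  if (acceptor_conc_molar <= 0 || path_cm <= 0)
    stop("concentration and path length must be positive", call. = FALSE)
  spectrum(absorbance$wavelength_nm,
           absorbance$value / (acceptor_conc_molar * path_cm),
           kind = "absorbance", units = "L/mol/cm")
}

#' Spectral overlap integral J
#'
#' J = sum F(lambda) epsilon(lambda) lambda^4 d lambda / sum F(lambda)
#' d lambda, evaluated with trapezoidal weights on the donor emission grid.
#' The acceptor absorptivity is linearly interpolated onto the donor grid
#' and taken as zero outside its measured range; the wavelength entering
#' the lambda^4 factor is converted to cm so that J carries cm^3 L mol^-1,
#' the units under which the 8.79e-25 critical-radius prefactor is
#' dimensionally correct.
#'
#' @param donor_emission Donor `"spectrum"` of kind `"emission"`.
#' @param epsilon Acceptor molar absorptivity `"spectrum"` (L/mol/cm), e.g.
#'   from [molar_absorptivity()].
#' @return J in cm^3 L mol^-1.
#' @export
overlap_integral <- function(donor_emission, epsilon) {
  stopifnot(inherits(donor_emission, "spectrum"),
            inherits(epsilon, "spectrum"))
  if (donor_emission$kind != "emission")
    stop("donor spectrum must be of kind 'emission'", call. = FALSE)
  lo <- max(min(donor_emission$wavelength_nm), min(epsilon$wavelength_nm))
  hi <- min(max(donor_emission$wavelength_nm), max(epsilon$wavelength_nm))
  if (lo >= hi)
    stop("no spectral overlap between donor emission and acceptor absorption",
         call. = FALSE)
  wl <- donor_emission$wavelength_nm
  fv <- donor_emission$value
  eps <- stats::approx(epsilon$wavelength_nm, epsilon$value, xout = wl,
                       rule = 1)$y
  eps[is.na(eps)] <- 0
  lam_cm <- wl * 1e-7
  num <- pracma::trapz(wl, fv * eps * lam_cm^4)
  den <- pracma::trapz(wl, fv)
  if (den == 0) stop("donor emission integrates to zero", call. = FALSE)
  num / den
}

#' Forster critical radius R0
#'
#' R0^6 = 8.79e-25 K^2 n^-4 Phi J with J in cm^3 L mol^-1 gives R0 in cm;
#' the result is returned in nm.  R0 is the donor-acceptor distance at
#' which the transfer efficiency is 50%.
#'
#' @param J Overlap integral, cm^3 L mol^-1, >= 0.
#' @param constants A [fret_constants()] object.
#' @return R0 in nm.
#' @export
forster_radius <- function(J, constants = fret_constants()) {
  stopifnot(inherits(constants, "fret_constants"))
  if (J < 0) stop("overlap integral must be nonnegative", call. = FALSE)
  r0_cm <- (8.79e-25 * constants$kappa2 * constants$refractive_index^-4 *
              constants$quantum_yield * J)^(1 / 6)
  r0_cm * 1e7
}

#' Energy transfer efficiency from donor quenching
#'
#' @param f Donor intensity in the presence of acceptor, 0 < f <= f0.
#' @param f0 Donor intensity without acceptor.
#' @return E = 1 - f/f0.
#' @export
transfer_efficiency <- function(f, f0) {
  if (f0 <= 0 || f <= 0) stop("intensities must be positive", call. = FALSE)
  if (f > f0)
    stop("F > F0 would give a negative transfer efficiency", call. = FALSE)
  1 - f / f0
}

#' Transfer efficiency implied by a donor-acceptor distance
#'
#' @param r Donor-acceptor distance, nm, > 0.
#' @param r0 Critical radius, nm, > 0.
#' @return E = R0^6 / (R0^6 + r^6).
#' @export
efficiency_from_distance <- function(r, r0) {
  if (r <= 0 || r0 <= 0) stop("distances must be positive", call. = FALSE)
  r0^6 / (r0^6 + r^6)
}

#' Donor-acceptor distance from transfer efficiency
#'
#' Inverts E = R0^6 / (R0^6 + r^6).
#'
#' @param E Transfer efficiency, strictly between 0 and 1.
#' @param r0 Critical radius, nm, > 0.
#' @return r in nm.
#' @export
donor_acceptor_distance <- function(E, r0) {
  if (E <= 0 || E >= 1)
    stop("distance is undefined at E = 0 or E = 1", call. = FALSE)
  if (r0 <= 0) stop("R0 must be positive", call. = FALSE)
  r0 * ((1 - E) / E)^(1 / 6)
}

#' Validity checks for non-radiative energy transfer
#'
#' Reports whether the donor-acceptor distance satisfies the conditions
#' under which Forster transfer is operative: r below 8 nm, and r within
#' (0.5 R0, 2 R0) — the band conventionally taken as consistent with
#' static (complex-forming) quenching.
#'
#' @param r Donor-acceptor distance, nm, > 0.
#' @param r0 Critical radius, nm, > 0.
#' @return A list: `within_8nm`, `static_band`, `ratio` (= r/R0).
#' @export
check_forster_conditions <- function(r, r0) {
  if (r <= 0 || r0 <= 0) stop("distances must be positive", call. = FALSE)
  list(within_8nm = r < 8,
       static_band = r > 0.5 * r0 && r < 2 * r0,
       ratio = r / r0)
}

#' Run the full Forster chain
#'
#' Convenience wrapper: from a donor emission spectrum, an acceptor
#' absorbance trace with its concentration, and a quenched/unquenched
#' intensity pair, computes J, R0, E, r and the validity report.
#'
#' @param donor_emission Donor `"spectrum"` (emission).
#' @param acceptor_absorbance Acceptor `"spectrum"` (absorbance, AU).
#' @param acceptor_conc_molar Acceptor concentration behind the absorbance
#'   trace, mol/L.
#' @param f,f0 Donor intensity with and without acceptor.
#' @param constants A [fret_constants()] object.
#' @param path_cm Cuvette path, cm.
#' @return An object of class `"fret_result"`: `J`, `r0_nm`, `efficiency`,
#'   `r_nm`, `conditions`.
#' @export
fret_chain <- function(donor_emission, acceptor_absorbance,
                       acceptor_conc_molar, f, f0,
                       constants = fret_constants(), path_cm = 1) {
  eps <- molar_absorptivity(acceptor_absorbance, acceptor_conc_molar, path_cm)
  J <- overlap_integral(donor_emission, eps)
  r0 <- forster_radius(J, constants)
  E <- transfer_efficiency(f, f0)
  r <- donor_acceptor_distance(E, r0)
  structure(list(J = J, r0_nm = r0, efficiency = E, r_nm = r,
                 conditions = check_forster_conditions(r, r0)),
            class = "fret_result")
}

#' @export
print.fret_result <- function(x, ...) {
  cat(sprintf("FRET chain: J = %.4g cm^3 L/mol, R0 = %.3f nm, E = %.4f, r = %.3f nm\n",
              x$J, x$r0_nm, x$efficiency, x$r_nm))
  cat(sprintf("  r < 8 nm: %s; 0.5 R0 < r < 2 R0: %s (r/R0 = %.3f)\n",
              x$conditions$within_8nm, x$conditions$static_band,
              x$conditions$ratio))
  invisible(x)
}
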