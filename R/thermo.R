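# van't Hoff thermodynamics and sign-rule classification of binding forces.

#' Universal gas constant, J/mol/K
#' @export
GAS_CONSTANT <- 8.314

#' van't Hoff regression of association constants
#'
#' Fits ln Ka = -dH/(R T) + dS/R by ordinary least squares of ln Ka on 1/T,
#' assuming the binding enthalpy and entropy are constant over the
#' temperature span.  Gibbs energies are populated at each input temperature
#' from dG = dH - T dS.
#'
#' As a diagnostic, dG is also evaluated through the equilibrium identity
#' -RT ln Ka; when the two disagree by more than `consistency_tol`
#' (relative), the result is flagged and a warning is raised.  Exactly
#' log-linear Ka satisfy the identity by construction, so a flag means the
#' supplied (Ka, T) pairs are not internally consistent with a single
#' (dH, dS).
#'
#' @param temperature_K Two or more distinct positive temperatures (K).
#' @param ka Association constants (L/mol), all positive, same length.
#' @param consistency_tol Relative tolerance of the dG cross-check.
#' @return An object of class `"thermo_params"`: `dH` (J/mol), `dS`
#'   (J/mol/K), `dG_by_T` (named, J/mol, from dH - T dS), `dG_from_lnKa`
#'   (named, J/mol, from -RT ln Ka), `r_squared`, `consistent`, `R`.
#' @export
vant_hoff_fit <- function(temperature_K, ka, consistency_tol = 0.01) {
  if (length(temperature_K) != length(ka))
    stop("temperature and Ka vectors must have the same length", call. = FALSE)
  if (length(temperature_K) < 2L)
    stop("need >= 2 distinct temperatures for a van't Hoff fit", call. = FALSE)
  if (anyDuplicated(temperature_K))
    stop("duplicate temperatures in van't Hoff input", call. = FALSE)
  if (any(temperature_K <= 0)) stop("temperatures must be positive (K)", call. = FALSE)
  if (any(!is.finite(ka)) || any(ka <= 0))
    stop("all Ka must be finite and positive", call. = FALSE)
  R <- GAS_CONSTANT
  x <- 1 / temperature_K
  y <- log(ka)
  fit <- stats::lm(y ~ x)
  dH <- -R * unname(stats::coef(fit)[2])
  dS <- R * unname(stats::coef(fit)[1])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(r2)) r2 <- NA_real_
  dG <- dH - temperature_K * dS
  names(dG) <- as.character(temperature_K)
  dG_lnka <- -R * temperature_K * log(ka)
  names(dG_lnka) <- as.character(temperature_K)
  rel <- abs(dG - dG_lnka) / pmax(abs(dG), abs(dG_lnka), 1)
  consistent <- all(rel <= consistency_tol)
  if (!consistent)
    warning(sprintf(
      "thermodynamic identity dG = -RT ln Ka disagrees with dH - T dS by up to %.1f%%; the supplied Ka are not log-linear in 1/T at a single (dH, dS)",
      100 * max(rel)), call. = FALSE)
  structure(list(dH = dH, dS = dS, dG_by_T = dG, dG_from_lnKa = dG_lnka,
                 r_squared = r2, consistent = consistent, R = R),
            class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf("van't Hoff fit: dH = %.4g kJ/mol, dS = %.4g J/mol/K, R^2 = %.4f\n",
              x$dH / 1000, x$dS, x$r_squared))
  for (tt in names(x$dG_by_T))
    cat(sprintf("  dG(%s K) = %.4g kJ/mol\n", tt, x$dG_by_T[[tt]] / 1000))
  if (!x$consistent)
    cat("  note: dG from -RT ln Ka disagrees with dH - T dS (inputs not log-linear)\n")
  invisible(x)
}

#' Gibbs free energy from enthalpy and entropy
#'
#' @param dH Enthalpy change, J/mol.
#' @param dS Entropy change, J/mol/K.
#' @param temperature_K Temperature(s), K, all positive.
#' @return dG = dH - T dS in J/mol, vectorized over `temperature_K`.
#' @export
gibbs <- function(dH, dS, temperature_K) {
  if (any(temperature_K <= 0)) stop("temperature must be positive (K)", call. = FALSE)
  dH - temperature_K * dS
}

#' Classify the dominant binding force from thermodynamic signs
#'
#' Applies the standard sign heuristic: dH > 0 with dS > 0 indicates
#' hydrophobic effects; dH < 0 with dS < 0 indicates van der Waals forces
#' and hydrogen bonds; dH < 0 with dS > 0 indicates electrostatic forces.
#' The remaining sign pattern and exact zeros are unclassified.
#'
#' @param dH Enthalpy change, J/mol (finite scalar).
#' @param dS Entropy change, J/mol/K (finite scalar).
#' @return A list with `force` (one of `"hydrophobic"`, `"vdw_hbond"`,
#'   `"electrostatic"`, `"unclassified"`) and `note`.
#' @export
classify_forces <- function(dH, dS) {
  if (!is.finite(dH) || !is.finite(dS))
    stop("dH and dS must be finite", call. = FALSE)
  if (dH == 0 || dS == 0)
    return(list(force = "unclassified",
                note = "a sign rule cannot be applied at an exact zero"))
  force <-
    if (dH > 0 && dS > 0) "hydrophobic"
    else if (dH < 0 && dS < 0) "vdw_hbond"
    else if (dH < 0 && dS > 0) "electrostatic"
    else "unclassified"
  note <- if (force == "unclassified")
    "dH > 0 with dS < 0 lies outside the sign rules" else ""
  list(force = force, note = note)
}

#' Tabulate binding thermodynamics
#'
#' Combines double-log binding fits and a van't Hoff result into one report
#' table (temperature, Ka, n, R-squared, dH, dG, dS) with kJ/mol display
#' units.
#'
#' @param binding_fits List of `"binding_fit"` objects, one per temperature.
#' @param thermo A `"thermo_params"` result.
#' @param compound Compound label column.
#' @return A `data.frame`.
#' @export
thermo_table <- function(binding_fits, thermo, compound = "") {
  if (inherits(binding_fits, "binding_fit")) binding_fits <- list(binding_fits)
  temps <- vapply(binding_fits, `[[`, numeric(1), "temperature_K")
  data.frame(
    compound = compound,
    temperature_K = temps,
    ka_L_per_mol = vapply(binding_fits, `[[`, numeric(1), "ka"),
    n_sites = vapply(binding_fits, `[[`, numeric(1), "n_sites"),
    r_squared = vapply(binding_fits, `[[`, numeric(1), "r_squared"),
    dH_kJ_per_mol = thermo$dH / 1000,
    dG_kJ_per_mol = unname(thermo$dG_by_T[as.character(temps)]) / 1000,
    dS_J_per_mol_K = thermo$dS)
}
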