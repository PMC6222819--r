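# Conformation-change summaries: mean residue ellipticity, synchronous
# fluorescence shifts, EEM peak picking, and ANS hydrophobicity slopes.

#' Protein constants for circular-dichroism normalization
#'
#' @param molecular_weight Protein molecular weight, g/mol (default 80000,
#'   bovine lactoferrin).
#' @param residue_count Number of amino acid residues, integer >= 2
#'   (default 708).
#' @param cd_path_length_cm Cuvette path in cm (default 0.1).
#' @param concentration_g_per_L Protein concentration in g/L.
#' @return A list of class `"protein_constants"`.
#' @export
protein_constants <- function(molecular_weight = 80000,
                              residue_count = 708,
                              cd_path_length_cm = 0.1,
                              concentration_g_per_L = 1) {
  if (molecular_weight <= 0 || cd_path_length_cm <= 0 ||
      concentration_g_per_L <= 0)
    stop("molecular weight, path length and concentration must be positive",
         call. = FALSE)
  if (residue_count < 2 || residue_count != round(residue_count))
    stop("residue_count must be an integer >= 2", call. = FALSE)
  structure(list(molecular_weight = molecular_weight,
                 residue_count = as.integer(residue_count),
                 cd_path_length_cm = cd_path_length_cm,
                 concentration_g_per_L = concentration_g_per_L),
            class = "protein_constants")
}

#' Mean residue ellipticity
#'
#' Converts an observed circular-dichroism signal in millidegrees to mean
#' residue ellipticity, MRE = theta M / (10 n l C) in deg cm^2 dmol^-1,
#' with M the molecular weight (g/mol), n the residue count, l the path in
#' cm and C the protein concentration in g/L.
#'
#' @param theta Observed CD in millidegrees (numeric vector), or a
#'   `"spectrum"` of kind `"cd"`, in which case a converted spectrum is
#'   returned.
#' @param constants A [protein_constants()] object.
#' @return MRE values (deg cm^2 dmol^-1), or a converted `"spectrum"`.
#' @export
mre <- function(theta, constants) {
  stopifnot(inherits(constants, "protein_constants"))
  factor <- constants$molecular_weight /
    (10 * constants$residue_count * constants$cd_path_length_cm *
       constants$concentration_g_per_L)
  if (inherits(theta, "spectrum")) {
    if (theta$kind != "cd")
      stop("mre needs a spectrum of kind 'cd'", call. = FALSE)
    return(spectrum(theta$wavelength_nm, theta$value * factor,
                    kind = "cd", units = "deg.cm^2/dmol"))
  }
  theta * factor
}

#' Synchronous-fluorescence shift summary
#'
#' Summarizes a series of synchronous-fluorescence spectra recorded at
#' increasing quencher concentrations and a fixed excitation-emission
#' offset: per-spectrum peak position and intensity, the peak shift
#' relative to the ligand-free trace, and the intensity quench.  The
#' offset selects the reporting residue: 15 nm for tyrosine, 60 nm for
#' tryptophan.
#'
#' @param spectra List of `"spectrum"` objects (>= 2), first recorded at
#'   zero quencher.
#' @param conc_molar Quencher concentrations, first exactly 0, strictly
#'   increasing, same length as `spectra`.
#' @param delta_lambda_nm Wavelength offset, 15 or 60.
#' @return A `data.frame` with columns `conc_molar`, `peak_nm`,
#'   `peak_intensity`, `shift_nm`, `quench`, `channel`.
#' @export
sync_shift_summary <- function(spectra, conc_molar, delta_lambda_nm) {
  if (!delta_lambda_nm %in% c(15, 60))
    stop("delta_lambda_nm must be 15 (tyrosine) or 60 (tryptophan)",
         call. = FALSE)
  if (length(spectra) < 2L)
    stop("need >= 2 spectra (ligand-free plus titrated)", call. = FALSE)
  if (length(spectra) != length(conc_molar))
    stop("one concentration per spectrum required", call. = FALSE)
  if (conc_molar[1] != 0)
    stop("first spectrum must be the ligand-free trace (conc 0)", call. = FALSE)
  if (is.unsorted(conc_molar, strictly = TRUE))
    stop("concentrations must be strictly increasing", call. = FALSE)
  pk <- lapply(spectra, peak)
  ref <- pk[[1]]
  data.frame(
    conc_molar = conc_molar,
    peak_nm = vapply(pk, `[[`, numeric(1), "wavelength_nm"),
    peak_intensity = vapply(pk, `[[`, numeric(1), "value"),
    shift_nm = vapply(pk, `[[`, numeric(1), "wavelength_nm") - ref$wavelength_nm,
    quench = ref$value - vapply(pk, `[[`, numeric(1), "value"),
    channel = if (delta_lambda_nm == 15) "tyrosine" else "tryptophan")
}

#' Pick peaks from an excitation-emission matrix
#'
#' Finds local maxima of the EEM after classifying first-order
#' (emission = excitation) and second-order (emission = 2 x excitation)
#' Rayleigh scatter ridges.  Ridge maxima are reported separately with
#' labels `rayleigh1`/`rayleigh2`; off-ridge maxima are ranked by
#' descending intensity and labeled `peakA` (protein fluorophores),
#' `peakB` (polypeptide backbone), then `other`.
#'
#' @param grid An [eem_grid()].
#' @param mask_halfwidth_nm Half-width of each scatter ridge mask, nm
#'   (default 10, matching a 5 nm slit bandpass).
#' @return A `data.frame` with columns `excitation_nm`, `emission_nm`,
#'   `intensity`, `label`; zero rows for an all-zero grid.
#' @export
eem_peaks <- function(grid, mask_halfwidth_nm = 10) {
  stopifnot(inherits(grid, "eem_grid"))
  ex <- grid$excitation_nm
  em <- grid$emission_nm
  M <- grid$intensity
  empty <- data.frame(excitation_nm = numeric(0), emission_nm = numeric(0),
                      intensity = numeric(0), label = character(0))
  if (all(M == 0)) return(empty)
  ridge1 <- outer(ex, em, function(x, m) abs(m - x) <= mask_halfwidth_nm)
  ridge2 <- outer(ex, em, function(x, m) abs(m - 2 * x) <= mask_halfwidth_nm)
  nr <- nrow(M); nc <- ncol(M)
  is_max <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      v <- M[i, j]
      if (v <= 0) next
      nb <- M[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
      if (v >= max(nb) && sum(nb == v) == 1L) is_max[i, j] <- TRUE
    }
  }
  rows <- list()
  ridge_max <- function(mask, label) {
    vals <- M[mask]
    if (length(vals) == 0 || max(vals) <= 0) return(NULL)
    idx <- which(mask & M == max(vals), arr.ind = TRUE)[1, , drop = TRUE]
    data.frame(excitation_nm = ex[idx[1]], emission_nm = em[idx[2]],
               intensity = M[idx[1], idx[2]], label = label)
  }
  rows$r1 <- ridge_max(ridge1, "rayleigh1")
  rows$r2 <- ridge_max(ridge2 & !ridge1, "rayleigh2")
  off <- which(is_max & !ridge1 & !ridge2, arr.ind = TRUE)
  if (nrow(off) > 0) {
    vals <- M[off]
    o <- order(vals, decreasing = TRUE)
    off <- off[o, , drop = FALSE]
    labs <- c("peakA", "peakB")[seq_len(min(2, nrow(off)))]
    if (nrow(off) > 2) labs <- c(labs, rep("other", nrow(off) - 2))
    rows$off <- data.frame(excitation_nm = ex[off[, 1]],
                           emission_nm = em[off[, 2]],
                           intensity = M[off],
                           label = labs)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) empty else `rownames<-`(out, NULL)
}

#' Surface-hydrophobicity slope from an ANS titration
#'
#' Ordinary least squares of relative ANS fluorescence against protein
#' concentration; the slope S0 indexes the protein's exposed hydrophobic
#' surface.
#'
#' @param concentration Protein concentrations, strictly increasing, >= 2
#'   points.
#' @param relative_f Relative fluorescence intensities, same length.
#' @param emission_peak_nm Emission wavelength at which the intensities
#'   were read (recorded for reporting; default `NA`).
#' @return An object of class `"hydrophobicity_fit"`: `s0`, `intercept`,
#'   `r_squared`, `emission_peak_nm`.
#' @export
hydrophobicity_slope <- function(concentration, relative_f,
                                 emission_peak_nm = NA_real_) {
  if (length(concentration) != length(relative_f))
    stop("concentration and fluorescence must have the same length",
         call. = FALSE)
  if (length(concentration) < 2L)
    stop("need >= 2 points for a hydrophobicity slope", call. = FALSE)
  if (is.unsorted(concentration, strictly = TRUE))
    stop("concentrations must be strictly increasing", call. = FALSE)
  fit <- stats::lm(relative_f ~ concentration)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(r2)) r2 <- NA_real_
  structure(list(s0 = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 emission_peak_nm = emission_peak_nm),
            class = "hydrophobicity_fit")
}

#' @export
print.hydrophobicity_fit <- function(x, ...) {
  cat(sprintf("ANS hydrophobicity: S0 = %.4g, R^2 = %.4f%s\n",
              x$s0, x$r_squared,
              if (is.finite(x$emission_peak_nm))
                sprintf(" (read at %g nm)", x$emission_peak_nm) else ""))
  invisible(x)
}

#' Percent change in surface hydrophobicity between two systems
#'
#' @param reference A `"hydrophobicity_fit"` for the untreated system.
#' @param treated A `"hydrophobicity_fit"` for the treated system.
#' @return 100 * (1 - S0_treated / S0_reference): the percent drop in S0.
#' @export
hydrophobicity_change_percent <- function(reference, treated) {
  stopifnot(inherits(reference, "hydrophobicity_fit"),
            inherits(treated, "hydrophobicity_fit"))
  if (reference$s0 == 0) stop("reference slope is zero", call. = FALSE)
  100 * (1 - treated$s0 / reference$s0)
}
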