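# Mass-action equilibrium: exact bound fraction with ligand depletion,
# dissociation percentage, and nonlinear Kd fitting of dose-response data.

#' Exact bound fraction under mass action
#'
#' Solves A + B <-> AB with Kd = \[A\]\[B\]/\[AB\] exactly for the complex
#' concentration, accounting for ligand depletion: \[AB\] is the smaller
#' root of the quadratic, computed in the numerically stable form
#' 2 A B / (s + sqrt(s^2 - 4 A B)) with s = A + B + Kd.  Vectorized over
#' `B_total`.
#'
#' @param A_total Total concentration of the labeled species (protein),
#'   mol/L, >= 0.
#' @param B_total Total titrant concentration(s), mol/L, >= 0.
#' @param Kd Dissociation constant, mol/L, > 0.
#' @return A list: `bound_fraction` (of A), `free_A`, `free_B`, `complex`
#'   (all mol/L, vectorized over `B_total`).
#' @export
fraction_bound <- function(A_total, B_total, Kd) {
  if (A_total < 0 || any(B_total < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (Kd <= 0) stop("Kd must be positive", call. = FALSE)
  s <- A_total + B_total + Kd
  disc <- pmax(s^2 - 4 * A_total * B_total, 0)
  ab <- ifelse(A_total * B_total == 0, 0,
               2 * A_total * B_total / (s + sqrt(disc)))
  list(bound_fraction = if (A_total > 0) ab / A_total else rep(0, length(B_total)),
       free_A = A_total - ab,
       free_B = B_total - ab,
       complex = ab)
}

#' Dissociation percentage of the labeled species at equilibrium
#'
#' @inheritParams fraction_bound
#' @return 100 * (1 - bound fraction of A), in percent.
#' @export
dissociation_percent <- function(A_total, B_total, Kd) {
  100 * (1 - fraction_bound(A_total, B_total, Kd)$bound_fraction)
}

#' Fit a dissociation constant to a dose-response curve
#'
#' Nonlinear least squares of
#' `response = baseline + amplitude * bound_fraction(A_total, dose, Kd)`
#' using the exact (ligand-depletion) isotherm.  Kd is fitted on the log
#' scale so positivity is structural; its standard error is propagated back
#' to the natural scale.
#'
#' @param dose Strictly increasing titrant concentrations, mol/L, >= 6
#'   points.
#' @param response Thermophoresis (or other) signal, same length.
#' @param A_total Labeled-species concentration, mol/L (default 2e-7, i.e.
#'   200 nM).
#' @return An object of class `"kd_fit"`: `kd` and `kd_se` (mol/L),
#'   `baseline`, `amplitude`, `fitted`, `residuals`, `flags`.
#' @export
fit_kd <- function(dose, response, A_total = 2e-7) {
  if (length(dose) != length(response))
    stop("dose and response must have the same length", call. = FALSE)
  if (length(dose) < 6L)
    stop("need >= 6 dose points to constrain a Kd fit", call. = FALSE)
  if (is.unsorted(dose, strictly = TRUE))
    stop("doses must be strictly increasing", call. = FALSE)
  if (any(dose < 0)) stop("doses must be >= 0", call. = FALSE)
  pos <- dose[dose > 0]
  amp0 <- response[length(response)] - response[1]
  if (amp0 == 0)  # degenerate (e.g. flat) traces need a start on the
    amp0 <- max(stats::sd(response),  # response scale
                0.05 * max(abs(response)), 1e-6)
  start <- list(baseline = response[1], amplitude = amp0,
                lkd = log(sqrt(min(pos) * max(pos))))
  model <- function(baseline, amplitude, lkd)
    baseline + amplitude * fraction_bound(A_total, dose, exp(lkd))$bound_fraction
  fit <- tryCatch(
    minpack.lm::nlsLM(response ~ model(baseline, amplitude, lkd),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      r0 <- response - do.call(model, start)
      stop(sprintf("Kd fit did not converge (%s); residual norm at start %.4g",
                   conditionMessage(e), sqrt(sum(r0^2))), call. = FALSE)
    })
  cf <- stats::coef(fit)
  sm <- summary(fit)$coefficients
  kd <- exp(cf[["lkd"]])
  kd_se <- kd * sm["lkd", "Std. Error"]
  flags <- character(0)
  scale <- max(abs(response))
  if (kd <= min(pos) || kd >= max(dose) ||
      abs(cf[["amplitude"]]) < 1e-8 * scale ||
      !is.finite(kd_se) || sm["lkd", "Std. Error"] > 5) {
    flags <- c(flags, "Kd poorly constrained")
    warning("Kd poorly constrained: estimate at/beyond the dose range or response carries no binding signal",
            call. = FALSE)
  }
  structure(list(kd = kd, kd_se = unname(kd_se),
                 baseline = cf[["baseline"]], amplitude = cf[["amplitude"]],
                 A_total = A_total,
                 fitted = stats::fitted(fit),
                 residuals = stats::residuals(fit),
                 flags = flags),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("Mass-action Kd fit: Kd = %.4g +/- %.2g mol/L (%.4g +/- %.2g nM)\n",
              x$kd, x$kd_se, x$kd * 1e9, x$kd_se * 1e9))
  cat(sprintf("  baseline = %.4g, amplitude = %.4g, A_total = %.3g mol/L\n",
              x$baseline, x$amplitude, x$A_total))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Read a dose-response table
#'
#' Two delimited columns: titrant dose (mol/L) and response.  Rows are
#' sorted by dose on return.
#'
#' @param path File path.
#' @return A `data.frame` with columns `dose_molar`, `response`.
#' @export
read_dose_response <- function(path) {
  m <- parse_numeric_table(path, 2L)
  m <- m[order(m[, 1]), , drop = FALSE]
  data.frame(dose_molar = m[, 1], response = m[, 2])
}

#' Write a dose-response table
#'
#' @param dose Doses, mol/L.
#' @param response Responses, same length.
#' @param path Output file path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_dose_response <- function(dose, response, path, delim = ",") {
  stopifnot(length(dose) == length(response))
  writeLines(c(paste("dose_molar", "response", sep = delim),
               sprintf("%.17g%s%.17g", dose, delim, response)), path)
  invisible(path)
}
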