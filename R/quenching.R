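# Stern-Volmer quenching analysis and the double-logarithmic binding fit.

#' Stern-Volmer fit of a quenching titration
#'
#' Fits F0/F = 1 + Ksv\[Q\] by ordinary least squares over the nonzero
#' ligand concentrations.  The intercept is fitted free rather than pinned
#' to 1 so its deviation serves as a diagnostic; the bimolecular quenching
#' rate constant is Kq = Ksv / tau0.
#'
#' @param series A [titration_series()] with at least three nonzero
#'   concentrations.
#' @param tau0 Unquenched fluorophore lifetime in seconds (default 1e-8 s,
#'   the canonical biomolecule value).
#' @return An object of class `"quench_result"`: `ksv` (L/mol), `kq`
#'   (L/mol/s), `intercept`, `r_squared`, `temperature_K`, `tau0`, and a
#'   character vector `flags` (possibly empty) carrying `"no quenching"`
#'   when the fitted slope is not positive and `"intercept deviates from 1"`
#'   when |intercept - 1| > 0.05.
#' @export
stern_volmer_fit <- function(series, tau0 = 1e-8) {
  stopifnot(inherits(series, "titration_series"))
  if (!is.numeric(tau0) || length(tau0) != 1L || tau0 <= 0)
    stop("tau0 must be a single positive number (seconds)", call. = FALSE)
  f <- series$intensity
  if (any(f == 0)) stop("zero intensity in titration series", call. = FALSE)
  f0 <- f[1]
  nz <- series$conc_molar > 0
  if (sum(nz) < 3L)
    stop("need >= 3 nonzero concentrations for a Stern-Volmer fit",
         call. = FALSE)
  x <- series$conc_molar[nz]
  y <- f0 / f[nz]
  fit <- stats::lm(y ~ x)
  ksv <- unname(stats::coef(fit)[2])
  b0 <- unname(stats::coef(fit)[1])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(r2)) r2 <- NA_real_
  flags <- character(0)
  if (ksv <= 0) flags <- c(flags, "no quenching")
  if (abs(b0 - 1) > 0.05) flags <- c(flags, "intercept deviates from 1")
  structure(list(ksv = ksv, kq = ksv / tau0, intercept = b0,
                 r_squared = r2, temperature_K = series$temperature_K,
                 tau0 = tau0, flags = flags),
            class = "quench_result")
}

#' @export
print.quench_result <- function(x, ...) {
  cat(sprintf("Stern-Volmer fit at %g K: Ksv = %.4g L/mol, Kq = %.4g L/mol/s, intercept = %.4f, R^2 = %.4f\n",
              x$temperature_K, x$ksv, x$kq, x$intercept, x$r_squared))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Classify the quenching mechanism from temperature dependence
#'
#' Static (complex-forming) quenching shows a Stern-Volmer constant that
#' falls with temperature and a bimolecular rate constant above the maximum
#' diffusion-collision limit; dynamic (collisional) quenching shows the
#' opposite pattern.  Anything else is reported as indeterminate with a
#' reason.
#'
#' @param results A list of `"quench_result"` objects at two or more
#'   distinct temperatures.
#' @param diffusion_limit Maximum diffusion-collision quenching rate
#'   constant in L/mol/s (default 2.0e10).
#' @return A list with `mechanism` (one of `"static"`, `"dynamic"`,
#'   `"indeterminate"`) and `reason`.
#' @export
classify_mechanism <- function(results, diffusion_limit = 2.0e10) {
  if (inherits(results, "quench_result")) results <- list(results)
  stopifnot(all(vapply(results, inherits, logical(1), "quench_result")))
  temps <- vapply(results, `[[`, numeric(1), "temperature_K")
  if (length(unique(temps)) < 2L)
    stop("need >=2 temperatures to classify a quenching mechanism",
         call. = FALSE)
  o <- order(temps)
  ksv <- vapply(results, `[[`, numeric(1), "ksv")[o]
  kq <- vapply(results, `[[`, numeric(1), "kq")[o]
  decreasing <- all(diff(ksv) < 0)
  increasing <- all(diff(ksv) > 0)
  above <- all(kq > diffusion_limit)
  below <- all(kq <= diffusion_limit)
  if (decreasing && above) {
    mech <- "static"
    reason <- "Ksv decreases with temperature and all Kq exceed the diffusion-collision limit"
  } else if (increasing && below) {
    mech <- "dynamic"
    reason <- "Ksv increases with temperature and all Kq are within the diffusion-collision limit"
  } else {
    mech <- "indeterminate"
    reason <- sprintf(
      "Ksv trend (%s) and Kq magnitude (%s the %.3g L/mol/s limit) do not jointly match either mechanism",
      if (decreasing) "decreasing" else if (increasing) "increasing" else "non-monotone",
      if (above) "all above" else if (below) "all within" else "mixed about",
      diffusion_limit)
  }
  list(mechanism = mech, reason = reason)
}

#' Double-logarithmic binding fit
#'
#' Fits log10\[(F0 - F)/F\] = log10 Ka + n log10\[Q\] by ordinary least
#' squares over the nonzero concentrations, giving the association constant
#' Ka (from the intercept) and the apparent number of binding sites n (the
#' slope).  Points with F >= F0 carry no quenching signal and are dropped
#' with a warning.
#'
#' @param series A [titration_series()].
#' @return An object of class `"binding_fit"`: `ka` (L/mol), `n_sites`,
#'   `r_squared`, `temperature_K`, `n_points` used.
#' @export
double_log_fit <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  f0 <- series$intensity[1]
  nz <- which(series$conc_molar > 0)
  f <- series$intensity[nz]
  q <- series$conc_molar[nz]
  usable <- f < f0
  if (any(!usable))
    warning(sum(!usable), " point(s) with F >= F0 dropped from double-log fit",
            call. = FALSE)
  if (sum(usable) < 3L)
    stop("fewer than 3 usable points (F < F0) for the double-log fit",
         call. = FALSE)
  x <- log10(q[usable])
  y <- log10((f0 - f[usable]) / f[usable])
  fit <- stats::lm(y ~ x)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(r2)) r2 <- NA_real_
  structure(list(ka = 10^unname(stats::coef(fit)[1]),
                 n_sites = unname(stats::coef(fit)[2]),
                 r_squared = r2,
                 temperature_K = series$temperature_K,
                 n_points = sum(usable)),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Double-log binding fit at %g K: Ka = %.4g L/mol, n = %.3f, R^2 = %.4f (%d points)\n",
              x$temperature_K, x$ka, x$n_sites, x$r_squared, x$n_points))
  invisible(x)
}

#' Tabulate quenching results
#'
#' Mirrors the conventional report layout (temperature, Ksv, Kq, intercept,
#' R-squared) as a data frame ready for delimited-text export.
#'
#' @param results A list of `"quench_result"` objects.
#' @param compound Compound label column.
#' @return A `data.frame`.
#' @export
quench_table <- function(results, compound = "") {
  if (inherits(results, "quench_result")) results <- list(results)
  data.frame(
    compound = compound,
    temperature_K = vapply(results, `[[`, numeric(1), "temperature_K"),
    ksv_L_per_mol = vapply(results, `[[`, numeric(1), "ksv"),
    kq_L_per_mol_s = vapply(results, `[[`, numeric(1), "kq"),
    intercept = vapply(results, `[[`, numeric(1), "intercept"),
    r_squared = vapply(results, `[[`, numeric(1), "r_squared"),
    flags = vapply(results, function(r) paste(r$flags, collapse = "; "),
                   character(1)))
}
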