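# Domain containers and delimited-text I/O for wavelength-resolved data.

#' Construct a spectrum
#'
#' A spectrum is one wavelength-indexed trace: fluorescence emission in
#' arbitrary units, absorbance in AU, or circular dichroism in millidegrees,
#' according to `kind`.
#'
#' @param wavelength_nm Numeric vector of wavelengths in nm.  Need not be
#'   sorted on input; it is sorted on construction.  Duplicates are rejected.
#' @param value Numeric vector of the same length as `wavelength_nm`.
#' @param kind One of `"emission"`, `"absorbance"`, `"cd"`.  Absorbance
#'   values must be non-negative.
#' @param units Optional unit string carried along for reporting (e.g.
#'   `"L/mol/cm"` for a molar-absorptivity trace).
#' @return An object of class `"spectrum"`: a list with elements
#'   `wavelength_nm`, `value`, `kind`, `units`.
#' @export
spectrum <- function(wavelength_nm, value,
                     kind = c("emission", "absorbance", "cd"),
                     units = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(wavelength_nm) || !is.numeric(value))
    stop("wavelengths and values must be numeric", call. = FALSE)
  if (length(wavelength_nm) != length(value))
    stop("wavelengths and values must have the same length", call. = FALSE)
  if (length(wavelength_nm) < 1L)
    stop("a spectrum needs at least one point", call. = FALSE)
  if (anyNA(wavelength_nm) || anyNA(value) ||
      any(!is.finite(wavelength_nm)) || any(!is.finite(value)))
    stop("spectrum contains non-finite values", call. = FALSE)
  o <- order(wavelength_nm)
  wavelength_nm <- wavelength_nm[o]
  value <- value[o]
  if (anyDuplicated(wavelength_nm))
    stop("duplicate wavelengths: ",
         paste(unique(wavelength_nm[duplicated(wavelength_nm)]), collapse = ", "),
         call. = FALSE)
  if (kind == "absorbance" && any(value < 0))
    stop("absorbance values must be >= 0", call. = FALSE)
  structure(list(wavelength_nm = wavelength_nm, value = value,
                 kind = kind, units = units),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d points, %.4g-%.4g nm>\n",
              x$kind, length(x$wavelength_nm),
              min(x$wavelength_nm), max(x$wavelength_nm)))
  invisible(x)
}

#' @export
length.spectrum <- function(x) length(x$wavelength_nm)

#' Construct a titration series
#'
#' Fluorescence intensities recorded across increasing ligand concentrations
#' at one temperature.  The first concentration must be exactly zero: its
#' intensity is the ligand-free anchor F0 used by every quenching fit.
#'
#' @param conc_molar Ligand concentrations in mol/L, strictly increasing,
#'   first entry exactly 0.
#' @param intensity Positive fluorescence intensities (a.u.), same length.
#' @param temperature_K Temperature of the series in kelvin.
#' @param label Optional text label.
#' @return An object of class `"titration_series"`.
#' @export
titration_series <- function(conc_molar, intensity, temperature_K,
                             label = "") {
  if (!is.numeric(conc_molar) || !is.numeric(intensity))
    stop("concentrations and intensities must be numeric", call. = FALSE)
  if (length(conc_molar) != length(intensity))
    stop("concentrations and intensities must have the same length",
         call. = FALSE)
  if (length(conc_molar) < 2L)
    stop("a titration series needs at least two points", call. = FALSE)
  if (conc_molar[1] != 0)
    stop("no F0 anchor: first concentration must be exactly 0", call. = FALSE)
  if (is.unsorted(conc_molar, strictly = TRUE))
    stop("concentrations must be strictly increasing", call. = FALSE)
  if (any(!is.finite(intensity)) || any(intensity <= 0))
    stop("all intensities must be finite and > 0", call. = FALSE)
  if (!is.numeric(temperature_K) || length(temperature_K) != 1L ||
      temperature_K <= 0)
    stop("temperature_K must be a single positive number", call. = FALSE)
  structure(list(conc_molar = conc_molar, intensity = intensity,
                 temperature_K = temperature_K, label = as.character(label)),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration series%s: %d points, %.4g-%.4g mol/L, %g K, F0 = %.4g>\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$conc_molar), min(x$conc_molar), max(x$conc_molar),
              x$temperature_K, x$intensity[1]))
  invisible(x)
}

#' Construct an excitation-emission matrix grid
#'
#' @param excitation_nm Increasing excitation wavelengths (rows).
#' @param emission_nm Increasing emission wavelengths (columns).
#' @param intensity Matrix of fluorescence intensities with dimensions
#'   `length(excitation_nm) x length(emission_nm)`, all finite.
#' @return An object of class `"eem_grid"`.
#' @export
eem_grid <- function(excitation_nm, emission_nm, intensity) {
  if (is.unsorted(excitation_nm, strictly = TRUE) ||
      is.unsorted(emission_nm, strictly = TRUE))
    stop("EEM axes must be strictly increasing", call. = FALSE)
  intensity <- as.matrix(intensity)
  if (nrow(intensity) != length(excitation_nm) ||
      ncol(intensity) != length(emission_nm))
    stop("intensity matrix dimensions must match the axis lengths",
         call. = FALSE)
  if (any(!is.finite(intensity)))
    stop("EEM intensities must all be finite", call. = FALSE)
  structure(list(excitation_nm = excitation_nm, emission_nm = emission_nm,
                 intensity = intensity),
            class = "eem_grid")
}

#' @export
print.eem_grid <- function(x, ...) {
  cat(sprintf("<EEM grid: %d excitation x %d emission>\n",
              length(x$excitation_nm), length(x$emission_nm)))
  invisible(x)
}

# --- delimited-text plumbing ------------------------------------------------

# Sniffs the field delimiter of one line among comma/tab/semicolon.
# Mixed delimiters on the same line are rejected loudly rather than guessed.
sniff_delim <- function(line, path) {
  cands <- c(",", "\t", ";")
  present <- vapply(cands, function(d) grepl(d, line, fixed = TRUE), logical(1))
  if (sum(present) > 1L)
    stop("mixed delimiters on first line of ", path, call. = FALSE)
  if (sum(present) == 0L)
    stop("no recognised delimiter (comma/tab/semicolon) in ", path,
         call. = FALSE)
  cands[present]
}

# Line-wise numeric table parser so errors can name the offending line.
# Returns a numeric matrix with ncol columns; skips an optional header.
parse_numeric_table <- function(path, ncol_expected) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("empty file: ", path, call. = FALSE)
  delim <- sniff_delim(lines[keep[1]], path)
  rows <- strsplit(trimws(lines[keep]), delim, fixed = TRUE)
  first <- suppressWarnings(as.numeric(rows[[1]]))
  has_header <- anyNA(first)
  data_idx <- if (has_header) keep[-1] else keep
  data_rows <- if (has_header) rows[-1] else rows
  if (length(data_rows) == 0L)
    stop("no data rows in ", path, call. = FALSE)
  out <- matrix(NA_real_, nrow = length(data_rows), ncol = ncol_expected)
  for (i in seq_along(data_rows)) {
    f <- trimws(data_rows[[i]])
    if (length(f) != ncol_expected)
      stop(sprintf("line %d of %s: expected %d fields, found %d",
                   data_idx[i], path, ncol_expected, length(f)),
           call. = FALSE)
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v))
      stop(sprintf("line %d of %s: non-numeric value '%s'",
                   data_idx[i], path, f[which(is.na(v))[1]]),
           call. = FALSE)
    out[i, ] <- v
  }
  out
}

#' Read a spectrum from delimited text
#'
#' Expects two columns (wavelength nm, value); the delimiter is sniffed
#' among comma, tab and semicolon, and a single header line is skipped if
#' present.  Rows are sorted by wavelength on return; duplicated wavelengths
#' are an error.
#'
#' @param path File path.
#' @param kind Spectrum kind; see [spectrum()].
#' @inheritParams spectrum
#' @return A `"spectrum"`.
#' @export
read_spectrum <- function(path, kind = c("emission", "absorbance", "cd"),
                          units = NULL) {
  kind <- match.arg(kind)
  m <- parse_numeric_table(path, 2L)
  if (nrow(m) < 2L)
    stop("spectrum in ", path, " has fewer than 2 points", call. = FALSE)
  spectrum(m[, 1], m[, 2], kind = kind, units = units)
}

#' Write a spectrum to delimited text
#'
#' Values are written at full double precision so that
#' `read_spectrum(write_spectrum(x))` is the identity.
#'
#' @param x A `"spectrum"`.
#' @param path Output file path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(x, path, delim = ",") {
  stopifnot(inherits(x, "spectrum"))
  lines <- c(paste("wavelength_nm", "value", sep = delim),
             sprintf("%.17g%s%.17g", x$wavelength_nm, delim, x$value))
  writeLines(lines, path)
  invisible(path)
}

#' Read a long-format titration table
#'
#' Expects three columns (ligand concentration mol/L, temperature K,
#' intensity a.u.), one series per distinct temperature.  Each series must
#' contain a zero-concentration row, which anchors F0.
#'
#' @param path File path.
#' @return A list of [titration_series()], ordered by temperature.
#' @export
read_titration_table <- function(path) {
  m <- parse_numeric_table(path, 3L)
  temps <- sort(unique(m[, 2]))
  out <- lapply(temps, function(tt) {
    sub <- m[m[, 2] == tt, , drop = FALSE]
    sub <- sub[order(sub[, 1]), , drop = FALSE]
    if (sub[1, 1] != 0)
      stop("no F0 anchor: series at ", tt,
           " K lacks a zero-concentration row", call. = FALSE)
    titration_series(sub[, 1], sub[, 3], temperature_K = tt,
                     label = sprintf("%g K", tt))
  })
  names(out) <- as.character(temps)
  out
}

#' Write titration series to a long-format table
#'
#' @param series A `"titration_series"` or list of them.
#' @param path Output file path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_titration_table <- function(series, path, delim = ",") {
  if (inherits(series, "titration_series")) series <- list(series)
  lines <- paste("conc_molar", "temperature_K", "intensity", sep = delim)
  for (s in series) {
    stopifnot(inherits(s, "titration_series"))
    lines <- c(lines, sprintf("%.17g%s%.17g%s%.17g",
                              s$conc_molar, delim, s$temperature_K,
                              delim, s$intensity))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an excitation-emission matrix file
#'
#' Layout: first row holds the emission axis (first cell is a corner
#' placeholder), first column the excitation axis, body the intensities.
#'
#' @param path File path.
#' @return An `"eem_grid"`.
#' @export
read_eem <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  delim <- sniff_delim(lines[1], path)
  rows <- strsplit(trimws(lines), delim, fixed = TRUE)
  em <- as.numeric(rows[[1]][-1])
  body <- do.call(rbind, lapply(rows[-1], function(f) as.numeric(f)))
  if (anyNA(em) || anyNA(body))
    stop("non-numeric entries in EEM file ", path, call. = FALSE)
  eem_grid(body[, 1], em, body[, -1, drop = FALSE])
}

#' Write an excitation-emission matrix file
#'
#' @param x An `"eem_grid"`.
#' @param path Output file path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_eem <- function(x, path, delim = ",") {
  stopifnot(inherits(x, "eem_grid"))
  header <- paste(c("ex_nm", sprintf("%.17g", x$emission_nm)),
                  collapse = delim)
  body <- vapply(seq_along(x$excitation_nm), function(i) {
    paste(sprintf("%.17g", c(x$excitation_nm[i], x$intensity[i, ])),
          collapse = delim)
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Locate the emission peak of a spectrum
#'
#' Returns the coordinates of the global maximum; ties are broken toward the
#' smaller wavelength.  A completely flat trace returns its first point with
#' `degenerate = TRUE`.
#'
#' @param x A `"spectrum"`.
#' @param ... Unused.
#' @return A list with `wavelength_nm`, `value`, `degenerate`.
#' @export
peak <- function(x, ...) UseMethod("peak")

#' @rdname peak
#' @export
peak.spectrum <- function(x, ...) {
  i <- which.max(x$value)
  list(wavelength_nm = x$wavelength_nm[i],
       value = x$value[i],
       degenerate = length(unique(x$value)) == 1L && length(x$value) > 1L)
}
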