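#' Measurement metadata for a recorded spectrum
#'
#' Bundles the experimental conditions a spectrum was recorded under. The
#' concentration and path length feed the Beer-Lambert extinction
#' coefficient; the excitation wavelength and refractive index feed the
#' relative quantum-yield calculation.
#'
#' @param solvent Solvent name (character), or `NA`.
#' @param concentration_M Molar concentration of the absorbing species
#'   (mol L^-1); must be positive when supplied.
#' @param path_length_cm Optical path length (cm); must be positive when
#'   supplied.
#' @param excitation_nm Fluorescence excitation wavelength (nm), or `NA`.
#' @param refractive_index Solvent refractive index (dimensionless), or `NA`.
#' @return An object of class `measurement_meta`.
#' @examples
#' measurement_meta("acetonitrile", concentration_M = 2e-5,
#'                  path_length_cm = 1, excitation_nm = 340)
#' @export
measurement_meta <- function(solvent = NA_character_,
                             concentration_M = NA_real_,
                             path_length_cm = NA_real_,
                             excitation_nm = NA_real_,
                             refractive_index = NA_real_) {
  if (!is.na(concentration_M) && concentration_M <= 0)
    photodft_abort("photodft_invalid_input", "concentration_M must be > 0")
  if (!is.na(path_length_cm) && path_length_cm <= 0)
    photodft_abort("photodft_invalid_input", "path_length_cm must be > 0")
  structure(
    list(solvent = as.character(solvent),
         concentration_M = as.numeric(concentration_M),
         path_length_cm = as.numeric(path_length_cm),
         excitation_nm = as.numeric(excitation_nm),
         refractive_index = as.numeric(refractive_index)),
    class = "measurement_meta"
  )
}

#' Construct and validate a spectrum
#'
#' The unit of all spectral arithmetic in the package: a strictly increasing
#' wavelength grid with one signal value per grid point. `kind` records what
#' the signal means -- absorbance (dimensionless optical density), emission
#' (arbitrary counts) or a theoretical (broadened stick) curve.
#'
#' Absorbance spectra may contain slightly negative baseline noise; values
#' below `-baseline_tol` are rejected.
#'
#' @param wavelengths_nm Numeric vector, strictly increasing, length >= 2.
#' @param signal Numeric vector, same length, all finite.
#' @param kind One of `"absorbance"`, `"emission"`, `"theoretical"`.
#' @param meta A [measurement_meta()] object.
#' @param baseline_tol Tolerance (absorbance units) for negative baseline
#'   noise in absorbance spectra. Default 0.005.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(wavelengths_nm, signal,
                     kind = c("absorbance", "emission", "theoretical"),
                     meta = measurement_meta(), baseline_tol = 0.005) {
  kind <- match.arg(kind)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  signal <- as.numeric(signal)
  if (length(wavelengths_nm) < 2L)
    photodft_abort("photodft_too_few_rows",
                   "a spectrum needs at least 2 points")
  if (length(signal) != length(wavelengths_nm))
    photodft_abort("photodft_invalid_input",
                   "signal and wavelengths_nm must have the same length")
  if (!all(is.finite(wavelengths_nm)) || !all(is.finite(signal)))
    photodft_abort("photodft_invalid_input",
                   "wavelengths and signal must all be finite")
  if (any(diff(wavelengths_nm) <= 0))
    photodft_abort("photodft_duplicate_wavelength",
                   "wavelengths_nm must be strictly increasing (no duplicates)")
  if (kind == "absorbance" && any(signal < -baseline_tol))
    photodft_abort(
      "photodft_invalid_input",
      sprintf("absorbance below -%g: not baseline noise", baseline_tol))
  if (!inherits(meta, "measurement_meta"))
    photodft_abort("photodft_invalid_input",
                   "meta must be a measurement_meta object")
  structure(list(wavelengths_nm = wavelengths_nm, signal = signal,
                 kind = kind, meta = meta),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d points, %.2f-%.2f nm>\n",
              x$kind, length(x$wavelengths_nm),
              min(x$wavelengths_nm), max(x$wavelengths_nm)))
  invisible(x)
}

#' Read a two-column spectrum from CSV
#'
#' Dialect: comma-separated `wavelength_nm,value` rows; an optional header
#' line; lines starting with `#` and blank lines are ignored. Rows are
#' sorted by wavelength on input; duplicated wavelengths are rejected
#' because they make interpolation ambiguous.
#'
#' @param path Path to the CSV file.
#' @param kind Spectrum kind, see [spectrum()].
#' @param meta Measurement metadata attached to the result.
#' @param baseline_tol Passed to [spectrum()].
#' @param quiet Suppress the one-line info message describing what was read.
#' @return A validated [spectrum()].
#' @export
read_spectrum_csv <- function(path, kind = c("absorbance", "emission",
                                             "theoretical"),
                              meta = measurement_meta(),
                              baseline_tol = 0.005, quiet = FALSE) {
  kind <- match.arg(kind)
  if (!file.exists(path))
    photodft_abort("photodft_missing_file",
                   sprintf("spectrum file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2L)
    photodft_abort("photodft_too_few_rows",
                   sprintf("'%s': need at least 2 data rows", path))
  cells <- strsplit(lines, ",", fixed = TRUE)
  bad_shape <- vapply(cells, length, 1L) < 2L
  if (any(bad_shape))
    photodft_abort("photodft_bad_numeric",
                   sprintf("'%s': row without two comma-separated columns", path))
  first <- suppressWarnings(as.numeric(cells[[1L]][1:2]))
  has_header <- any(is.na(first))
  if (has_header) cells <- cells[-1L]
  if (length(cells) < 2L)
    photodft_abort("photodft_too_few_rows",
                   sprintf("'%s': need at least 2 data rows", path))
  w <- suppressWarnings(as.numeric(vapply(cells, `[`, "", 1L)))
  s <- suppressWarnings(as.numeric(vapply(cells, `[`, "", 2L)))
  if (anyNA(w) || anyNA(s)) {
    row <- which(is.na(w) | is.na(s))[1L]
    photodft_abort("photodft_bad_numeric",
                   sprintf("'%s': non-numeric cell in data row %d", path, row))
  }
  if (anyDuplicated(w))
    photodft_abort("photodft_duplicate_wavelength",
                   sprintf("'%s': duplicate wavelength %g", path,
                           w[duplicated(w)][1L]))
  ord <- order(w)
  sp <- spectrum(w[ord], s[ord], kind = kind, meta = meta,
                 baseline_tol = baseline_tol)
  if (!quiet)
    message(sprintf("read %d-point %s spectrum (%.2f-%.2f nm) from '%s'",
                    length(w), kind, min(w), max(w), path))
  sp
}

#' Write a spectrum to CSV
#'
#' Values are written with full double precision so that reading the file
#' back reproduces the spectrum bit-for-bit.
#'
#' @param sp A [spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(sp, path) {
  stopifnot(inherits(sp, "spectrum"))
  lines <- c("wavelength_nm,value",
             sprintf("%.17g,%.17g", sp$wavelengths_nm, sp$signal))
  writeLines(lines, path)
  invisible(path)
}

#' Read measurement defaults from a YAML config
#'
#' Recognized keys: `solvent`, `concentration_M`, `path_length_cm`,
#' `excitation_nm`, `refractive_index`. Missing keys fall back to the
#' [measurement_meta()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A [measurement_meta()].
#' @export
read_meta_config <- function(path) {
  if (!file.exists(path))
    photodft_abort("photodft_missing_file",
                   sprintf("config file not found: '%s'", path))
  cfg <- yaml::read_yaml(path)
  pick <- function(key, default) if (!is.null(cfg[[key]])) cfg[[key]] else default
  measurement_meta(
    solvent = pick("solvent", NA_character_),
    concentration_M = pick("concentration_M", NA_real_),
    path_length_cm = pick("path_length_cm", NA_real_),
    excitation_nm = pick("excitation_nm", NA_real_),
    refractive_index = pick("refractive_index", NA_real_)
  )
}

#' Centered moving-average smoothing
#'
#' Deterministic pre-filter for peak picking on noisy spectra. The window
#' must be odd; the ends of the grid are padded by replicating the first
#' and last samples so the output has the same length and no phase shift.
#'
#' @param sp A [spectrum()].
#' @param window Odd integer window width (points); `1` is a no-op.
#' @return A smoothed [spectrum()].
#' @export
smooth_spectrum <- function(sp, window) {
  stopifnot(inherits(sp, "spectrum"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    photodft_abort("photodft_invalid_input",
                   "smoothing window must be an odd positive integer")
  if (window == 1L) return(sp)
  half <- window %/% 2L
  y <- sp$signal
  padded <- c(rep(y[1L], half), y, rep(y[length(y)], half))
  sm <- stats::filter(padded, rep(1 / window, window), sides = 2)
  sm <- as.numeric(sm)[(half + 1L):(half + length(y))]
  out <- sp
  out$signal <- sm
  out
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; the new grid must lie inside the original range
#' (no extrapolation, ever).
#'
#' @param sp A [spectrum()].
#' @param new_grid_nm Strictly increasing wavelengths (nm) inside the
#'   current range.
#' @return A [spectrum()] on `new_grid_nm`.
#' @export
resample_spectrum <- function(sp, new_grid_nm) {
  stopifnot(inherits(sp, "spectrum"))
  rng <- range(sp$wavelengths_nm)
  if (min(new_grid_nm) < rng[1L] || max(new_grid_nm) > rng[2L])
    photodft_abort("photodft_out_of_range",
                   "new grid extends beyond the recorded range")
  s <- stats::approx(sp$wavelengths_nm, sp$signal, xout = new_grid_nm)$y
  spectrum(new_grid_nm, s, kind = sp$kind, meta = sp$meta,
           baseline_tol = Inf)
}

# Subset a spectrum to a wavelength interval, erroring on an empty cut.
subset_to_window <- function(sp, window, min_points = 1L,
                             what = "window") {
  keep <- sp$wavelengths_nm >= window[1L] & sp$wavelengths_nm <= window[2L]
  if (sum(keep) < min_points)
    photodft_abort("photodft_empty_window",
                   sprintf("%s [%g, %g] intersects the grid in %d point(s); need >= %d",
                           what, window[1L], window[2L], sum(keep), min_points))
  list(w = sp$wavelengths_nm[keep], s = sp$signal[keep])
}
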