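#' Beer-Lambert molar extinction coefficient
#'
#' epsilon = A / (c * l): absorbance per unit concentration and path
#' length, in M^-1 cm^-1.
#'
#' @param absorbance Absorbance (dimensionless), >= 0.
#' @param concentration_M Molar concentration (mol L^-1), > 0.
#' @param path_length_cm Path length (cm), > 0.
#' @return The molar extinction coefficient (M^-1 cm^-1).
#' @examples
#' molar_extinction(0.35, 2e-5, 1)  # 17500
#' @export
molar_extinction <- function(absorbance, concentration_M, path_length_cm) {
  if (!is.numeric(concentration_M) || !is.numeric(path_length_cm) ||
      any(!is.finite(concentration_M)) || any(!is.finite(path_length_cm)) ||
      any(concentration_M <= 0) || any(path_length_cm <= 0))
    photodft_abort("photodft_beer_lambert",
                   "invalid Beer-Lambert parameters: concentration and path length must be > 0")
  if (any(!is.finite(absorbance)) || any(absorbance < 0))
    photodft_abort("photodft_beer_lambert",
                   "invalid Beer-Lambert parameters: absorbance must be >= 0")
  absorbance / (concentration_M * path_length_cm)
}

#' Stokes shift in wavenumbers
#'
#' Signed energy separation between absorption and emission maxima,
#' `1e7 * (1/lambda_abs - 1/lambda_emi)` with wavelengths in nm and the
#' result in cm^-1. Positive when emission is red-shifted relative to
#' absorption.
#'
#' @param lambda_abs_nm Absorption maximum (nm), > 0.
#' @param lambda_emi_nm Emission maximum (nm), > 0.
#' @return Stokes shift (cm^-1). Vectorized.
#' @examples
#' stokes_shift_wavenumber(337.83, 428.02)  # ~6237 cm^-1
#' @export
stokes_shift_wavenumber <- function(lambda_abs_nm, lambda_emi_nm) {
  if (any(!is.finite(lambda_abs_nm)) || any(!is.finite(lambda_emi_nm)) ||
      any(lambda_abs_nm <= 0) || any(lambda_emi_nm <= 0))
    photodft_abort("photodft_nonpositive_wavelength",
                   "wavelengths must be positive")
  1e7 * (1 / lambda_abs_nm - 1 / lambda_emi_nm)
}

#' Quantum-yield reference standard
#'
#' Holds the reference-side quantities of the comparative quantum-yield
#' method: the literature yield, the absorbance at the excitation
#' wavelength, the integrated emission area, and the solvent refractive
#' index. The conventional standard for ~340 nm excitation is quinine
#' sulfate in 0.5 M H2SO4, phi = 0.54.
#'
#' @param phi_ref Reference quantum yield, in (0, 1].
#' @param absorbance_ref Reference absorbance at the excitation wavelength,
#'   > 0.
#' @param integrated_emission_ref Reference integrated emission area
#'   (signal * nm), > 0.
#' @param refractive_index_ref Reference solvent refractive index, > 0.
#'   Default 1.346 (dilute aqueous H2SO4).
#' @param label Free-text label.
#' @return An object of class `quantum_yield_reference`.
#' @export
quantum_yield_reference <- function(phi_ref = 0.54, absorbance_ref,
                                    integrated_emission_ref,
                                    refractive_index_ref = 1.346,
                                    label = "quinine sulfate / 0.5 M H2SO4") {
  stopifnot_scalar_number(phi_ref, "phi_ref")
  stopifnot_scalar_number(absorbance_ref, "absorbance_ref")
  stopifnot_scalar_number(integrated_emission_ref, "integrated_emission_ref")
  stopifnot_scalar_number(refractive_index_ref, "refractive_index_ref")
  if (phi_ref <= 0 || phi_ref > 1)
    photodft_abort("photodft_invalid_input", "phi_ref must be in (0, 1]")
  if (absorbance_ref <= 0 || integrated_emission_ref <= 0 ||
      refractive_index_ref <= 0)
    photodft_abort("photodft_invalid_input",
                   "reference absorbance, emission area and refractive index must be > 0")
  structure(list(phi_ref = phi_ref, absorbance_ref = absorbance_ref,
                 integrated_emission_ref = integrated_emission_ref,
                 refractive_index_ref = refractive_index_ref,
                 label = label),
            class = "quantum_yield_reference")
}

#' Relative fluorescence quantum yield
#'
#' Comparative (single-point) method against a reference standard:
#'
#'   phi = phi_R * (A_R / A) * (I / I_R) * (n^2 / n_R^2)
#'
#' where A is the absorbance at the excitation wavelength, I the
#' integrated emission intensity and n the solvent refractive index, with
#' R-subscripted quantities from the reference. Values above 1 indicate a
#' measurement or bookkeeping error; they are returned as-is with a
#' warning rather than clamped, so the problem surfaces.
#'
#' @param integrated_emission Sample integrated emission area
#'   (signal * nm), > 0.
#' @param absorbance_at_excitation Sample absorbance at the excitation
#'   wavelength, > 0.
#' @param refractive_index Sample solvent refractive index, > 0.
#' @param reference A [quantum_yield_reference()].
#' @return The relative quantum yield (dimensionless).
#' @export
relative_quantum_yield <- function(integrated_emission,
                                   absorbance_at_excitation,
                                   refractive_index, reference) {
  stopifnot(inherits(reference, "quantum_yield_reference"))
  stopifnot_scalar_number(integrated_emission, "integrated_emission")
  stopifnot_scalar_number(absorbance_at_excitation, "absorbance_at_excitation")
  stopifnot_scalar_number(refractive_index, "refractive_index")
  if (integrated_emission <= 0 || absorbance_at_excitation <= 0 ||
      refractive_index <= 0)
    photodft_abort("photodft_nonpositive_input",
                   "quantum yield inputs must be positive")
  phi <- reference$phi_ref *
    (reference$absorbance_ref / absorbance_at_excitation) *
    (integrated_emission / reference$integrated_emission_ref) *
    (refractive_index^2 / reference$refractive_index_ref^2)
  if (phi > 1)
    photodft_warn("photodft_phi_above_one",
                  sprintf("relative quantum yield %.4g exceeds 1; check absorbances and areas",
                          phi))
  phi
}

#' Pipeline configuration for compound summaries
#'
#' @param smooth_window Odd moving-average width (points) applied before
#'   peak picking, or `NULL` for none. Peak *positions* come from the
#'   smoothed signal; absorbances, heights and areas are always taken from
#'   the raw signal.
#' @param abs_window,emi_window Optional wavelength windows (nm) passed to
#'   [find_lambda_max()] for the absorption and emission peak searches.
#' @return A list of class `summary_config`.
#' @export
summary_config <- function(smooth_window = NULL, abs_window = NULL,
                           emi_window = NULL) {
  structure(list(smooth_window = smooth_window, abs_window = abs_window,
                 emi_window = emi_window),
            class = "summary_config")
}

#' Photophysical summary of one compound
#'
#' Runs the full single-compound pipeline: band maxima from
#' [find_lambda_max()] (optionally after smoothing), the molar extinction
#' coefficient from the absorbance at the absorption maximum via
#' [molar_extinction()] using the concentration and path length in the
#' absorbance spectrum's metadata, the Stokes shift from the two maxima,
#' and the relative quantum yield from the absorbance at the excitation
#' wavelength and the integrated emission area.
#'
#' The excitation wavelength is taken from the emission spectrum's
#' metadata (falling back to the absorbance spectrum's); the sample
#' refractive index from the emission metadata, falling back to the
#' reference's (ratio 1) when absent.
#'
#' @param abs_spectrum Absorbance [spectrum()]; its metadata must carry
#'   `concentration_M` and `path_length_cm`.
#' @param emi_spectrum Emission [spectrum()].
#' @param reference A [quantum_yield_reference()].
#' @param compound_id Identifier for the output row.
#' @param config A [summary_config()].
#' @return A one-row `data.frame` (class `photophysical_summary`) with
#'   columns `compound_id`, `lambda_abs_nm`, `lambda_emi_nm`, `epsilon`,
#'   `stokes_shift_wavenumber`, `quantum_yield`.
#' @export
summarize_compound <- function(abs_spectrum, emi_spectrum, reference,
                               compound_id = "", config = summary_config()) {
  stopifnot(inherits(abs_spectrum, "spectrum"),
            inherits(emi_spectrum, "spectrum"),
            inherits(reference, "quantum_yield_reference"))
  if (abs_spectrum$kind != "absorbance")
    photodft_abort("photodft_invalid_input",
                   "abs_spectrum must have kind 'absorbance'")
  if (emi_spectrum$kind != "emission")
    photodft_abort("photodft_invalid_input",
                   "emi_spectrum must have kind 'emission'")
  excitation <- emi_spectrum$meta$excitation_nm
  if (is.na(excitation)) excitation <- abs_spectrum$meta$excitation_nm
  if (is.na(excitation))
    photodft_abort("photodft_invalid_input",
                   "excitation wavelength missing from measurement metadata")
  conc <- abs_spectrum$meta$concentration_M
  path <- abs_spectrum$meta$path_length_cm
  if (is.na(conc) || is.na(path))
    photodft_abort("photodft_invalid_input",
                   "absorbance metadata must carry concentration_M and path_length_cm")
  n_sample <- emi_spectrum$meta$refractive_index
  if (is.na(n_sample)) n_sample <- reference$refractive_index_ref

  abs_for_peak <- abs_spectrum
  emi_for_peak <- emi_spectrum
  if (!is.null(config$smooth_window)) {
    abs_for_peak <- smooth_spectrum(abs_spectrum, config$smooth_window)
    emi_for_peak <- smooth_spectrum(emi_spectrum, config$smooth_window)
  }
  pk_abs <- find_lambda_max(abs_for_peak, window = config$abs_window)
  pk_emi <- find_lambda_max(emi_for_peak, window = config$emi_window)

  a_max <- absorbance_at(abs_spectrum, pk_abs$lambda_nm)
  eps <- molar_extinction(a_max, conc, path)
  stokes <- stokes_shift_wavenumber(pk_abs$lambda_nm, pk_emi$lambda_nm)
  a_exc <- absorbance_at(abs_spectrum, excitation)
  area <- integrate_signal(emi_spectrum)
  phi <- relative_quantum_yield(area, a_exc, n_sample, reference)

  out <- data.frame(compound_id = compound_id,
                    lambda_abs_nm = pk_abs$lambda_nm,
                    lambda_emi_nm = pk_emi$lambda_nm,
                    epsilon = eps,
                    stokes_shift_wavenumber = stokes,
                    quantum_yield = phi,
                    stringsAsFactors = FALSE)
  class(out) <- c("photophysical_summary", "data.frame")
  out
}
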