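# Synthetic data with known ground truth. The generators emulate the
# measurement conditions of the study panel: dilute acetonitrile solutions
# (2e-5 M, 1 cm path), 340 nm excitation, single Gaussian absorption and
# emission bands, additive homoscedastic Gaussian noise. Band widths
# default to 25 nm (absorption) and 45 nm (emission) FWHM -- typical for
# solution-phase organic fluorophores; no published widths exist, so only
# recovery behaviour, not shape, is asserted against them.

FWHM_TO_SD <- 1 / (2 * sqrt(2 * log(2)))

#' Ground-truth record for a synthetic compound
#'
#' @param compound_id Identifier.
#' @param true_lambda_abs_nm,true_lambda_emi_nm True band maxima (nm).
#' @param true_epsilon True molar extinction coefficient (M^-1 cm^-1).
#' @param true_phi True quantum yield.
#' @param seed Seed the artifact was generated under (NA when generated
#'   from the ambient RNG stream).
#' @return One-row `data.frame` of class `synthetic_truth`.
#' @export
synthetic_truth <- function(compound_id, true_lambda_abs_nm,
                            true_lambda_emi_nm = NA_real_,
                            true_epsilon = NA_real_, true_phi = NA_real_,
                            seed = NA_integer_) {
  out <- data.frame(compound_id = as.character(compound_id),
                    true_lambda_abs_nm = true_lambda_abs_nm,
                    true_lambda_emi_nm = true_lambda_emi_nm,
                    true_epsilon = true_epsilon,
                    true_phi = true_phi,
                    seed = as.integer(seed),
                    stringsAsFactors = FALSE)
  class(out) <- c("synthetic_truth", "data.frame")
  out
}

check_grid_coverage <- function(grid, center, sd_nm) {
  if (min(grid) > center - 5 * sd_nm || max(grid) < center + 5 * sd_nm)
    photodft_abort("photodft_grid_coverage",
                   sprintf("grid [%g, %g] does not cover the band at %g nm +/- 5 sigma (%g nm)",
                           min(grid), max(grid), center, 5 * sd_nm))
  invisible(TRUE)
}

#' Generate a synthetic absorbance spectrum
#'
#' Single Gaussian band with peak absorbance `epsilon * conc * path`
#' (Beer-Lambert) centered at the true maximum, plus additive Gaussian
#' noise. Deterministic for a fixed `seed`.
#'
#' @param lambda_abs_nm True absorption maximum (nm).
#' @param epsilon True molar extinction coefficient (M^-1 cm^-1).
#' @param conc_M Concentration (mol/L). Default 2e-5.
#' @param path_cm Path length (cm). Default 1.
#' @param width_nm Band FWHM (nm). Default 25.
#' @param grid_nm Wavelength grid; must cover the band +/- 5 sigma.
#' @param noise_sd Additive noise standard deviation (absorbance units).
#' @param seed Integer seed, or `NULL` to draw from the ambient RNG.
#' @param excitation_nm Excitation wavelength stored in the metadata.
#' @param compound_id Identifier for the truth record.
#' @return `list(spectrum = <spectrum>, truth = <synthetic_truth>)`.
#' @export
generate_absorption_spectrum <- function(lambda_abs_nm, epsilon,
                                         conc_M = 2e-5, path_cm = 1,
                                         width_nm = 25,
                                         grid_nm = seq(280, 400, by = 0.5),
                                         noise_sd = 0, seed = NULL,
                                         excitation_nm = 340,
                                         compound_id = "syn") {
  stopifnot_scalar_number(lambda_abs_nm, "lambda_abs_nm")
  stopifnot_scalar_number(epsilon, "epsilon")
  if (epsilon <= 0 || conc_M <= 0 || path_cm <= 0 || width_nm <= 0 ||
      noise_sd < 0)
    photodft_abort("photodft_invalid_input",
                   "band parameters must be positive (noise_sd >= 0)")
  sd_nm <- width_nm * FWHM_TO_SD
  check_grid_coverage(grid_nm, lambda_abs_nm, sd_nm)
  if (!is.null(seed)) set.seed(seed)
  peak <- epsilon * conc_M * path_cm
  sig <- peak * exp(-(grid_nm - lambda_abs_nm)^2 / (2 * sd_nm^2))
  if (noise_sd > 0) sig <- sig + stats::rnorm(length(grid_nm), 0, noise_sd)
  meta <- measurement_meta("acetonitrile", concentration_M = conc_M,
                           path_length_cm = path_cm,
                           excitation_nm = excitation_nm)
  sp <- spectrum(grid_nm, sig, kind = "absorbance", meta = meta,
                 baseline_tol = Inf)
  list(spectrum = sp,
       truth = synthetic_truth(compound_id, lambda_abs_nm,
                               true_epsilon = epsilon,
                               seed = if (is.null(seed)) NA_integer_ else seed))
}

#' Generate a synthetic emission spectrum with a known quantum yield
#'
#' Builds a Gaussian emission band whose integrated area is chosen by
#' inverting the comparative quantum-yield relation, so that running
#' [relative_quantum_yield()] on the noiseless band (with the same
#' reference, absorbance and refractive index) returns exactly `phi`.
#'
#' @param lambda_emi_nm True emission maximum (nm).
#' @param phi True quantum yield, > 0.
#' @param reference A [quantum_yield_reference()].
#' @param abs_at_excitation Sample absorbance at the excitation wavelength.
#' @param refractive_index Sample solvent refractive index. Defaults to
#'   the reference's (ratio 1).
#' @param width_nm Band FWHM (nm). Default 45.
#' @param grid_nm Wavelength grid; must cover the band +/- 5 sigma.
#' @param noise_sd Additive noise standard deviation (signal units).
#' @param seed Integer seed, or `NULL`.
#' @param excitation_nm Excitation wavelength stored in the metadata.
#' @param compound_id Identifier for the truth record.
#' @return `list(spectrum = <spectrum>, truth = <synthetic_truth>)`.
#' @export
generate_emission_spectrum <- function(lambda_emi_nm, phi, reference,
                                       abs_at_excitation,
                                       refractive_index = NULL,
                                       width_nm = 45,
                                       grid_nm = seq(300, 540, by = 0.5),
                                       noise_sd = 0, seed = NULL,
                                       excitation_nm = 340,
                                       compound_id = "syn") {
  stopifnot(inherits(reference, "quantum_yield_reference"))
  stopifnot_scalar_number(lambda_emi_nm, "lambda_emi_nm")
  stopifnot_scalar_number(phi, "phi")
  stopifnot_scalar_number(abs_at_excitation, "abs_at_excitation")
  if (is.null(refractive_index))
    refractive_index <- reference$refractive_index_ref
  if (phi <= 0 || abs_at_excitation <= 0 || width_nm <= 0 || noise_sd < 0)
    photodft_abort("photodft_invalid_input",
                   "band parameters must be positive (noise_sd >= 0)")
  sd_nm <- width_nm * FWHM_TO_SD
  check_grid_coverage(grid_nm, lambda_emi_nm, sd_nm)
  if (!is.null(seed)) set.seed(seed)
  # invert phi = phi_R (A_R/A)(I/I_R)(n^2/n_R^2) for the band area I
  area <- phi / reference$phi_ref *
    (abs_at_excitation / reference$absorbance_ref) *
    (reference$refractive_index_ref^2 / refractive_index^2) *
    reference$integrated_emission_ref
  sig <- area * stats::dnorm(grid_nm, lambda_emi_nm, sd_nm)
  if (noise_sd > 0) sig <- sig + stats::rnorm(length(grid_nm), 0, noise_sd)
  meta <- measurement_meta("acetonitrile",
                           excitation_nm = excitation_nm,
                           refractive_index = refractive_index)
  sp <- spectrum(grid_nm, sig, kind = "emission", meta = meta)
  list(spectrum = sp,
       truth = synthetic_truth(compound_id, NA_real_,
                               true_lambda_emi_nm = lambda_emi_nm,
                               true_phi = phi,
                               seed = if (is.null(seed)) NA_integer_ else seed))
}

#' Generate a random frontier-orbital panel
#'
#' Uniform HOMO/LUMO draws over the stated ranges (defaults span the
#' study panel: HOMO in \[-5.93, -5.41\] eV, LUMO in \[-3.69, -2.00\] eV),
#' resampled until every record has a positive gap.
#'
#' @param n Number of records.
#' @param homo_range,lumo_range Length-2 numeric ranges (eV).
#' @param seed Integer seed, or `NULL`.
#' @param ids Compound identifiers (default `fmo01`, `fmo02`, ...).
#' @return List of [fmo_record()]s.
#' @export
generate_fmo_panel <- function(n, homo_range = c(-5.93, -5.41),
                               lumo_range = c(-3.69, -2.00), seed = NULL,
                               ids = sprintf("fmo%02d", seq_len(n))) {
  if (n < 1L)
    photodft_abort("photodft_invalid_input", "n must be >= 1")
  if (homo_range[1L] >= lumo_range[2L])
    photodft_abort("photodft_invalid_input",
                   "impossible ranges: no HOMO draw can lie below any LUMO draw")
  if (!is.null(seed)) set.seed(seed)
  homo <- stats::runif(n, homo_range[1L], homo_range[2L])
  lumo <- stats::runif(n, lumo_range[1L], lumo_range[2L])
  bad <- which(homo >= lumo)
  tries <- 0L
  while (length(bad) > 0L && tries < 10000L) {
    homo[bad] <- stats::runif(length(bad), homo_range[1L], homo_range[2L])
    lumo[bad] <- stats::runif(length(bad), lumo_range[1L], lumo_range[2L])
    bad <- which(homo >= lumo)
    tries <- tries + 1L
  }
  if (length(bad) > 0L)
    photodft_abort("photodft_invalid_input",
                   "could not draw positive-gap records from the given ranges")
  Map(fmo_record, ids, homo, lumo)
}

#' Generate random TD-DFT excited states
#'
#' Root energies are sorted increasing; oscillator strengths are uniform
#' on `f_range`; each state's CI coefficients are drawn standard-normal
#' and rescaled so `sum(2 c^2) = 1` (a normalized closed-shell expansion).
#' Orbital pairs run over distinct occupied/virtual combinations around
#' `homo_index`.
#'
#' @param n_states Number of roots, >= 1.
#' @param n_pairs_per_state Orbital pairs per root, >= 1 (at most 9
#'   distinct pairs are available).
#' @param seed Integer seed, or `NULL`.
#' @param homo_index HOMO index used for the absolute orbital numbering.
#' @param energy_range Root-energy range (eV).
#' @param f_range Oscillator-strength range.
#' @return List of [excited_state()]s.
#' @export
generate_tddft_states <- function(n_states, n_pairs_per_state = 3L,
                                  seed = NULL, homo_index = 50L,
                                  energy_range = c(2.5, 3.7),
                                  f_range = c(0, 0.2)) {
  if (n_states < 1L || n_pairs_per_state < 1L)
    photodft_abort("photodft_invalid_input", "counts must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  pairs <- expand.grid(from = homo_index - 0:2, to = homo_index + 1:3)
  if (n_pairs_per_state > nrow(pairs))
    photodft_abort("photodft_invalid_input",
                   sprintf("at most %d distinct orbital pairs available", nrow(pairs)))
  energies <- sort(stats::runif(n_states, energy_range[1L], energy_range[2L]))
  fs <- stats::runif(n_states, f_range[1L], f_range[2L])
  lapply(seq_len(n_states), function(i) {
    sel <- pairs[sample.int(nrow(pairs), n_pairs_per_state), , drop = FALSE]
    x <- stats::rnorm(n_pairs_per_state)
    coefs <- x / sqrt(2 * sum(x^2))   # sum(2 c^2) = 1 by construction
    trans <- Map(orbital_transition, sel$from, sel$to, coefs)
    excited_state(i, energies[i], fs[i], unname(trans))
  })
}

#' Default quantum-yield reference used by the synthetic panel
#'
#' Quinine sulfate in 0.5 M H2SO4 (phi = 0.54), with a nominal absorbance
#' of 0.35 at 340 nm and an integrated emission area of 5000 (arbitrary
#' counts * nm). The absolute reference area is arbitrary -- only ratios
#' enter the comparative method -- but it must be the same object on the
#' generation and recovery sides.
#'
#' @return A [quantum_yield_reference()].
#' @export
default_reference <- function() {
  quantum_yield_reference(phi_ref = 0.54, absorbance_ref = 0.35,
                          integrated_emission_ref = 5000,
                          refractive_index_ref = 1.346)
}

#' Generate a full synthetic compound panel
#'
#' Draws per-compound truths uniformly inside the observed panel ranges
#' (lambda_abs 337.83-341.73 nm, lambda_emi 411.70-429.90 nm, epsilon
#' 1.55e4-2.40e4 M^-1 cm^-1, phi 0.015-0.558) and emits, per compound, an
#' absorbance spectrum, an emission spectrum whose area encodes the true
#' quantum yield, a frontier-orbital record and three TD-DFT roots, all
#' under the standard measurement conditions (2e-5 M, 1 cm, 340 nm
#' excitation, acetonitrile n = 1.344).
#'
#' `noise_sd_frac` scales additive noise as a fraction of each band's peak
#' height; `0` gives noiseless spectra for closure tests.
#'
#' @param n Number of compounds, >= 1.
#' @param seed Integer seed, or `NULL`.
#' @param noise_sd_frac Noise standard deviation as a fraction of peak
#'   height. Default 0.
#' @param reference A [quantum_yield_reference()]; default
#'   [default_reference()].
#' @param grid_step_nm Wavelength grid spacing (nm). Default 0.5.
#' @return List of length `n`; each element is
#'   `list(absorption, emission, fmo, states, truth)`.
#' @export
generate_compound_panel <- function(n = 16L, seed = NULL,
                                    noise_sd_frac = 0,
                                    reference = default_reference(),
                                    grid_step_nm = 0.5) {
  if (n < 1L)
    photodft_abort("photodft_invalid_input", "n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("syn%02d", seq_len(n))
  lab <- stats::runif(n, 337.83, 341.73)
  lem <- stats::runif(n, 411.70, 429.90)
  eps <- stats::runif(n, 1.55e4, 2.40e4)
  phi <- stats::runif(n, 0.015, 0.558)
  n_acn <- 1.344  # acetonitrile at ~20 C
  conc <- 2e-5
  path <- 1
  abs_grid <- seq(280, 400, by = grid_step_nm)
  emi_grid <- seq(300, 540, by = grid_step_nm)
  abs_sd <- 25 * FWHM_TO_SD
  fmo <- generate_fmo_panel(n, ids = ids)
  lapply(seq_len(n), function(i) {
    peak_a <- eps[i] * conc * path
    a_exc <- peak_a * exp(-(340 - lab[i])^2 / (2 * abs_sd^2))
    gen_a <- generate_absorption_spectrum(
      lab[i], eps[i], conc_M = conc, path_cm = path, grid_nm = abs_grid,
      noise_sd = noise_sd_frac * peak_a, compound_id = ids[i])
    gen_e <- generate_emission_spectrum(
      lem[i], phi[i], reference, a_exc, refractive_index = n_acn,
      grid_nm = emi_grid,
      noise_sd = noise_sd_frac * emission_peak_height(gen_e_area(
        phi[i], reference, a_exc, n_acn), 45 * FWHM_TO_SD),
      compound_id = ids[i])
    truth <- synthetic_truth(ids[i], lab[i], lem[i], eps[i], phi[i],
                             seed = if (is.null(seed)) NA_integer_ else seed)
    list(absorption = gen_a$spectrum, emission = gen_e$spectrum,
         fmo = fmo[[i]], states = generate_tddft_states(3L, 3L),
         truth = truth)
  })
}

# area implied by the comparative-method inversion (shared with the
# emission generator so noise can be scaled by the true peak height)
gen_e_area <- function(phi, reference, a_exc, n) {
  phi / reference$phi_ref * (a_exc / reference$absorbance_ref) *
    (reference$refractive_index_ref^2 / n^2) *
    reference$integrated_emission_ref
}

emission_peak_height <- function(area, sd_nm) {
  area / (sd_nm * sqrt(2 * pi))
}
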