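# Accessors for the published characterization tables of the 16-compound
# quinoline-sulphonamide panel (shipped as plain CSV under extdata). Cells
# are stored exactly as printed; `printed = TRUE` returns them as character
# strings so callers can recover the printed decimal precision.

published_csv <- function(name, printed) {
  path <- system.file("extdata", name, package = "photodft",
                      mustWork = TRUE)
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  if (printed) return(df)
  for (j in seq_along(df))
    if (names(df)[j] != "compound_id" && !anyNA(parse_number(df[[j]])))
      df[[j]] <- parse_number(df[[j]])
  df
}

#' Published photophysical panel (band maxima, extinction, Stokes, yield)
#'
#' Columns: `compound_id`, `lambda_abs_nm`, `lambda_emi_nm`,
#' `epsilon_1e4` (molar extinction x 1e-4, M^-1 cm^-1), `stokes_1e4`
#' (Stokes shift x 1e-4, cm^-1) and `phi` (relative quantum yield), as
#' printed.
#'
#' @param printed Return cells as printed character strings instead of
#'   numerics.
#' @return A `data.frame` with 16 rows.
#' @export
published_photophysics <- function(printed = FALSE) {
  published_csv("table1_photophysics.csv", printed)
}

#' Published frontier-orbital energies and reactivity descriptors
#'
#' Columns: `compound_id`, `homo_ev`, `lumo_ev` and the eight reported
#' descriptor columns (`gap_ev`, `ionization_ev`, `affinity_ev`,
#' `electronegativity_ev`, `chemical_potential_ev`, `hardness_ev`,
#' `softness_inv_ev`, `electrophilicity_ev`), as printed.
#'
#' @inheritParams published_photophysics
#' @return A `data.frame` with 16 rows.
#' @export
published_fmo <- function(printed = FALSE) {
  published_csv("table2_fmo.csv", printed)
}

#' Published TD-DFT transition table
#'
#' Three roots per compound for ten compounds: `compound_id`,
#' `lambda_exp_nm` (experimental band maximum), `lambda_theor_nm`,
#' `osc_strength`, `energy_ev` and the reported dominant orbital-pair
#' `contribution_label` with its `contribution_percent`, as printed.
#'
#' @inheritParams published_photophysics
#' @return A `data.frame` with 30 rows.
#' @export
published_tddft <- function(printed = FALSE) {
  published_csv("table3_tddft.csv", printed)
}
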