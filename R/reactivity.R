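#' Frontier molecular orbital record
#'
#' HOMO and LUMO energies (eV) for one compound. The gap must be positive:
#' several descriptor denominators are (I - A) = LUMO - HOMO.
#'
#' @param compound_id Identifier.
#' @param homo_ev HOMO energy (eV).
#' @param lumo_ev LUMO energy (eV); must exceed `homo_ev`.
#' @return An object of class `fmo_record`.
#' @export
fmo_record <- function(compound_id, homo_ev, lumo_ev) {
  stopifnot_scalar_number(homo_ev, "homo_ev")
  stopifnot_scalar_number(lumo_ev, "lumo_ev")
  if (homo_ev >= lumo_ev)
    photodft_abort("photodft_nonpositive_gap",
                   sprintf("non-positive gap: HOMO (%g eV) must lie below LUMO (%g eV)",
                           homo_ev, lumo_ev))
  structure(list(compound_id = as.character(compound_id),
                 homo_ev = homo_ev, lumo_ev = lumo_ev),
            class = "fmo_record")
}

#' Global reactivity descriptors from frontier-orbital energies
#'
#' Conceptual-DFT descriptor set under Koopmans' theorem
#' (I = -E_HOMO, A = -E_LUMO):
#'
#' * gap            `DE  = E_LUMO - E_HOMO`
#' * ionization     `I   = -E_HOMO`
#' * affinity       `A   = -E_LUMO`
#' * electronegativity `chi = (I + A) / 2`
#' * chemical potential `mu = -chi`
#' * hardness       `eta = (I - A) / 2`
#' * softness       `S   = 1 / eta`  (eV^-1)
#' * electrophilicity `omega = mu^2 / (2 eta)`
#' * electro-donating power  `omega- = (3I + A)^2 / (16 (I - A))`
#' * electro-accepting power `omega+ = (I + 3A)^2 / (16 (I - A))`
#'
#' All values are returned at full precision; rounding is the reporting
#' layer's job. Note the algebraic identity `omega- - omega+ = chi`.
#'
#' @param record An [fmo_record()].
#' @return A one-row `data.frame` (class `reactivity_descriptors`) with
#'   columns `compound_id`, `homo_ev`, `lumo_ev`, `gap_ev`,
#'   `ionization_ev`, `affinity_ev`, `electronegativity_ev`,
#'   `chemical_potential_ev`, `hardness_ev`, `softness_inv_ev`,
#'   `electrophilicity_ev`, `omega_minus_ev`, `omega_plus_ev`.
#' @examples
#' compute_descriptors(fmo_record("10a", -5.9243, -2.1605))
#' @export
compute_descriptors <- function(record) {
  if (!inherits(record, "fmo_record"))
    photodft_abort("photodft_invalid_input",
                   "record must be an fmo_record")
  I <- -record$homo_ev
  A <- -record$lumo_ev
  chi <- (I + A) / 2
  eta <- (I - A) / 2
  out <- data.frame(
    compound_id = record$compound_id,
    homo_ev = record$homo_ev,
    lumo_ev = record$lumo_ev,
    gap_ev = record$lumo_ev - record$homo_ev,
    ionization_ev = I,
    affinity_ev = A,
    electronegativity_ev = chi,
    chemical_potential_ev = -chi,
    hardness_ev = eta,
    softness_inv_ev = 1 / eta,
    electrophilicity_ev = chi^2 / (2 * eta),
    omega_minus_ev = (3 * I + A)^2 / (16 * (I - A)),
    omega_plus_ev = (I + 3 * A)^2 / (16 * (I - A)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("reactivity_descriptors", "data.frame")
  out
}

#' Descriptor table for a compound panel
#'
#' Applies [compute_descriptors()] to every record, preserving input
#' order. Accepts a list of [fmo_record()]s or a `data.frame` with columns
#' `compound_id`, `homo_ev`, `lumo_ev`.
#'
#' @param records List of [fmo_record()]s, or a data.frame as above.
#' @return A `data.frame` (class `reactivity_descriptors`), one row per
#'   compound.
#' @export
descriptor_table <- function(records) {
  if (is.data.frame(records)) {
    records <- lapply(seq_len(nrow(records)), function(i)
      fmo_record(records$compound_id[i], records$homo_ev[i],
                 records$lumo_ev[i]))
  }
  if (!is.list(records) || length(records) == 0L)
    photodft_abort("photodft_empty_input",
                   "records must be a non-empty list of fmo_record objects")
  ids <- vapply(records, function(r) r$compound_id, "")
  if (anyDuplicated(ids))
    photodft_abort("photodft_duplicate_id",
                   sprintf("duplicate compound_id: '%s'",
                           ids[duplicated(ids)][1L]))
  out <- do.call(rbind, lapply(records, compute_descriptors))
  class(out) <- c("reactivity_descriptors", "data.frame")
  rownames(out) <- NULL
  out
}

#' Rank compounds by a descriptor
#'
#' Stable sort on one descriptor column; ties are broken by lexicographic
#' `compound_id` so the ordering is fully deterministic.
#'
#' @param table A descriptor table from [descriptor_table()].
#' @param field A descriptor column name, e.g. `"gap_ev"`, `"homo_ev"`.
#' @param direction `"asc"` or `"desc"`.
#' @return Character vector of compound ids in rank order.
#' @export
rank_by <- function(table, field, direction = c("asc", "desc")) {
  direction <- match.arg(direction)
  if (!is.data.frame(table) || nrow(table) == 0L)
    photodft_abort("photodft_empty_input", "empty descriptor table")
  if (!field %in% names(table) || !is.numeric(table[[field]]))
    photodft_abort("photodft_invalid_input",
                   sprintf("'%s' is not a numeric descriptor column", field))
  v <- table[[field]]
  if (direction == "desc") v <- -v
  table$compound_id[order(v, table$compound_id)]
}
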