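# hc in eV*nm (CODATA); reproduces published lambda/energy pairings to
# +/- 0.02 nm. 1 eV = 8065.543937 cm^-1.
HC_EV_NM <- 1239.84193
EV_PER_CM <- 8065.543937

#' Convert excitation energy to wavelength (and back)
#'
#' `lambda (nm) = 1239.84193 / E (eV)`; the inverse is the same reciprocal
#' relation. Values are exact reciprocals of each other, so the round trip
#' is the identity to machine precision.
#'
#' @param energy_ev Excitation energy (eV), > 0. Vectorized.
#' @return Wavelength in nm.
#' @examples
#' energy_to_wavelength(3.1911)  # 388.53 nm
#' @export
energy_to_wavelength <- function(energy_ev) {
  if (any(!is.finite(energy_ev)) || any(energy_ev <= 0))
    photodft_abort("photodft_nonpositive_input", "energy must be positive")
  HC_EV_NM / energy_ev
}

#' @rdname energy_to_wavelength
#' @param wavelength_nm Wavelength (nm), > 0. Vectorized.
#' @export
wavelength_to_energy <- function(wavelength_nm) {
  if (any(!is.finite(wavelength_nm)) || any(wavelength_nm <= 0))
    photodft_abort("photodft_nonpositive_input", "wavelength must be positive")
  HC_EV_NM / wavelength_nm
}

#' One orbital-pair component of an excited state
#'
#' @param from_orbital,to_orbital Integer orbital indices (occupied ->
#'   virtual in the usual case).
#' @param coefficient CI expansion coefficient, signed, `|c| <= 1`.
#' @return An object of class `orbital_transition`.
#' @export
orbital_transition <- function(from_orbital, to_orbital, coefficient) {
  stopifnot_scalar_number(coefficient, "coefficient")
  if (abs(coefficient) > 1)
    photodft_abort("photodft_bad_coefficient",
                   sprintf("|coefficient| = %g exceeds 1", abs(coefficient)))
  structure(list(from_orbital = as.integer(from_orbital),
                 to_orbital = as.integer(to_orbital),
                 coefficient = coefficient),
            class = "orbital_transition")
}

#' One TD-DFT excited state
#'
#' A root of the linear-response problem: excitation energy, oscillator
#' strength, and the orbital-pair CI expansion. For closed-shell singlet
#' states the expansion should satisfy `sum(2 c^2) <= 1` (up to a small
#' de-excitation tolerance); a violation beyond 0.05 triggers a warning.
#'
#' @param index Positive integer root number.
#' @param energy_ev Excitation energy (eV), > 0.
#' @param oscillator_strength Dimensionless f, >= 0.
#' @param transitions List of [orbital_transition()]s.
#' @return An object of class `excited_state`.
#' @export
excited_state <- function(index, energy_ev, oscillator_strength,
                          transitions = list()) {
  stopifnot_scalar_number(energy_ev, "energy_ev")
  stopifnot_scalar_number(oscillator_strength, "oscillator_strength")
  if (energy_ev <= 0)
    photodft_abort("photodft_nonpositive_input",
                   "excitation energy must be positive")
  if (oscillator_strength < 0)
    photodft_abort("photodft_invalid_input",
                   "oscillator strength must be >= 0")
  stopifnot(is.list(transitions))
  norm2 <- sum(vapply(transitions,
                      function(t) 2 * t$coefficient^2, 0))
  if (length(transitions) && norm2 > 1 + 0.05)
    photodft_warn("photodft_norm_exceeded",
                  sprintf("sum(2c^2) = %.3f exceeds 1 + 0.05 for state %d",
                          norm2, as.integer(index)))
  structure(list(index = as.integer(index), energy_ev = energy_ev,
                 oscillator_strength = oscillator_strength,
                 transitions = transitions),
            class = "excited_state")
}

#' Orbital-pair contribution percentage
#'
#' Closed-shell convention: `200 * c^2` (the factor 2 accounts for the
#' doubly occupied reference; this is the convention of the common
#' visualization tools, and the only one under which dominant single
#' configurations exceed 50 %). Open-shell: `100 * c^2`.
#'
#' @param x An [orbital_transition()] or a bare numeric coefficient.
#' @param shell `"closed"` or `"open"`.
#' @return Contribution in percent.
#' @examples
#' contribution_percent(1 / sqrt(2))  # 100
#' contribution_percent(0.51473)      # 52.99
#' @export
contribution_percent <- function(x, shell = c("closed", "open")) {
  shell <- match.arg(shell)
  coef <- if (inherits(x, "orbital_transition")) x$coefficient else x
  if (any(!is.finite(coef)) || any(abs(coef) > 1))
    photodft_abort("photodft_bad_coefficient",
                   "|coefficient| must be <= 1")
  if (shell == "closed") 200 * coef^2 else 100 * coef^2
}

#' Symbolic frontier-orbital label
#'
#' Renders an absolute orbital index relative to a stated HOMO index:
#' occupied orbitals as `H`, `H-1`, ... and virtuals as `L`, `L+1`, ....
#' With `homo_index = NULL` the raw integer index is returned.
#'
#' @param index Integer orbital index (vectorized).
#' @param homo_index Index of the HOMO, or `NULL`.
#' @return Character labels.
#' @export
orbital_label <- function(index, homo_index = NULL) {
  if (is.null(homo_index)) return(as.character(index))
  ifelse(index <= homo_index,
         ifelse(index == homo_index, "H",
                sprintf("H-%d", homo_index - index)),
         ifelse(index == homo_index + 1L, "L",
                sprintf("L+%d", index - homo_index - 1L)))
}

#' Major orbital contributions of an excited state
#'
#' Ranks the state's orbital pairs by contribution percent (descending)
#' and keeps the top `top_k`. Ties are broken by ascending
#' `(from_orbital, to_orbital)` so the report is deterministic.
#'
#' @param state An [excited_state()] with at least one transition.
#' @param top_k Number of pairs to keep; values larger than the list
#'   return the full list, `0` returns an empty report.
#' @param shell Passed to [contribution_percent()].
#' @param homo_index HOMO index used for symbolic labels, or `NULL` for
#'   raw indices.
#' @return A `data.frame` (class `contribution_report`) with columns
#'   `label`, `from_orbital`, `to_orbital`, `percent`, plus attribute
#'   `state_index`.
#' @export
major_contributions <- function(state, top_k = 3L,
                                shell = c("closed", "open"),
                                homo_index = NULL) {
  shell <- match.arg(shell)
  stopifnot(inherits(state, "excited_state"))
  if (length(state$transitions) == 0L)
    photodft_abort("photodft_empty_input",
                   "state has no orbital-pair transitions")
  from <- vapply(state$transitions, function(t) t$from_orbital, 1L)
  to <- vapply(state$transitions, function(t) t$to_orbital, 1L)
  pct <- vapply(state$transitions,
                function(t) contribution_percent(t, shell), 0)
  ord <- order(-pct, from, to)
  keep <- ord[seq_len(min(max(top_k, 0L), length(ord)))]
  out <- data.frame(
    label = sprintf("%s -> %s",
                    orbital_label(from[keep], homo_index),
                    orbital_label(to[keep], homo_index)),
    from_orbital = from[keep], to_orbital = to[keep],
    percent = pct[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "state_index") <- state$index
  class(out) <- c("contribution_report", "data.frame")
  out
}

#' Gaussian-broadened theoretical UV-vis spectrum
#'
#' Convolves the stick spectrum (E_i, f_i) with a Gaussian line shape in
#' the energy domain and evaluates it on a wavelength grid:
#'
#'   signal(lambda) = sum_i f_i * exp(-(E(lambda) - E_i)^2 / (2 sigma^2))
#'
#' With `prefactor = "none"` the curve is in arbitrary units, directly
#' weighted by oscillator strength (the usual presentation). With
#' `prefactor = "epsilon"` the standard conversion to molar absorptivity
#' is applied: each band is scaled by `1.3062974e8 / sigma(cm^-1)`, giving
#' epsilon in M^-1 cm^-1.
#'
#' @param states List of [excited_state()]s; an empty list yields an
#'   all-zero spectrum.
#' @param sigma_ev Gaussian standard deviation (eV), > 0. Default 0.4.
#' @param grid_nm Strictly increasing wavelength grid (nm).
#' @param prefactor `"none"` or `"epsilon"`.
#' @return A [spectrum()] of kind `"theoretical"`.
#' @export
broaden_stick_spectrum <- function(states, sigma_ev = 0.4, grid_nm,
                                   prefactor = c("none", "epsilon")) {
  prefactor <- match.arg(prefactor)
  stopifnot_scalar_number(sigma_ev, "sigma_ev")
  if (sigma_ev <= 0)
    photodft_abort("photodft_nonpositive_input",
                   "broadening sigma must be positive")
  grid_nm <- as.numeric(grid_nm)
  if (length(grid_nm) < 2L || any(diff(grid_nm) <= 0))
    photodft_abort("photodft_invalid_input",
                   "grid_nm must be strictly increasing with >= 2 points")
  e_grid <- wavelength_to_energy(grid_nm)
  sig <- numeric(length(grid_nm))
  for (st in states) {
    stopifnot(inherits(st, "excited_state"))
    sig <- sig + st$oscillator_strength *
      exp(-(e_grid - st$energy_ev)^2 / (2 * sigma_ev^2))
  }
  if (prefactor == "epsilon")
    sig <- sig * 1.3062974e8 / (sigma_ev * EV_PER_CM)
  spectrum(grid_nm, sig, kind = "theoretical")
}

# number token used by the log parser
.num_re <- "[-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?"

#' Parse excited states from a Gaussian-style log excerpt
#'
#' Recognizes blocks of the form
#'
#' ```
#' Excited State   1:   Singlet-A   3.1911 eV  388.53 nm  f=0.0090
#'    48 -> 51    0.51473
#' ```
#'
#' i.e. a header line carrying the root number, energy (eV), wavelength
#' (nm) and oscillator strength, followed by orbital-pair lines
#' `<i> -> <j> <coefficient>`. The wavelength in the file is ignored and
#' recomputed from the energy. Lines outside blocks are ignored; a header
#' or pair line that starts like one but carries a malformed number is an
#' error naming the line.
#'
#' @param x Either a path to a log file or a character vector of lines.
#' @return A list of [excited_state()]s.
#' @export
parse_tddft_log <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    readLines(x, warn = FALSE)
  else unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)

  head_re <- paste0("^\\s*Excited State\\s+(\\d+):\\s+(\\S+)\\s+(", .num_re,
                    ")\\s+eV\\s+(", .num_re, ")\\s+nm\\s+f\\s*=\\s*(",
                    .num_re, ")")
  pair_re <- paste0("^\\s*(\\d+)\\s*->\\s*(\\d+)\\s+(", .num_re, ")\\s*$")

  states <- list()
  cur <- NULL
  flush <- function(cur, states) {
    if (is.null(cur)) return(states)
    st <- excited_state(cur$index, cur$energy, cur$f, cur$transitions)
    c(states, list(st))
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^\\s*Excited State\\s", ln)) {
      m <- regmatches(ln, regexec(head_re, ln))[[1L]]
      if (length(m) == 0L)
        photodft_abort("photodft_parse",
                       sprintf("malformed 'Excited State' header at line %d", i),
                       line = i)
      states <- flush(cur, states)
      cur <- list(index = as.integer(m[2L]), energy = as.numeric(m[4L]),
                  f = as.numeric(m[6L]), transitions = list())
      next
    }
    if (!is.null(cur) && grepl("->", ln, fixed = TRUE)) {
      m <- regmatches(ln, regexec(pair_re, ln))[[1L]]
      if (length(m) == 0L)
        photodft_abort("photodft_parse",
                       sprintf("malformed orbital-pair line at line %d", i),
                       line = i)
      coef <- as.numeric(m[4L])
      cur$transitions <- c(cur$transitions,
                           list(orbital_transition(as.integer(m[2L]),
                                                   as.integer(m[3L]), coef)))
      next
    }
    # any other line ends the current block and is otherwise ignored
    if (!is.null(cur) && nzchar(trimws(ln))) {
      states <- flush(cur, states)
      cur <- NULL
    }
  }
  flush(cur, states)
}

#' Serialize excited states to the log fixture format
#'
#' Inverse of [parse_tddft_log()]: numbers are written with enough digits
#' (17 significant) that parsing the output reproduces the states exactly.
#'
#' @param states List of [excited_state()]s.
#' @param path Optional file to write; when `NULL` the lines are returned.
#' @return Character vector of lines (invisibly when `path` is given).
#' @export
write_tddft_log <- function(states, path = NULL) {
  lines <- character(0)
  for (st in states) {
    lines <- c(lines,
               sprintf("Excited State %d: Singlet-A %.17g eV %.4f nm f=%.17g",
                       st$index, st$energy_ev,
                       energy_to_wavelength(st$energy_ev),
                       st$oscillator_strength),
               vapply(st$transitions, function(t)
                 sprintf("    %d -> %d    %.17g", t$from_orbital,
                         t$to_orbital, t$coefficient), ""),
               "")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
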