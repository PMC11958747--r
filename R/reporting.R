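#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention of the
#' reported tables), unlike base `round()`'s round-half-even. A guard of
#' 1e-9 ulp absorbs binary representation error just below a tie.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @examples
#' round_half_up(0.62375, 4)  # 0.6238
#' round(0.62375, 4)          # 0.6237 or 0.6238 depending on representation
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * trunc(abs(x) * p + 0.5 + 1e-9) / p
}

# fixed-decimal formatting with half-up rounding, ASCII minus, and
# signed-zero normalization ("-0.0000" -> "0.0000")
format_fixed <- function(x, digits) {
  r <- round_half_up(x, digits)
  r[r == 0] <- 0   # drop negative zero
  sprintf(paste0("%.", digits, "f"), r)
}

# numeric parser that also accepts the U+2212 minus sign
parse_number <- function(x) {
  suppressWarnings(as.numeric(gsub("−", "-", x)))
}

#' Construct a report table
#'
#' A titled table of pre-formatted cells plus the raw numeric data it was
#' rendered from. The formatted view is what gets written to CSV/TSV; the
#' raw view keeps full precision for further computation.
#'
#' @param title Table title.
#' @param columns Character vector of column names.
#' @param formatted `data.frame` of character cells (one column per name).
#' @param data `data.frame` of the underlying raw values.
#' @return An object of class `report_table`.
#' @export
report_table <- function(title, columns, formatted, data) {
  stopifnot(is.data.frame(formatted), is.data.frame(data),
            length(columns) == ncol(formatted))
  if (nrow(formatted) == 0L)
    photodft_abort("photodft_empty_input", "a report needs at least one row")
  names(formatted) <- columns
  structure(list(title = title, columns = columns,
                 formatted = formatted, data = data),
            class = "report_table")
}

#' @export
print.report_table <- function(x, ...) {
  cat(x$title, "\n")
  print(x$formatted, row.names = FALSE)
  invisible(x)
}

#' Write a report table to CSV or TSV
#'
#' @param rt A [report_table()].
#' @param path Output path.
#' @param sep Field separator, `","` (CSV) or `"\t"` (TSV).
#' @return `path`, invisibly.
#' @export
write_report <- function(rt, path, sep = ",") {
  stopifnot(inherits(rt, "report_table"))
  utils::write.table(rt$formatted, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read back a written report
#'
#' Re-parses a CSV/TSV written by [write_report()], converting numeric
#' columns (ASCII or U+2212 minus signs both accepted).
#'
#' @param path Report file.
#' @param sep Field separator.
#' @return A `data.frame` with numeric columns where parseable.
#' @export
read_report <- function(path, sep = ",") {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", check.names = FALSE)
  for (j in seq_along(df)) {
    v <- parse_number(df[[j]])
    if (!anyNA(v)) df[[j]] <- v
  }
  df
}

#' Photophysical summary report
#'
#' Renders summaries in the panel-table convention: wavelengths to 2
#' decimals; extinction coefficient and Stokes shift scaled by 1e-4 and
#' printed to 4 decimals; quantum yield to 4 decimals.
#'
#' @param summaries A `data.frame` of [summarize_compound()] rows.
#' @return A [report_table()].
#' @export
photophysics_report <- function(summaries) {
  if (!is.data.frame(summaries) || nrow(summaries) == 0L)
    photodft_abort("photodft_empty_input", "no summaries to report")
  fmt <- data.frame(
    Code = as.character(summaries$compound_id),
    lambda_abs = format_fixed(summaries$lambda_abs_nm, 2),
    lambda_emi = format_fixed(summaries$lambda_emi_nm, 2),
    epsilon_1e4 = format_fixed(summaries$epsilon / 1e4, 4),
    stokes_1e4 = format_fixed(summaries$stokes_shift_wavenumber / 1e4, 4),
    phi = format_fixed(summaries$quantum_yield, 4),
    stringsAsFactors = FALSE)
  report_table("Photophysical properties",
               c("Code", "lambda_abs_nm", "lambda_emi_nm",
                 "epsilon_x1e-4", "stokes_x1e-4", "phi"),
               fmt, summaries)
}

#' Global reactivity descriptor report
#'
#' Renders a descriptor table to 4 decimals (half-up), in the column order
#' Code, HOMO, LUMO, gap, I, A, chi, mu, eta, S, omega, with an optional
#' `significant` marker column flagging the `mark_smallest_gaps` smallest
#' gaps (machine-readable stand-in for bold highlighting).
#'
#' @param table A [descriptor_table()] result.
#' @param mark_smallest_gaps Integer; `0` omits the marker column.
#' @return A [report_table()].
#' @export
reactivity_report <- function(table, mark_smallest_gaps = 0L) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    photodft_abort("photodft_empty_input", "no descriptor rows to report")
  fmt <- data.frame(
    Code = as.character(table$compound_id),
    HOMO = format_fixed(table$homo_ev, 4),
    LUMO = format_fixed(table$lumo_ev, 4),
    gap = format_fixed(table$gap_ev, 4),
    I = format_fixed(table$ionization_ev, 4),
    A = format_fixed(table$affinity_ev, 4),
    chi = format_fixed(table$electronegativity_ev, 4),
    mu = format_fixed(table$chemical_potential_ev, 4),
    eta = format_fixed(table$hardness_ev, 4),
    S = format_fixed(table$softness_inv_ev, 4),
    omega = format_fixed(table$electrophilicity_ev, 4),
    stringsAsFactors = FALSE)
  cols <- c("Code", "HOMO", "LUMO", "gap", "I", "A", "chi", "mu", "eta",
            "S", "omega")
  if (mark_smallest_gaps > 0L) {
    k <- min(mark_smallest_gaps, nrow(table))
    marked <- table$compound_id %in%
      rank_by(table, "gap_ev", "asc")[seq_len(k)]
    fmt$significant <- ifelse(marked, "TRUE", "FALSE")
    cols <- c(cols, "significant")
  }
  report_table("Global reactivity descriptors", cols, fmt, table)
}

#' TD-DFT transition report
#'
#' One row per excited state: theoretical wavelength (2 decimals, from the
#' excitation energy), oscillator strength (4 decimals), energy (4
#' decimals) and the top-k orbital contributions rendered as
#' `"H -> L (52.99)"` strings (percent to 2 decimals), joined by `"; "`.
#'
#' @param states_per_compound Named list: compound id -> list of
#'   [excited_state()]s.
#' @param top_k Contributions kept per state; `0` leaves the column empty.
#' @param shell Passed to [major_contributions()].
#' @param homo_index Single HOMO index, or a named vector/list keyed by
#'   compound id, or `NULL` for raw indices.
#' @return A [report_table()].
#' @export
tddft_report <- function(states_per_compound, top_k = 3L,
                         shell = c("closed", "open"), homo_index = NULL) {
  shell <- match.arg(shell)
  if (!is.list(states_per_compound) || length(states_per_compound) == 0L)
    photodft_abort("photodft_empty_input", "no states to report")
  rows <- list()
  for (id in names(states_per_compound)) {
    hi <- if (is.null(homo_index)) NULL
          else if (length(homo_index) > 1L) homo_index[[id]]
          else homo_index
    for (st in states_per_compound[[id]]) {
      contrib <- ""
      if (top_k > 0L && length(st$transitions) > 0L) {
        mc <- major_contributions(st, top_k = top_k, shell = shell,
                                  homo_index = hi)
        contrib <- paste(sprintf("%s (%s)", mc$label,
                                 format_fixed(mc$percent, 2)),
                         collapse = "; ")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        Code = id, state = st$index,
        lambda_nm = energy_to_wavelength(st$energy_ev),
        f = st$oscillator_strength, energy_ev = st$energy_ev,
        contributions = contrib, stringsAsFactors = FALSE)
    }
  }
  data <- do.call(rbind, rows)
  fmt <- data.frame(
    Code = data$Code, state = as.character(data$state),
    lambda_nm = format_fixed(data$lambda_nm, 2),
    f = format_fixed(data$f, 4),
    energy_ev = format_fixed(data$energy_ev, 4),
    contributions = data$contributions, stringsAsFactors = FALSE)
  report_table("TD-DFT transitions",
               c("Code", "state", "lambda_nm", "f", "energy_ev",
                 "contributions"),
               fmt, data)
}
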