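# Structured error conditions: every user-facing failure mode gets its own
# class ("photodft_<what>") so callers and tests can discriminate them.

photodft_abort <- function(class, message, call = sys.call(-1), ...) {
  cond <- structure(
    class = c(class, "photodft_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cond)
}

photodft_warn <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "photodft_warning", "warning", "condition"),
    list(message = message, call = NULL, ...)
  )
  warning(cond)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    photodft_abort("photodft_invalid_input",
                   sprintf("'%s' must be a single finite number", name))
  invisible(x)
}
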