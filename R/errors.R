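# Classed conditions used across the pipeline. Every error a caller may want
# to branch on carries a stereophyte-specific class in addition to
# "stereophyte_error".

sp_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "stereophyte_error"), ...)
}

sp_validation_error <- function(message, ...) {
  sp_abort(message, "stereophyte_validation_error", ...)
}

sp_io_error <- function(message, ...) {
  sp_abort(message, "stereophyte_io_error", ...)
}

sp_format_error <- function(message, ...) {
  sp_abort(message, "stereophyte_format_error", ...)
}

# Failure modes named by the rectification / reconstruction stages.
insufficient_matches <- function(message) {
  sp_abort(message, "stereophyte_insufficient_matches")
}

reconstruction_failure <- function(message) {
  sp_abort(message, "stereophyte_reconstruction_failure")
}

rectification_failure <- function(message) {
  sp_abort(message, "stereophyte_rectification_failure")
}

undefined_ratio <- function(message) {
  sp_abort(message, "stereophyte_undefined_ratio")
}

degenerate_regression <- function(message) {
  sp_abort(message, "stereophyte_degenerate_regression")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_scalar <- function(x, name, lo = -Inf, hi = Inf, strict_lo = FALSE) {
  if (!is_scalar_number(x)) {
    sp_validation_error(sprintf("`%s` must be a single finite number", name))
  }
  bad_lo <- if (strict_lo) x <= lo else x < lo
  if (bad_lo || x > hi) {
    sp_validation_error(sprintf(
      "`%s` = %g is outside its allowed range %s%g, %g]",
      name, x, if (strict_lo) "(" else "[", lo, hi
    ))
  }
  invisible(x)
}
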