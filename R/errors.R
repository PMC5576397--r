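# condition helpers -- every user-facing error carries a subclass so callers
# (and tests) can branch on the failure mode rather than on message text.

abort_invalid_input <- function(msg, ...) {
  rlang::abort(msg, class = "emdeeg_error_invalid_input", ...)
}

abort_not_enough_extrema <- function(msg = "too few extrema to build spline envelopes") {
  rlang::abort(msg, class = "emdeeg_error_not_enough_extrema")
}

abort_degenerate_signal <- function(msg) {
  rlang::abort(msg, class = "emdeeg_error_degenerate_signal")
}

abort_missing_channel <- function(msg) {
  rlang::abort(msg, class = "emdeeg_error_missing_channel")
}

abort_format <- function(msg) {
  rlang::abort(msg, class = "emdeeg_error_format")
}

check_numeric_finite <- function(x, arg = "x") {
  if (!is.numeric(x)) {
    abort_invalid_input(sprintf("`%s` must be numeric", arg))
  }
  if (anyNA(x) || any(!is.finite(x))) {
    abort_invalid_input(sprintf("`%s` contains non-finite values", arg))
  }
  invisible(x)
}
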