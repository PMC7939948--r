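# Classed conditions so callers can distinguish recoverable signal states
# (calibration failure, unusable reference, degenerate samples) from bugs.

stop_squatcoach <- function(subclass, message, ...) {
  cond <- structure(
    class = c(paste0("squatcoach_", subclass), "squatcoach_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

#' @keywords internal
assert_that <- function(ok, message) {
  if (!isTRUE(ok)) stop_squatcoach("contract_violation", message)
  invisible(TRUE)
}
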