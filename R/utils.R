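# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Gas constant in kJ/(mol K)
#' @keywords internal
RGAS <- 8.314e-3

#' Convert degrees Celsius to kelvin
#'
#' @param x temperature(s) in degrees Celsius.
#' @return temperature(s) in kelvin.
#' @export
celsius_to_kelvin <- function(x) {
  stopifnot(is.numeric(x))
  x + 273.15
}

stop_mp <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop_mp(fmt, ...)
  invisible(TRUE)
}

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}
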