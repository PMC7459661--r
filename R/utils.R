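#' Clamp values to the unit interval
#'
#' Behavioural variables in the packaged models are dimensionless on
#' \eqn{[0, 1]} (low/mid/high mapped to 0/0.5/1). `clamp01()` is the
#' saturation used throughout the model equations.
#'
#' @param x Numeric vector.
#' @param lower,upper Interval ends.
#' @return `x` with values outside `[lower, upper]` replaced by the ends.
#' @export
#' @examples
#' clamp01(c(-0.2, 0.4, 1.7))
clamp01 <- function(x, lower = 0, upper = 1) {
  pmin(pmax(x, lower), upper)
}

# stop() wrapper carrying a class so callers can distinguish structural model
# errors from parameter errors.
structural_error <- function(msg) {
  stop(errorCondition(msg, class = c("burnoutSD_structural_error", "error")))
}

parameter_error <- function(msg) {
  stop(errorCondition(msg, class = c("burnoutSD_parameter_error", "error")))
}

validation_error <- function(msg) {
  stop(errorCondition(msg, class = c("burnoutSD_validation_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
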