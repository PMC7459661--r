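#' Piecewise-linear table function
#'
#' Table (lookup) functions are the standard system-dynamics device for
#' declaring a nonlinear relationship as a set of breakpoints, e.g. the
#' saturating curve mapping capacity for effort to the effort that is
#' actually available: flat near full capacity, with a sharp decline once
#' capacity is nearly depleted.
#'
#' @param xs Strictly increasing numeric breakpoints.
#' @param ys Output values at the breakpoints; same length as `xs` (>= 2).
#' @return An object of class `table_function`.
#' @seealso [table_lookup()]
#' @export
#' @examples
#' f <- table_function(c(0, 0.5, 1), c(0, 0.9, 1))
#' table_lookup(f, 0.25)
table_function <- function(xs, ys) {
  if (!is.numeric(xs) || !is.numeric(ys)) {
    validation_error("table_function: xs and ys must be numeric")
  }
  if (length(xs) != length(ys) || length(xs) < 2L) {
    validation_error("table_function: xs and ys must have equal length >= 2")
  }
  if (any(diff(xs) <= 0)) {
    validation_error("table_function: xs must be strictly increasing")
  }
  structure(list(xs = as.numeric(xs), ys = as.numeric(ys)),
            class = "table_function")
}

#' Evaluate a table function
#'
#' Linear interpolation between the bracketing breakpoints; inputs outside
#' the breakpoint range clamp to the end values.
#'
#' @param tf A [table_function()].
#' @param x Numeric vector of lookup points.
#' @return Interpolated values, same length as `x`.
#' @export
table_lookup <- function(tf, x) {
  if (!inherits(tf, "table_function")) {
    validation_error("table_lookup: tf must be a table_function")
  }
  stats::approx(tf$xs, tf$ys, xout = x, method = "linear", rule = 2)$y
}

#' @export
print.table_function <- function(x, ...) {
  cat("<table_function> ", length(x$xs), " breakpoints on [",
      x$xs[1], ", ", x$xs[length(x$xs)], "]\n", sep = "")
  invisible(x)
}

# Turn a table_function into a plain closure so model equations can call it
# by name, e.g. effort_capacity_curve(capacity_for_effort).
as_closure <- function(tf) {
  force(tf)
  function(x) table_lookup(tf, x)
}
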