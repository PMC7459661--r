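#' One explicit-Euler step of first-order (exponential) smoothing
#'
#' First-order smoothing models a perception or adjustment delay: the
#' smoothed value moves toward its input at a rate proportional to the gap
#' divided by the smoothing time. Continuous limit:
#' \eqn{x(t) = target + (x_0 - target) e^{-t/\tau}}.
#'
#' @param current Current smoothed value.
#' @param target Input being smoothed toward.
#' @param tau Smoothing time (weeks), > 0.
#' @param dt Step size (weeks), 0 < dt <= tau. A warning is issued for
#'   dt > tau/4, where explicit Euler becomes visibly inaccurate.
#' @return The smoothed value after one step:
#'   `current + dt * (target - current) / tau`.
#' @export
first_order_smooth_step <- function(current, target, tau, dt) {
  if (!is.numeric(tau) || tau <= 0) parameter_error("smoothing time tau must be > 0")
  if (dt <= 0 || dt > tau) parameter_error("require 0 < dt <= tau")
  if (dt > tau / 4) warning("dt > tau/4: smoothing step is coarse", call. = FALSE)
  current + dt * (target - current) / tau
}

#' One explicit-Euler step of a goal-seeking stock
#'
#' A goal-seeking stock gradually adjusts to a target at a rate
#' `(target - stock) / adjust_time`. Numerically identical to
#' [first_order_smooth_step()]; kept distinct because in the burnout models
#' the target is endogenous (e.g. demands chasing an extrapolation of
#' current performance) rather than an exogenous input being smoothed.
#'
#' @param stock Current stock value.
#' @param target Target the stock adjusts toward.
#' @param adjust_time Adjustment time (weeks), > 0.
#' @param dt Step size (weeks).
#' @return Stock after one step.
#' @export
goal_seek_step <- function(stock, target, adjust_time, dt) {
  if (!is.numeric(adjust_time) || adjust_time <= 0) {
    parameter_error("adjust_time must be > 0")
  }
  stock + dt * (target - stock) / adjust_time
}

#' Simulation run configuration
#'
#' @param t0 Start time in weeks.
#' @param horizon Duration in weeks (> 0).
#' @param dt Step size in weeks (> 0); `horizon / dt` must be an integer.
#'   The default 0.125 weeks is far finer than the weekly scale on which the
#'   behavioural patterns unfold.
#' @param seed Integer seed recorded with the run (the engine itself is
#'   deterministic; the seed matters for downstream stochastic components).
#' @return An object of class `run_config`.
#' @export
run_config <- function(t0 = 0, horizon = 100, dt = 0.125, seed = 1L) {
  if (dt <= 0) parameter_error("run_config: dt must be > 0")
  if (horizon <= 0) parameter_error("run_config: horizon must be > 0")
  n <- horizon / dt
  if (abs(n - round(n)) > 1e-8) {
    parameter_error("run_config: horizon/dt must be an integer")
  }
  structure(list(t0 = t0, horizon = horizon, dt = dt, seed = as.integer(seed),
                 n_steps = as.integer(round(n))),
            class = "run_config")
}

#' Multi-variable trajectory on a common time grid
#'
#' @param times Strictly increasing time grid (weeks).
#' @param series Named list of numeric vectors, or a matrix with one column
#'   per variable, aligned to `times`. No missing values.
#' @return An object of class `trajectory_set`.
#' @export
trajectory_set <- function(times, series) {
  if (!length(times) || any(diff(times) <= 0)) {
    validation_error("trajectory_set: times must be non-empty and strictly increasing")
  }
  if (!is.matrix(series)) {
    series <- do.call(cbind, lapply(series, as.numeric))
  }
  if (is.null(colnames(series)) || any(!nzchar(colnames(series)))) {
    validation_error("trajectory_set: series must be named")
  }
  if (nrow(series) != length(times)) {
    validation_error("trajectory_set: series length must match the time grid")
  }
  if (any(!is.finite(series))) {
    validation_error("trajectory_set: series contain missing/non-finite values")
  }
  structure(list(times = as.numeric(times), series = series),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("<trajectory_set> ", ncol(x$series), " variables on ",
      length(x$times), " grid points, t = [", x$times[1], ", ",
      x$times[length(x$times)], "] weeks\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.trajectory_set <- function(x, ...) {
  data.frame(week = x$times, x$series, check.names = FALSE)
}

#' Extract one series from a trajectory set
#'
#' @param traj A [trajectory_set()].
#' @param var Variable name.
#' @return Numeric vector aligned to `traj$times`.
#' @export
traj_series <- function(traj, var) {
  if (!var %in% colnames(traj$series)) {
    validation_error(paste0("trajectory has no variable '", var, "'"))
  }
  traj$series[, var]
}

#' One explicit-Euler step of a model graph
#'
#' Auxiliaries and flows are evaluated in topological order at time t, then
#' each stock is updated as `stock + dt * (sum(inflows) - sum(outflows))`;
#' constants are unchanged. Declared-bounded variables are clamped after the
#' update.
#'
#' @param model A [model_graph()].
#' @param state Named numeric vector with a value for every stock and
#'   constant.
#' @param dt Step size (weeks).
#' @return List with `state` (stocks and constants at t + dt) and
#'   `auxiliaries` (auxiliary/flow values at t).
#' @export
euler_step <- function(model, state, dt) {
  given <- names(model$variables)[model$variables %in% c("stock", "constant")]
  missing <- setdiff(given, names(state))
  if (length(missing)) {
    validation_error(paste0("euler_step: state missing value(s) for: ",
                            paste(missing, collapse = ", ")))
  }
  aux <- evaluate_auxiliaries(model, state)
  nxt <- state
  for (s in names(model$net_flow)) {
    nf <- model$net_flow[[s]]
    rate <- sum(aux[nf$inflows], 0) - sum(aux[nf$outflows], 0)
    val <- state[[s]] + dt * rate
    b <- model$bounds[[s]]
    if (!is.null(b)) val <- clamp01(val, b[1], b[2])
    nxt[[s]] <- val
  }
  list(state = nxt, auxiliaries = aux)
}

#' Run a model graph over a time grid
#'
#' Deterministic explicit-Euler integration recording every variable
#' (stocks, constants, auxiliaries and flows) at every grid point.
#'
#' @param model A [model_graph()].
#' @param config A [run_config()].
#' @param initial Named numeric vector covering all stocks and constants.
#' @return A [trajectory_set()] with `horizon/dt + 1` grid points.
#' @export
run_simulation <- function(model, config, initial) {
  stopifnot(inherits(model, "model_graph"), inherits(config, "run_config"))
  times <- config$t0 + seq(0, config$n_steps) * config$dt
  vnames <- names(model$variables)
  out <- matrix(NA_real_, nrow = length(times), ncol = length(vnames),
                dimnames = list(NULL, vnames))
  state <- initial
  for (i in seq_along(times)) {
    step <- euler_step(model, state, config$dt)
    out[i, names(state)] <- state[names(state)]
    out[i, names(step$auxiliaries)] <- step$auxiliaries
    state <- step$state
  }
  trajectory_set(times, out)
}
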