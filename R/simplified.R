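#' Parameters of the simplified capacity-effort-demands model
#'
#' The simplified illustration model has two stocks. Capacity for effort
#' accumulates a constant recovery inflow and is drained by a load
#' proportional to effort. Demands are a goal-seeking stock chasing an
#' extrapolation of current performance. Effort is the smaller of the
#' perceived demands and the effort the current capacity makes available
#' (a saturating table function, flat near full capacity with a sharp
#' decline once capacity is nearly depleted).
#'
#' The defaults are the packaged reference parameterization: a single
#' calibration, frozen, under which a well-rested start overshoots into
#' collapse with the effort peak after week 24 and a stable depleted
#' equilibrium before week 52.
#'
#' @param initial_capacity Starting capacity for effort, in \eqn{[0,1]}.
#' @param initial_demands Starting demands, in \eqn{[0,1]}.
#' @param recovery_rate Constant recovery inflow (per week).
#' @param load_coefficient Load per unit effort (per week).
#' @param effect_of_performance_on_demands Dimensionless gain turning
#'   performance into the demand target.
#' @param time_to_adjust_demands Demand adjustment time (weeks).
#' @param performance_gain Dimensionless gain from effort to performance.
#' @param effort_capacity_curve Nondecreasing [table_function()] mapping
#'   capacity to available effort.
#' @return An object of class `simplified_params`.
#' @export
simplified_params <- function(initial_capacity = 0.95,
                              initial_demands = 0.35,
                              recovery_rate = 0.042,
                              load_coefficient = 0.12,
                              effect_of_performance_on_demands = 1.10,
                              time_to_adjust_demands = 4,
                              performance_gain = 1,
                              effort_capacity_curve = table_function(
                                c(0, 0.25, 0.5, 0.75, 1),
                                c(0, 0.25, 0.85, 0.97, 1))) {
  p <- list(initial_capacity = initial_capacity,
            initial_demands = initial_demands,
            recovery_rate = recovery_rate,
            load_coefficient = load_coefficient,
            effect_of_performance_on_demands = effect_of_performance_on_demands,
            time_to_adjust_demands = time_to_adjust_demands,
            performance_gain = performance_gain,
            effort_capacity_curve = effort_capacity_curve)
  num <- vapply(p[setdiff(names(p), "effort_capacity_curve")], identity, numeric(1))
  if (any(num <= 0)) parameter_error("simplified_params: all parameters must be positive")
  if (any(diff(effort_capacity_curve$ys) < 0)) {
    parameter_error("simplified_params: effort_capacity_curve must be nondecreasing")
  }
  structure(p, class = "simplified_params")
}

#' Build the simplified model graph
#'
#' Wires the two-stock structure: effort = min(demands, f(capacity)),
#' performance proportional to effort, demands goal-seeking toward
#' performance times its gain, and capacity integrating recovery minus
#' effort-proportional load. The causal diagram carries exactly one
#' reinforcing loop (effort -> performance -> demands -> effort) and one
#' balancing loop (capacity -> effort -> load -> capacity).
#'
#' @param params A [simplified_params()].
#' @return A [model_graph()].
#' @export
build_simplified_model <- function(params = simplified_params()) {
  stopifnot(inherits(params, "simplified_params"))
  variables <- c(
    capacity_for_effort = "stock",
    demands = "stock",
    effort = "auxiliary",
    performance = "auxiliary",
    recovery = "flow",
    load = "flow",
    demand_change = "flow",
    recovery_rate = "constant",
    load_coefficient = "constant",
    effect_of_performance_on_demands = "constant",
    time_to_adjust_demands = "constant",
    performance_gain = "constant"
  )
  equations <- list(
    effort = "min(demands, effort_capacity_curve(capacity_for_effort))",
    performance = "performance_gain * effort",
    recovery = "recovery_rate",
    load = "load_coefficient * effort",
    demand_change =
      "(performance * effect_of_performance_on_demands - demands) / time_to_adjust_demands"
  )
  net_flow <- list(
    capacity_for_effort = list(inflows = "recovery", outflows = "load"),
    demands = list(inflows = "demand_change", outflows = character())
  )
  edges <- data.frame(
    source  = c("demands", "capacity_for_effort", "effort", "performance",
                "effort", "load"),
    target  = c("effort", "effort", "performance", "demands",
                "load", "capacity_for_effort"),
    sign    = c("+", "+", "+", "+", "+", "-"),
    delayed = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)
  )
  initial <- c(
    capacity_for_effort = params$initial_capacity,
    demands = params$initial_demands,
    recovery_rate = params$recovery_rate,
    load_coefficient = params$load_coefficient,
    effect_of_performance_on_demands = params$effect_of_performance_on_demands,
    time_to_adjust_demands = params$time_to_adjust_demands,
    performance_gain = params$performance_gain
  )
  model_graph(
    variables = variables,
    equations = equations,
    net_flow = net_flow,
    edges = edges,
    tables = list(effort_capacity_curve = params$effort_capacity_curve),
    bounds = list(demands = c(0, 1)),
    reference_state = initial
  )
}

#' Run the packaged reference scenario of the simplified model
#'
#' Deterministic run from a well-rested state (capacity high, demands low)
#' under the frozen reference parameterization: effort and demands rise
#' together, effort tips over after week 24 as capacity is drained, the
#' system oscillates and settles around week 45-50 at a capacity well below
#' its starting value.
#'
#' @param dt Step size in weeks.
#' @param horizon Run length in weeks.
#' @return A list of class `reference_run` with elements `params`, `config`
#'   and `traj` (a [trajectory_set()]).
#' @export
reference_run <- function(dt = 0.125, horizon = 100) {
  params <- simplified_params()
  model <- build_simplified_model(params)
  config <- run_config(t0 = 0, horizon = horizon, dt = dt)
  traj <- run_simulation(model, config, model$reference_state)
  structure(list(params = params, config = config, traj = traj),
            class = "reference_run")
}

#' @export
print.reference_run <- function(x, ...) {
  cat("<reference_run> simplified burnout model, ",
      x$config$horizon, " weeks at dt = ", x$config$dt, "\n", sep = "")
  cat("  effort peak week:   ",
      detect_peak_week(traj_series(x$traj, "effort"), x$traj$times), "\n", sep = "")
  cat("  settling week (2%): ",
      detect_settling_week(x$traj, band = 0.02,
                           vars = c("capacity_for_effort", "demands", "effort")),
      "\n", sep = "")
  invisible(x)
}

#' Week of the global maximum of a series
#'
#' Quantifies the tipping point of an overshoot-and-collapse trajectory as
#' the time of the series' global maximum (first occurrence on ties).
#'
#' @param series Numeric values.
#' @param times Time grid aligned to `series`.
#' @return The time of the maximum.
#' @export
detect_peak_week <- function(series, times) {
  if (!length(series)) validation_error("detect_peak_week: empty series")
  if (length(series) != length(times)) {
    validation_error("detect_peak_week: series and times differ in length")
  }
  times[which.max(series)]
}

#' Earliest settling time of a trajectory
#'
#' The settling week is the earliest grid time after which every selected
#' series stays within a band of its final value for the rest of the run.
#' The band is `band` times the series' overall excursion (max - min over
#' the run), so a constant series settles at the start and a series still
#' moving at the end of the run never settles. If only the final grid point
#' qualifies, the run is deemed never to settle and the end time (horizon)
#' is returned.
#'
#' @param traj A [trajectory_set()].
#' @param band Band half-width as a fraction of each series' excursion.
#' @param vars Variables to require simultaneously; default all.
#' @return Settling time in weeks.
#' @export
detect_settling_week <- function(traj, band = 0.02, vars = NULL) {
  if (!is.numeric(band) || band <= 0) parameter_error("band must be > 0")
  vars <- vars %||% colnames(traj$series)
  n <- length(traj$times)
  ok <- rep(TRUE, n)
  for (v in vars) {
    x <- traj_series(traj, v)
    tol <- band * diff(range(x))
    ok <- ok & (abs(x - x[n]) <= tol)
  }
  # earliest index from which all later points stay inside the band
  stays <- rev(cumall(rev(ok)))
  idx <- which(stays)[1]
  if (is.na(idx) || idx == n) return(traj$times[n])
  traj$times[idx]
}

cumall <- function(x) cumsum(!x) == 0
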