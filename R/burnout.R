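#' Parameters of the full burnout model
#'
#' The full model couples four processes: regulating demands (task load,
#' requirements per task and hindrances compose an indicated demand; the
#' demand stock goal-seeks toward the larger of that and a
#' performance-extrapolated target), regulating effort (mental effort is the
#' smaller of motivated demands and the effort the perceived capacity makes
#' available), impacts on body and mind (stress accumulates with effort and
#' with the motivation-weighted performance gap, and is relieved by
#' recovery; capacity for effort and cognitive/emotional functions erode
#' under sustained load), and burnout symptoms (a smoothed image of depleted
#' capacity, which can trigger learning: a lasting downward adjustment of
#' work-goal relevance and expected consequences).
#'
#' The first seven arguments are the persona-controllable quantities (the
#' scenario table): caps and initial values of work-goal relevance and
#' expected consequences, plus three binary switches gating whether each
#' goal variable may change and whether learning is enabled. All remaining
#' arguments are shared across personas; their defaults are the packaged
#' calibration, frozen.
#'
#' @param maximum_expected_consequences,maximum_work_goal_relevance Caps in
#'   \eqn{[0,1]} on the two goal stocks.
#' @param work_goal_relevance0,expected_consequences0 Initial values of the
#'   goal stocks (clamped to their caps at construction).
#' @param switch_allow_expected_consequences_to_change,switch_allow_work_goal_relevance_to_change,switch_learning
#'   Binary switches (0/1).
#' @param base_task_load,base_requirements Baseline demand composition
#'   levels in \eqn{[0,1]}.
#' @param hindrance_level Exogenous hindrance level in \eqn{[0,1]}.
#' @param hindrance_gain Dimensionless reinforcement of indicated demand by
#'   hindrances.
#' @param handover_gain Strength of the task-handing-over coping route;
#'   effective relief scales with (1 - expected consequences).
#' @param goal_adjust_gain Strength of the requirement-lowering coping
#'   route; effective relief scales with (1 - work-goal relevance).
#' @param effect_of_performance_on_demands Gain from performance to the
#'   demand target.
#' @param time_to_adjust_demands Demand adjustment time (weeks).
#' @param motivation_exponent Exponent of the nondecreasing motivation
#'   response g(m) = m^motivation_exponent (g(0)=0, g(1)=1).
#' @param self_efficacy_floor Floor of the self-efficacy contribution to
#'   motivation: a run of missed requirements dents but does not abolish
#'   the willingness to try again after rest.
#' @param blind_gain How strongly motivation masks depleted capacity in the
#'   perceived capacity for effort.
#' @param tau_perception Perception delay (weeks): perceived capacity is a
#'   first-order lag of the motivation-masked true capacity, so fatigue is
#'   noticed late.
#' @param recovery_crowding How strongly invested effort crowds out
#'   recovery time: recovery = clamp01(1 - recovery_crowding * effort), so
#'   sustained high effort leaves essentially no room to recuperate.
#' @param stress_gain Stress inflow gain (per week).
#' @param effort_weight,gap_weight Relative stressor weights of mental
#'   effort and of the motivation-weighted performance gap.
#' @param tau_stress_recovery Stress relief time at full recovery (weeks).
#' @param tau_capacity_recovery Capacity refill time at full recovery
#'   (weeks).
#' @param effort_load,stress_load Capacity drain rates per unit effort and
#'   per unit excess stress above the exhaustion onset (per week); below the
#'   onset, stress does not deplete capacity.
#' @param exhaustion_onset Stress level above which cognitive and emotional
#'   functions erode.
#' @param cog_erosion Erosion rate of cognitive/emotional functions above
#'   the onset threshold (per week per unit excess stress).
#' @param tau_cognitive_recovery Cognitive recovery time below the onset
#'   threshold (weeks).
#' @param tau_symptoms Smoothing time of exhaustion symptoms over depleted
#'   capacity (weeks).
#' @param tau_self_efficacy Smoothing time of self-efficacy over closed
#'   performance gaps (weeks).
#' @param learning_trigger Symptom level whose crossing arms the learning
#'   loop.
#' @param latch_tau Time constant of the (fast, one-way) learning latch.
#' @param tau_learning Goal-adjustment time while learning (weeks).
#' @param tau_goal_drift Upward drift time of the goal stocks toward their
#'   caps while un-learned (weeks).
#' @param wgr_learned_target,ec_learned_target Post-learning resting levels
#'   of the two goal stocks.
#' @param effort_capacity_curve Nondecreasing [table_function()] mapping
#'   perceived capacity to available effort.
#' @param demands0,stress0,capacity0,cognitive0,symptoms0,self_efficacy0
#'   Shared initial state: normal effort, well rested, confident, healthy
#'   stress activation.
#' @return An object of class `burnout_params`.
#' @export
burnout_params <- function(maximum_expected_consequences = 1,
                           maximum_work_goal_relevance = 1,
                           work_goal_relevance0 = 0.6,
                           expected_consequences0 = 0.6,
                           switch_allow_expected_consequences_to_change = 1,
                           switch_allow_work_goal_relevance_to_change = 1,
                           switch_learning = 1,
                           base_task_load = 0.85,
                           base_requirements = 0.95,
                           hindrance_level = 0.3,
                           hindrance_gain = 0.4,
                           handover_gain = 0.6,
                           goal_adjust_gain = 0.35,
                           effect_of_performance_on_demands = 1.5,
                           time_to_adjust_demands = 6,
                           motivation_exponent = 0.5,
                           self_efficacy_floor = 0.7,
                           blind_gain = 0.25,
                           tau_perception = 7,
                           recovery_crowding = 1.4,
                           stress_gain = 0.45,
                           effort_weight = 0.85,
                           gap_weight = 0.4,
                           tau_stress_recovery = 2,
                           tau_capacity_recovery = 6,
                           effort_load = 0.04,
                           stress_load = 1.0,
                           exhaustion_onset = 0.55,
                           cog_erosion = 0.25,
                           tau_cognitive_recovery = 12,
                           tau_symptoms = 6,
                           tau_self_efficacy = 6,
                           learning_trigger = 0.5,
                           latch_tau = 0.5,
                           tau_learning = 10,
                           tau_goal_drift = 15,
                           wgr_learned_target = 0.4,
                           ec_learned_target = 0.4,
                           effort_capacity_curve = table_function(
                             c(0, 0.5, 0.62, 0.75, 1),
                             c(0, 0.08, 0.85, 0.95, 1)),
                           demands0 = 0.3,
                           stress0 = 0.15,
                           capacity0 = 0.95,
                           cognitive0 = 0.95,
                           symptoms0 = 0.05,
                           self_efficacy0 = 0.9) {
  p <- as.list(environment())
  sw <- c("switch_allow_expected_consequences_to_change",
          "switch_allow_work_goal_relevance_to_change", "switch_learning")
  for (s in sw) {
    if (!p[[s]] %in% c(0, 1)) parameter_error(paste0(s, " must be 0 or 1"))
  }
  taus <- c("time_to_adjust_demands", "tau_stress_recovery",
            "tau_capacity_recovery", "tau_cognitive_recovery", "tau_symptoms",
            "tau_self_efficacy", "tau_learning", "tau_goal_drift", "latch_tau",
            "tau_perception")
  for (tt in taus) {
    if (p[[tt]] <= 0) parameter_error(paste0(tt, " must be > 0"))
  }
  unit <- c("maximum_expected_consequences", "maximum_work_goal_relevance",
            "work_goal_relevance0", "expected_consequences0", "hindrance_level",
            "exhaustion_onset", "learning_trigger")
  for (u in unit) {
    if (p[[u]] < 0 || p[[u]] > 1) parameter_error(paste0(u, " must be in [0,1]"))
  }
  # The caps are what bind: initial goal values are clamped to their maxima.
  p$work_goal_relevance0 <- min(p$work_goal_relevance0, p$maximum_work_goal_relevance)
  p$expected_consequences0 <- min(p$expected_consequences0, p$maximum_expected_consequences)
  structure(p, class = "burnout_params")
}

# ---- rate helpers: single source of truth shared by the model-graph
# equations and the exported per-step operations -------------------------

motivation_value <- function(work_goal_relevance, expected_consequences,
                             self_efficacy, self_efficacy_floor) {
  work_goal_relevance * expected_consequences *
    (self_efficacy_floor + (1 - self_efficacy_floor) * self_efficacy)
}

perceived_capacity_value <- function(capacity, motivation, blind_gain) {
  clamp01(capacity + blind_gain * motivation * (1 - capacity))
}

indicated_demand_value <- function(task_load, requirements_per_task,
                                   hindrances, hindrance_gain) {
  clamp01(task_load * requirements_per_task * (1 + hindrance_gain * hindrances))
}

stress_rate <- function(stress, mental_effort, gap, motivation, recovery,
                        stress_gain, effort_weight, gap_weight,
                        tau_stress_recovery) {
  inflow <- stress_gain *
    clamp01(effort_weight * mental_effort + gap_weight * motivation * gap)
  inflow * (1 - stress) - stress * recovery / tau_stress_recovery
}

capacity_rate <- function(capacity, mental_effort, stress, recovery,
                          tau_capacity_recovery, effort_load, stress_load,
                          exhaustion_onset) {
  recovery * (1 - capacity) / tau_capacity_recovery -
    (effort_load * mental_effort +
       stress_load * max(0, stress - exhaustion_onset)) * capacity
}

cognitive_rate <- function(cognitive, stress, exhaustion_onset, cog_erosion,
                           tau_cognitive_recovery) {
  (stress <= exhaustion_onset) * (1 - cognitive) / tau_cognitive_recovery -
    cog_erosion * max(0, stress - exhaustion_onset) * cognitive
}

symptoms_rate <- function(symptoms, capacity, tau_symptoms) {
  ((1 - capacity) - symptoms) / tau_symptoms
}

self_efficacy_rate <- function(self_efficacy, gap, tau_self_efficacy) {
  (clamp01(1 - gap) - self_efficacy) / tau_self_efficacy
}

latch_rate <- function(latch, symptoms, learning_trigger, latch_tau) {
  (symptoms > learning_trigger) * (1 - latch) / latch_tau
}

# Goal stocks (work-goal relevance, expected consequences): while un-learned
# they drift toward their cap (success inflates the importance attached to
# work); once learning is latched they goal-seek toward the learned resting
# level, but only while symptoms are declining.
goal_rate <- function(value, cap, learned_target, switch_own, switch_learning,
                      latch, declining, tau_goal_drift, tau_learning) {
  engaged <- switch_learning * latch
  switch_own * ((1 - engaged) * (cap - value) / tau_goal_drift +
                  engaged * declining * (learned_target - value) / tau_learning)
}

# ---- exported per-step operations --------------------------------------

#' One step of the demand-regulation process
#'
#' Composes the indicated demand from task load, requirements per task and
#' hindrances, takes the larger of that and the performance-extrapolated
#' target, and moves the demand stock toward it by goal seeking.
#'
#' @param task_load,requirements_per_task,hindrances Inputs in \eqn{[0,1]}.
#' @param demands_stock Current demand stock.
#' @param performance Current performance.
#' @param params A [burnout_params()].
#' @param dt Step (weeks).
#' @return Updated demand stock.
#' @export
demand_update <- function(task_load, requirements_per_task, hindrances,
                          demands_stock, performance, params, dt) {
  vals <- c(task_load, requirements_per_task, hindrances, demands_stock, performance)
  if (any(vals < 0 | vals > 1)) {
    validation_error("demand_update: inputs must be in [0,1]")
  }
  indicated <- indicated_demand_value(task_load, requirements_per_task,
                                      hindrances, params$hindrance_gain)
  target <- clamp01(max(indicated,
                        performance * params$effect_of_performance_on_demands))
  clamp01(goal_seek_step(demands_stock, target, params$time_to_adjust_demands, dt))
}

#' Effort regulation
#'
#' Mental effort is the smaller of motivated demands and the effort the
#' perceived capacity makes available: `min(demands * g(motivation),
#' f(perceived_capacity))` with g nondecreasing, g(0)=0, g(1)=1. High
#' motivation therefore holds effort at the demand level even as the true
#' capacity falls.
#'
#' @param demands,motivation_to_meet_demands,perceived_capacity_for_effort
#'   Inputs in \eqn{[0,1]}.
#' @param effort_capacity_curve A [table_function()] or function.
#' @param motivation_exponent Exponent of g.
#' @return Mental effort in \eqn{[0,1]}.
#' @export
effort_update <- function(demands, motivation_to_meet_demands,
                          perceived_capacity_for_effort,
                          effort_capacity_curve, motivation_exponent = 0.5) {
  f <- if (inherits(effort_capacity_curve, "table_function")) {
    as_closure(effort_capacity_curve)
  } else {
    effort_capacity_curve
  }
  g <- motivation_to_meet_demands^motivation_exponent
  min(demands * g, f(perceived_capacity_for_effort))
}

#' Performance and the gap in performance
#'
#' Performance is effort modulated by cognitive and emotional functions;
#' the gap is the unmet part of the demands.
#'
#' @param mental_effort,cognitive_and_emotional_functions,demands Inputs in
#'   \eqn{[0,1]}.
#' @return List with `performance` and `gap_in_performance`.
#' @export
performance_and_gap <- function(mental_effort,
                                cognitive_and_emotional_functions, demands) {
  performance <- mental_effort * cognitive_and_emotional_functions
  list(performance = performance,
       gap_in_performance = max(0, demands - performance))
}

#' One step of the body-and-mind process
#'
#' Advances the stress, capacity-for-effort, cognitive-and-emotional-
#' functions and symptoms-of-exhaustion stocks by one Euler step, given the
#' current auxiliary values in `state`.
#'
#' @param state Named list/vector with `stress`, `capacity_for_effort`,
#'   `cognitive_and_emotional_functions`, `symptoms_of_exhaustion`,
#'   `mental_effort`, `gap_in_performance`, `motivation_to_meet_demands`,
#'   `recovery`.
#' @param params A [burnout_params()].
#' @param dt Step (weeks).
#' @return `state` with the four stocks updated (clamped to \eqn{[0,1]}).
#' @export
stress_and_body_step <- function(state, params, dt) {
  s <- as.list(state)
  s$stress <- clamp01(s$stress + dt * stress_rate(
    s$stress, s$mental_effort, s$gap_in_performance,
    s$motivation_to_meet_demands, s$recovery, params$stress_gain,
    params$effort_weight, params$gap_weight, params$tau_stress_recovery))
  s$capacity_for_effort <- clamp01(s$capacity_for_effort + dt * capacity_rate(
    state[["capacity_for_effort"]], s$mental_effort, state[["stress"]],
    s$recovery, params$tau_capacity_recovery, params$effort_load,
    params$stress_load, params$exhaustion_onset))
  s$cognitive_and_emotional_functions <- clamp01(
    s$cognitive_and_emotional_functions + dt * cognitive_rate(
      state[["cognitive_and_emotional_functions"]], state[["stress"]],
      params$exhaustion_onset, params$cog_erosion,
      params$tau_cognitive_recovery))
  s$symptoms_of_exhaustion <- clamp01(
    s$symptoms_of_exhaustion + dt * symptoms_rate(
      state[["symptoms_of_exhaustion"]], state[["capacity_for_effort"]],
      params$tau_symptoms))
  s
}

#' One step of the learning process
#'
#' If learning is enabled, the symptom level has crossed the learning
#' trigger (latched), and symptoms are currently declining, the two goal
#' stocks goal-seek toward their learned resting levels -- each only if its
#' own switch allows change. With its switch at 0 a goal stock is frozen.
#' While un-latched, enabled goal stocks drift toward their caps.
#'
#' @param state Named list/vector with `work_goal_relevance`,
#'   `expected_consequences`, `symptoms_of_exhaustion`,
#'   `capacity_for_effort`, `learning_latch`.
#' @param params A [burnout_params()].
#' @param dt Step (weeks).
#' @return `state` with the goal stocks and latch updated.
#' @export
learning_step <- function(state, params, dt) {
  s <- as.list(state)
  declining <- as.numeric((1 - s$capacity_for_effort) < s$symptoms_of_exhaustion)
  s$work_goal_relevance <- clamp01(
    s$work_goal_relevance + dt * goal_rate(
      state[["work_goal_relevance"]], params$maximum_work_goal_relevance,
      params$wgr_learned_target,
      params$switch_allow_work_goal_relevance_to_change,
      params$switch_learning, state[["learning_latch"]], declining,
      params$tau_goal_drift, params$tau_learning),
    upper = params$maximum_work_goal_relevance)
  s$expected_consequences <- clamp01(
    s$expected_consequences + dt * goal_rate(
      state[["expected_consequences"]], params$maximum_expected_consequences,
      params$ec_learned_target,
      params$switch_allow_expected_consequences_to_change,
      params$switch_learning, state[["learning_latch"]], declining,
      params$tau_goal_drift, params$tau_learning),
    upper = params$maximum_expected_consequences)
  s$learning_latch <- clamp01(
    s$learning_latch + dt * latch_rate(
      state[["learning_latch"]], s$symptoms_of_exhaustion,
      params$learning_trigger, params$latch_tau))
  s
}

# ---- model construction ------------------------------------------------

burnout_initial_state <- function(params) {
  c(demands = params$demands0,
    stress = params$stress0,
    capacity_for_effort = params$capacity0,
    cognitive_and_emotional_functions = params$cognitive0,
    symptoms_of_exhaustion = params$symptoms0,
    self_efficacy = params$self_efficacy0,
    perceived_capacity_for_effort = params$capacity0,
    work_goal_relevance = params$work_goal_relevance0,
    expected_consequences = params$expected_consequences0,
    learning_latch = 0,
    hindrances = params$hindrance_level,
    base_task_load = params$base_task_load,
    base_requirements = params$base_requirements,
    hindrance_gain = params$hindrance_gain,
    handover_gain = params$handover_gain,
    goal_adjust_gain = params$goal_adjust_gain,
    effect_of_performance_on_demands = params$effect_of_performance_on_demands,
    time_to_adjust_demands = params$time_to_adjust_demands,
    motivation_exponent = params$motivation_exponent,
    self_efficacy_floor = params$self_efficacy_floor,
    blind_gain = params$blind_gain,
    stress_gain = params$stress_gain,
    effort_weight = params$effort_weight,
    gap_weight = params$gap_weight,
    tau_stress_recovery = params$tau_stress_recovery,
    tau_capacity_recovery = params$tau_capacity_recovery,
    effort_load = params$effort_load,
    stress_load = params$stress_load,
    exhaustion_onset = params$exhaustion_onset,
    cog_erosion = params$cog_erosion,
    tau_cognitive_recovery = params$tau_cognitive_recovery,
    tau_symptoms = params$tau_symptoms,
    tau_self_efficacy = params$tau_self_efficacy,
    tau_perception = params$tau_perception,
    recovery_crowding = params$recovery_crowding,
    learning_trigger = params$learning_trigger,
    latch_tau = params$latch_tau,
    tau_learning = params$tau_learning,
    tau_goal_drift = params$tau_goal_drift,
    wgr_learned_target = params$wgr_learned_target,
    ec_learned_target = params$ec_learned_target,
    switch_allow_work_goal_relevance_to_change =
      params$switch_allow_work_goal_relevance_to_change,
    switch_allow_expected_consequences_to_change =
      params$switch_allow_expected_consequences_to_change,
    switch_learning = params$switch_learning)
}

#' Build the full burnout model graph
#'
#' Encodes the four-process structure with its five named feedback loops
#' (see [verify_named_loops()]): "regulating demands" and "limits of the
#' body" and "learning to adjust goals and perception" balancing, "blinded
#' by motivation" and "pressure to do more" reinforcing. With all three
#' switches at 0, the two goal stocks have zero net flow and stay at their
#' initial values.
#'
#' @param params A [burnout_params()].
#' @return A [model_graph()] whose `reference_state` is the shared initial
#'   state.
#' @export
build_burnout_model <- function(params = burnout_params()) {
  stopifnot(inherits(params, "burnout_params"))
  stocks <- c("demands", "stress", "capacity_for_effort",
              "cognitive_and_emotional_functions", "symptoms_of_exhaustion",
              "self_efficacy", "perceived_capacity_for_effort",
              "work_goal_relevance", "expected_consequences",
              "learning_latch")
  aux <- c("task_load", "requirements_per_task", "indicated_demand",
           "motivation_to_meet_demands", "mental_effort", "performance",
           "gap_in_performance", "demand_target", "recovery",
           "stress_activation", "symptoms_declining")
  flows <- c("demand_change", "stress_change", "capacity_change",
             "cognitive_change", "symptoms_change", "self_efficacy_change",
             "perceived_capacity_change", "work_goal_relevance_change",
             "expected_consequences_change", "learning_latch_change")
  consts <- c("hindrances", "base_task_load", "base_requirements",
              "hindrance_gain", "handover_gain", "goal_adjust_gain",
              "effect_of_performance_on_demands", "time_to_adjust_demands",
              "motivation_exponent", "self_efficacy_floor", "blind_gain", "stress_gain",
              "effort_weight", "gap_weight", "tau_stress_recovery",
              "tau_capacity_recovery", "effort_load", "stress_load",
              "exhaustion_onset", "cog_erosion", "tau_cognitive_recovery",
              "tau_symptoms", "tau_self_efficacy", "tau_perception",
              "recovery_crowding", "learning_trigger",
              "latch_tau", "tau_learning", "tau_goal_drift",
              "wgr_learned_target", "ec_learned_target",
              "switch_allow_work_goal_relevance_to_change",
              "switch_allow_expected_consequences_to_change",
              "switch_learning")
  variables <- c(
    stats::setNames(rep("stock", length(stocks)), stocks),
    stats::setNames(rep("auxiliary", length(aux)), aux),
    stats::setNames(rep("flow", length(flows)), flows),
    stats::setNames(rep("constant", length(consts)), consts)
  )

  equations <- list(
    motivation_to_meet_demands =
      "motivation_value(work_goal_relevance, expected_consequences, self_efficacy, self_efficacy_floor)",
    mental_effort =
      "effort_update(demands, motivation_to_meet_demands, perceived_capacity_for_effort, effort_capacity_curve, motivation_exponent)",
    performance =
      "mental_effort * cognitive_and_emotional_functions",
    gap_in_performance =
      "max(0, demands - performance)",
    task_load =
      "clamp01(base_task_load * (1 - handover_gain * (1 - expected_consequences) * gap_in_performance))",
    requirements_per_task =
      "clamp01(base_requirements * (1 - goal_adjust_gain * (1 - work_goal_relevance)))",
    indicated_demand =
      "indicated_demand_value(task_load, requirements_per_task, hindrances, hindrance_gain)",
    demand_target =
      "clamp01(max(indicated_demand, performance * effect_of_performance_on_demands))",
    recovery =
      "clamp01(1 - recovery_crowding * mental_effort)",
    stress_activation =
      "stress",
    symptoms_declining =
      "as.numeric((1 - capacity_for_effort) < symptoms_of_exhaustion)",
    demand_change =
      "(demand_target - demands) / time_to_adjust_demands",
    stress_change =
      "stress_rate(stress, mental_effort, gap_in_performance, motivation_to_meet_demands, recovery, stress_gain, effort_weight, gap_weight, tau_stress_recovery)",
    capacity_change =
      "capacity_rate(capacity_for_effort, mental_effort, stress, recovery, tau_capacity_recovery, effort_load, stress_load, exhaustion_onset)",
    cognitive_change =
      "cognitive_rate(cognitive_and_emotional_functions, stress, exhaustion_onset, cog_erosion, tau_cognitive_recovery)",
    symptoms_change =
      "symptoms_rate(symptoms_of_exhaustion, capacity_for_effort, tau_symptoms)",
    self_efficacy_change =
      "self_efficacy_rate(self_efficacy, gap_in_performance, tau_self_efficacy)",
    perceived_capacity_change =
      "(perceived_capacity_value(capacity_for_effort, motivation_to_meet_demands, blind_gain) - perceived_capacity_for_effort) / tau_perception",
    work_goal_relevance_change =
      "goal_rate(work_goal_relevance, maximum_work_goal_relevance_c, wgr_learned_target, switch_allow_work_goal_relevance_to_change, switch_learning, learning_latch, symptoms_declining, tau_goal_drift, tau_learning)",
    expected_consequences_change =
      "goal_rate(expected_consequences, maximum_expected_consequences_c, ec_learned_target, switch_allow_expected_consequences_to_change, switch_learning, learning_latch, symptoms_declining, tau_goal_drift, tau_learning)",
    learning_latch_change =
      "latch_rate(learning_latch, symptoms_of_exhaustion, learning_trigger, latch_tau)"
  )

  flow_of <- c(demands = "demand_change",
               stress = "stress_change",
               capacity_for_effort = "capacity_change",
               cognitive_and_emotional_functions = "cognitive_change",
               symptoms_of_exhaustion = "symptoms_change",
               self_efficacy = "self_efficacy_change",
               perceived_capacity_for_effort = "perceived_capacity_change",
               work_goal_relevance = "work_goal_relevance_change",
               expected_consequences = "expected_consequences_change",
               learning_latch = "learning_latch_change")
  net_flow <- lapply(stats::setNames(nm = stocks), function(s) {
    list(inflows = unname(flow_of[[s]]), outflows = character())
  })

  edges <- rbind(
    data.frame(source = "work_goal_relevance", target = "motivation_to_meet_demands", sign = "+", delayed = FALSE),
    data.frame(source = "expected_consequences", target = "motivation_to_meet_demands", sign = "+", delayed = FALSE),
    data.frame(source = "self_efficacy", target = "motivation_to_meet_demands", sign = "+", delayed = FALSE),
    data.frame(source = "capacity_for_effort", target = "perceived_capacity_for_effort", sign = "+", delayed = TRUE),
    data.frame(source = "motivation_to_meet_demands", target = "perceived_capacity_for_effort", sign = "+", delayed = TRUE),
    data.frame(source = "demands", target = "mental_effort", sign = "+", delayed = FALSE),
    data.frame(source = "motivation_to_meet_demands", target = "mental_effort", sign = "+", delayed = FALSE),
    data.frame(source = "perceived_capacity_for_effort", target = "mental_effort", sign = "+", delayed = FALSE),
    data.frame(source = "mental_effort", target = "performance", sign = "+", delayed = FALSE),
    data.frame(source = "cognitive_and_emotional_functions", target = "performance", sign = "+", delayed = FALSE),
    data.frame(source = "demands", target = "gap_in_performance", sign = "+", delayed = FALSE),
    data.frame(source = "performance", target = "gap_in_performance", sign = "-", delayed = FALSE),
    data.frame(source = "gap_in_performance", target = "task_load", sign = "-", delayed = FALSE),
    data.frame(source = "expected_consequences", target = "task_load", sign = "+", delayed = FALSE),
    data.frame(source = "work_goal_relevance", target = "requirements_per_task", sign = "+", delayed = FALSE),
    data.frame(source = "task_load", target = "indicated_demand", sign = "+", delayed = FALSE),
    data.frame(source = "requirements_per_task", target = "indicated_demand", sign = "+", delayed = FALSE),
    data.frame(source = "hindrances", target = "indicated_demand", sign = "+", delayed = FALSE),
    data.frame(source = "indicated_demand", target = "demand_target", sign = "+", delayed = FALSE),
    data.frame(source = "performance", target = "demand_target", sign = "+", delayed = FALSE),
    data.frame(source = "demand_target", target = "demands", sign = "+", delayed = TRUE),
    data.frame(source = "mental_effort", target = "recovery", sign = "-", delayed = FALSE),
    data.frame(source = "mental_effort", target = "stress", sign = "+", delayed = FALSE),
    data.frame(source = "gap_in_performance", target = "stress", sign = "+", delayed = FALSE),
    data.frame(source = "recovery", target = "stress", sign = "-", delayed = FALSE),
    data.frame(source = "recovery", target = "capacity_for_effort", sign = "+", delayed = FALSE),
    data.frame(source = "mental_effort", target = "capacity_for_effort", sign = "-", delayed = FALSE),
    data.frame(source = "stress", target = "capacity_for_effort", sign = "-", delayed = FALSE),
    data.frame(source = "stress", target = "cognitive_and_emotional_functions", sign = "-", delayed = TRUE),
    data.frame(source = "capacity_for_effort", target = "symptoms_of_exhaustion", sign = "-", delayed = TRUE),
    data.frame(source = "gap_in_performance", target = "self_efficacy", sign = "-", delayed = TRUE),
    data.frame(source = "symptoms_of_exhaustion", target = "work_goal_relevance", sign = "-", delayed = TRUE),
    data.frame(source = "symptoms_of_exhaustion", target = "expected_consequences", sign = "-", delayed = TRUE),
    data.frame(source = "stress", target = "stress_activation", sign = "+", delayed = FALSE)
  )

  initial <- c(burnout_initial_state(params),
               maximum_work_goal_relevance_c = params$maximum_work_goal_relevance,
               maximum_expected_consequences_c = params$maximum_expected_consequences)
  variables <- c(variables,
                 maximum_work_goal_relevance_c = "constant",
                 maximum_expected_consequences_c = "constant")

  unit_vars <- c(stocks, aux)
  bounds <- stats::setNames(rep(list(c(0, 1)), length(unit_vars)), unit_vars)
  bounds$work_goal_relevance <- c(0, params$maximum_work_goal_relevance)
  bounds$expected_consequences <- c(0, params$maximum_expected_consequences)

  process <- c(
    stats::setNames(rep("regulating demands",
                        5), c("demands", "task_load", "requirements_per_task",
                              "indicated_demand", "demand_target")),
    stats::setNames(rep("regulating effort", 6),
                    c("mental_effort", "performance", "gap_in_performance",
                      "motivation_to_meet_demands",
                      "perceived_capacity_for_effort", "self_efficacy")),
    stats::setNames(rep("impacts on body and mind", 4),
                    c("stress", "capacity_for_effort", "recovery",
                      "stress_activation")),
    stats::setNames(rep("burnout symptoms", 6),
                    c("cognitive_and_emotional_functions",
                      "symptoms_of_exhaustion", "work_goal_relevance",
                      "expected_consequences", "learning_latch",
                      "symptoms_declining"))
  )

  model_graph(
    variables = variables,
    equations = equations,
    net_flow = net_flow,
    edges = edges,
    tables = list(effort_capacity_curve = params$effort_capacity_curve),
    bounds = bounds,
    reference_state = initial,
    process = process
  )
}

# Variable-set signatures identifying the five named loops among the
# enumerated simple cycles.
named_loop_signatures <- function() {
  list(
    "regulating demands" = c("demands", "gap_in_performance", "task_load",
                             "indicated_demand", "demand_target"),
    "blinded by motivation" = c("mental_effort", "performance",
                                "gap_in_performance", "self_efficacy",
                                "motivation_to_meet_demands"),
    "pressure to do more" = c("mental_effort", "performance", "demand_target",
                              "demands"),
    "limits of the body" = c("mental_effort", "capacity_for_effort",
                             "perceived_capacity_for_effort"),
    "learning to adjust goals and perception" =
      c("mental_effort", "capacity_for_effort", "symptoms_of_exhaustion",
        "work_goal_relevance", "motivation_to_meet_demands")
  )
}

#' Locate the five named feedback loops of the burnout model
#'
#' Matches each named loop to a concrete enumerated simple cycle via its
#' packaged variable-set signature and reports its polarity. Fails loudly,
#' naming the loop, if a signature has no matching cycle (e.g. after
#' ablating edges).
#'
#' @param model A [model_graph()] built by [build_burnout_model()].
#' @param max_len Maximum cycle length passed to
#'   [enumerate_feedback_loops()].
#' @return Named list of [feedback_loop()]s, one per named loop.
#' @export
verify_named_loops <- function(model, max_len = 8L) {
  loops <- enumerate_feedback_loops(model, max_len = max_len)
  sets <- lapply(loops, function(l) sort(l$cycle))
  sigs <- named_loop_signatures()
  out <- list()
  missing <- character()
  for (nm in names(sigs)) {
    hit <- which(vapply(sets, function(s) identical(s, sort(sigs[[nm]])),
                        logical(1)))
    if (!length(hit)) {
      missing <- c(missing, nm)
    } else {
      l <- loops[[hit[1]]]
      l$label <- nm
      out[[nm]] <- l
    }
  }
  if (length(missing)) {
    structural_error(paste0("missing named feedback loop(s): ",
                            paste(missing, collapse = "; ")))
  }
  out
}
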