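test_that("the full model exposes all reported state variables", {
  m <- build_burnout_model()
  needed <- c("demands", "stress", "capacity_for_effort",
              "cognitive_and_emotional_functions", "symptoms_of_exhaustion",
              "work_goal_relevance", "expected_consequences", "task_load",
              "requirements_per_task", "hindrances", "mental_effort",
              "performance", "gap_in_performance", "motivation_to_meet_demands",
              "perceived_capacity_for_effort", "self_efficacy",
              "stress_activation", "recovery")
  expect_true(all(needed %in% names(m$variables)))
})

test_that("all five named loops are present with the narrated polarities", {
  loops <- verify_named_loops(build_burnout_model())
  expect_length(loops, 5)
  expect_equal(loops[["pressure to do more"]]$polarity, "reinforcing")
  expect_equal(loops[["blinded by motivation"]]$polarity, "reinforcing")
  expect_equal(loops[["limits of the body"]]$polarity, "balancing")
  expect_equal(loops[["regulating demands"]]$polarity, "balancing")
  expect_equal(loops[["learning to adjust goals and perception"]]$polarity,
               "balancing")
})

test_that("ablating the learning edges is reported as one missing loop", {
  m <- build_burnout_model()
  keep <- !(m$edges$source == "symptoms_of_exhaustion" &
              m$edges$target %in% c("work_goal_relevance",
                                    "expected_consequences"))
  m$edges <- m$edges[keep, ]
  err <- tryCatch(verify_named_loops(m), error = identity)
  expect_s3_class(err, "burnoutSD_structural_error")
  expect_match(conditionMessage(err), "learning to adjust goals and perception")
  expect_false(grepl("limits of the body", conditionMessage(err)))
})

test_that("the declared causal polarities survive numerical perturbation", {
  expect_silent(check_edge_signs(build_burnout_model()))
})

test_that("demand_update composes, targets and goal-seeks", {
  p <- burnout_params()
  # zero task load: indicated demand is zero, so the stock only chases the
  # performance extrapolation (here also zero) and decays
  d1 <- demand_update(0, 0.9, 0.5, 0.5, 0, p, 0.125)
  expect_lt(d1, 0.5)
  expect_error(demand_update(1.2, 0.5, 0.5, 0.5, 0.5, p, 0.125), "\\[0,1\\]")

  # hindrances reinforce: more hindrance never lowers the updated stock
  base <- vapply(seq(0, 1, 0.1), function(h) {
    demand_update(0.6, 0.8, h, 0.4, 0.3, p, 0.125)
  }, numeric(1))
  expect_true(all(diff(base) >= 0))

  # constant indicated demand: exponential convergence to it
  target <- min(1, 0.6 * 0.8 * (1 + p$hindrance_gain * 0.5))
  d <- 0
  n <- round(5 * p$time_to_adjust_demands / 0.05)
  for (i in seq_len(n)) d <- demand_update(0.6, 0.8, 0.5, d, 0, p, 0.05)
  expect_equal(d, target, tolerance = 0.01)
})

test_that("effort regulation is motivation-gated and capacity-limited", {
  f <- burnout_params()$effort_capacity_curve
  expect_equal(effort_update(0.4, 1, 1, f), 0.4)
  expect_equal(effort_update(0.4, 0, 1, f), 0)
  # nondecreasing in perceived capacity at fixed demands
  eff <- vapply(seq(0, 1, 0.05), function(cap) {
    effort_update(0.9, 0.8, cap, f)
  }, numeric(1))
  expect_true(all(diff(eff) >= 0))
})

test_that("performance and gap follow the product/deficit arithmetic", {
  pg <- performance_and_gap(0.5, 1, 0.5)
  expect_equal(pg$gap_in_performance, 0)
  pg <- performance_and_gap(0.8, 0, 0.6)
  expect_equal(pg$performance, 0)
  expect_equal(pg$gap_in_performance, 0.6)
  set.seed(11)
  for (i in 1:25) {
    e <- stats::runif(1); cg <- stats::runif(1); d <- stats::runif(1)
    pg <- performance_and_gap(e, cg, d)
    expect_equal(pg$performance, e * cg)
    expect_equal(pg$gap_in_performance, max(0, d - e * cg))
  }
})

test_that("stress decays at rest and sustained stress erodes cognition", {
  p <- burnout_params()
  rest <- list(stress = 0.6, capacity_for_effort = 0.8,
               cognitive_and_emotional_functions = 0.9,
               symptoms_of_exhaustion = 0.2, mental_effort = 0,
               gap_in_performance = 0, motivation_to_meet_demands = 0.5,
               recovery = 1)
  s <- rest
  trace <- numeric(40)
  for (i in 1:40) {
    s <- stress_and_body_step(s, p, 0.125)
    trace[i] <- s$stress
  }
  expect_true(all(diff(c(rest$stress, trace)) < 0))

  hot <- list(stress = p$exhaustion_onset + 0.3, capacity_for_effort = 0.4,
              cognitive_and_emotional_functions = 0.9,
              symptoms_of_exhaustion = 0.5, mental_effort = 0.7,
              gap_in_performance = 0.3, motivation_to_meet_demands = 0.8,
              recovery = 0.1)
  s <- hot
  for (i in seq_len(8 / 0.125)) {
    s$stress <- hot$stress  # hold stress high
    s <- stress_and_body_step(s, p, 0.125)
  }
  expect_lt(s$cognitive_and_emotional_functions,
            hot$cognitive_and_emotional_functions)
})

test_that("one body step reproduces hand-computed Euler arithmetic", {
  p <- burnout_params(stress_gain = 0.4, effort_weight = 0.5, gap_weight = 0.5,
                      tau_stress_recovery = 2, tau_capacity_recovery = 10,
                      effort_load = 0.1, stress_load = 0.5,
                      exhaustion_onset = 0.5, cog_erosion = 0.2,
                      tau_cognitive_recovery = 10, tau_symptoms = 4)
  st <- list(stress = 0.6, capacity_for_effort = 0.5,
             cognitive_and_emotional_functions = 0.8,
             symptoms_of_exhaustion = 0.3, mental_effort = 0.6,
             gap_in_performance = 0.2, motivation_to_meet_demands = 0.5,
             recovery = 0.4)
  out <- stress_and_body_step(st, p, 0.1)
  # stress: inflow 0.4*min(1, 0.5*0.6 + 0.5*0.5*0.2)*(1-0.6) = 0.4*0.35*0.4
  #         outflow 0.6*0.4/2
  expect_equal(out$stress, 0.6 + 0.1 * (0.4 * 0.35 * 0.4 - 0.6 * 0.4 / 2))
  # capacity: 0.4*0.5/10 - (0.1*0.6 + 0.5*(0.6-0.5))*0.5
  expect_equal(out$capacity_for_effort,
               0.5 + 0.1 * (0.4 * 0.5 / 10 - (0.06 + 0.05) * 0.5))
  # cognition: stress 0.6 > onset 0.5 -> erosion only
  expect_equal(out$cognitive_and_emotional_functions,
               0.8 + 0.1 * (-0.2 * 0.1 * 0.8))
  # symptoms: ((1-0.5) - 0.3)/4
  expect_equal(out$symptoms_of_exhaustion, 0.3 + 0.1 * 0.05)
})

test_that("learning is gated by the switches, the latch and symptom decline", {
  p_off <- burnout_params(switch_allow_expected_consequences_to_change = 0,
                          switch_allow_work_goal_relevance_to_change = 0,
                          switch_learning = 0,
                          work_goal_relevance0 = 0.9,
                          expected_consequences0 = 0.9)
  st <- list(work_goal_relevance = 0.9, expected_consequences = 0.9,
             symptoms_of_exhaustion = 0.8, capacity_for_effort = 0.9,
             learning_latch = 1)
  out <- learning_step(st, p_off, 0.125)
  expect_identical(out$work_goal_relevance, 0.9)
  expect_identical(out$expected_consequences, 0.9)

  # switches on, latched, symptoms declining: both goal stocks move toward
  # their learned targets
  p_on <- burnout_params()
  st$symptoms_of_exhaustion <- 0.6  # > 1 - capacity, so declining
  out <- learning_step(st, p_on, 0.125)
  expect_lt(out$work_goal_relevance, 0.9)
  expect_lt(out$expected_consequences, 0.9)

  # learning enabled but the trigger never crossed: only the upward drift
  # toward the cap operates, never a decline below the current level
  st2 <- list(work_goal_relevance = 0.6, expected_consequences = 0.6,
              symptoms_of_exhaustion = 0.1, capacity_for_effort = 0.95,
              learning_latch = 0)
  out2 <- learning_step(st2, p_on, 0.125)
  expect_gte(out2$work_goal_relevance, 0.6)
  expect_gte(out2$expected_consequences, 0.6)
  expect_equal(out2$learning_latch, 0)
})

test_that("graph equations agree with the exported step operations", {
  p <- burnout_params()
  m <- build_burnout_model(p)
  st <- m$reference_state
  st[["demands"]] <- 0.7; st[["capacity_for_effort"]] <- 0.55
  st[["self_efficacy"]] <- 0.7; st[["stress"]] <- 0.6
  aux <- euler_step(m, st, 0.125)$auxiliaries
  mot <- st[["work_goal_relevance"]] * st[["expected_consequences"]] *
    (p$self_efficacy_floor + (1 - p$self_efficacy_floor) * st[["self_efficacy"]])
  expect_equal(aux[["motivation_to_meet_demands"]], mot)
  expect_equal(aux[["mental_effort"]],
               effort_update(st[["demands"]], mot,
                             st[["perceived_capacity_for_effort"]],
                             p$effort_capacity_curve, p$motivation_exponent))
  pg <- performance_and_gap(aux[["mental_effort"]],
                            st[["cognitive_and_emotional_functions"]],
                            st[["demands"]])
  expect_equal(aux[["performance"]], pg$performance)
  expect_equal(aux[["gap_in_performance"]], pg$gap_in_performance)
})

test_that("raising hindrances never lowers peak stress", {
  peak_stress <- function(h) {
    params <- burnout_params(hindrance_level = h)
    m <- build_burnout_model(params)
    tr <- run_simulation(m, run_config(horizon = 60, dt = 0.25),
                         m$reference_state)
    max(traj_series(tr, "stress_activation"))
  }
  peaks <- vapply(c(0.1, 0.3, 0.5, 0.7), peak_stress, numeric(1))
  expect_true(all(diff(peaks) >= 0))
})
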