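test_that("table functions interpolate linearly and clamp at the ends", {
  tf <- table_function(c(0, 1), c(0, 1))
  expect_equal(table_lookup(tf, 0.5), 0.5)
  expect_equal(table_lookup(tf, 1.7), 1.0)
  expect_equal(table_lookup(tf, -2), 0)

  tf3 <- table_function(c(0, 0.5, 1), c(0, 0.9, 1))
  expect_equal(table_lookup(tf3, 0.25), 0.45)
  expect_equal(table_lookup(tf3, c(0.5, 0.75)), c(0.9, 0.95))

  expect_error(table_function(c(0, 0.5, 0.5), c(0, 1, 2)), "increasing")
  expect_error(table_function(0, 1), "length")
})

test_that("first-order smoothing matches its fixed point and Euler limits", {
  expect_equal(first_order_smooth_step(0.7, 0.7, 5, 0.1), 0.7)
  # dt = tau reaches the target in a single step
  expect_warning(x <- first_order_smooth_step(0, 1, 4, 4), "coarse")
  expect_equal(x, 1)
  expect_error(first_order_smooth_step(0, 1, -1, 0.1), "tau")
  expect_error(first_order_smooth_step(0, 1, 2, 3), "dt")
})

test_that("smoothing and goal seeking track the exponential closed form", {
  # x(t) = target + (x0 - target) exp(-t/tau); after t = tau: 1 - exp(-1)
  for (stepper in list(first_order_smooth_step, goal_seek_step)) {
    tau <- 8; dt <- 0.01
    x <- 0
    for (i in seq_len(tau / dt)) x <- stepper(x, 1, tau, dt)
    expect_equal(x, 1 - exp(-1), tolerance = 1e-3)
  }
  expect_equal(goal_seek_step(0.4, 0.4, 10, 1), 0.4)
  expect_error(goal_seek_step(0, 1, 0, 0.1), "adjust_time")
})

test_that("a goal-seeking stock lags a ramp target by the adjustment time", {
  # steady-state response to target = a*t is stock = a*(t - tau)
  tau <- 10; dt <- 0.01; a <- 0.02
  x <- 0
  for (i in seq_len(80 / dt)) x <- goal_seek_step(x, a * (i * dt), tau, dt)
  lag <- (a * 80 - x) / a
  expect_equal(lag, tau, tolerance = 0.02)
})

test_that("euler_step accumulates stocks and reports auxiliaries at t", {
  m <- one_stock_model()
  state <- c(level = 0, inflow_rate = 0.1, outflow_rate = 0)
  for (i in 1:10) state <- euler_step(m, state, 1)$state
  expect_equal(unname(state[["level"]]), 1.0)

  # inflow == outflow conserves the stock
  state <- c(level = 0.4, inflow_rate = 0.3, outflow_rate = 0.3)
  expect_equal(euler_step(m, state, 0.5)$state[["level"]], 0.4)

  # hand Euler arithmetic: ds/dt = 0.2 - 0.05, s0 = 0.5, 2 weeks
  state <- c(level = 0.5, inflow_rate = 0.2, outflow_rate = 0.05)
  for (i in 1:4) state <- euler_step(m, state, 0.5)$state
  expect_equal(unname(state[["level"]]), 0.8)

  expect_error(euler_step(m, c(level = 0), 1), "missing value")
})

test_that("cyclic auxiliary dependencies are rejected with the cycle named", {
  expect_error(
    model_graph(
      variables = c(a = "auxiliary", b = "auxiliary"),
      equations = list(a = "b + 1", b = "a + 1")
    ),
    "cyclic.*a.*b",
    class = "burnoutSD_structural_error"
  )
})

test_that("run_simulation is deterministic and records every variable", {
  m <- one_stock_model()
  init <- c(level = 0.2, inflow_rate = 0, outflow_rate = 0)
  cfg <- run_config(horizon = 10, dt = 0.5)
  tr <- run_simulation(m, cfg, init)
  expect_equal(length(tr$times), 21)
  expect_setequal(colnames(tr$series), names(m$variables))
  # zero flows: everything constant
  expect_true(all(apply(tr$series, 2, function(x) diff(range(x))) == 0))
  # bit-identical repetition
  tr2 <- run_simulation(m, cfg, init)
  expect_identical(tr$series, tr2$series)
})

test_that("explicit Euler converges at first order on the simplified model", {
  m <- build_simplified_model()
  ref <- run_simulation(m, run_config(horizon = 24, dt = 0.025),
                        m$reference_state)
  endpoint <- function(tr) tr$series[nrow(tr$series), c("capacity_for_effort", "demands")]
  e_ref <- endpoint(ref)
  errs <- vapply(c(1, 0.5, 0.25), function(dt) {
    tr <- run_simulation(m, run_config(horizon = 24, dt = dt),
                         m$reference_state)
    max(abs(endpoint(tr) - e_ref))
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(errs) ~ log(c(1, 0.5, 0.25))))[[2]]
  expect_equal(slope, 1, tolerance = 0.1)
})

test_that("run_config validates its grid", {
  expect_error(run_config(horizon = 10, dt = 3), "integer")
  expect_error(run_config(horizon = -1, dt = 0.5), "horizon")
  expect_error(run_config(horizon = 10, dt = 0), "dt")
})

test_that("model graphs serialize to JSON and rebuild equivalently", {
  m <- build_simplified_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_graph(m, path)
  m2 <- read_model_graph(path)
  cfg <- run_config(horizon = 30, dt = 0.25)
  tr1 <- run_simulation(m, cfg, m$reference_state)
  tr2 <- run_simulation(m2, cfg, m2$reference_state)
  expect_equal(tr1$series, tr2$series)
})

test_that("declared edge signs match numerical perturbation", {
  expect_silent(check_edge_signs(build_simplified_model()))
  # a deliberately wrong sign is caught
  m <- build_simplified_model()
  m$edges$sign[m$edges$source == "effort" & m$edges$target == "load"] <- "-"
  expect_error(check_edge_signs(m), "effort -> load",
               class = "burnoutSD_structural_error")
})
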