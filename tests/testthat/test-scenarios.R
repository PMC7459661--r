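test_that("persona parameter vectors match the scenario table", {
  p1 <- persona_params("P1")
  expect_equal(p1$overrides, list(
    maximum_expected_consequences = 1, maximum_work_goal_relevance = 1,
    work_goal_relevance0 = 0.6, expected_consequences0 = 0.6,
    switch_allow_expected_consequences_to_change = 1,
    switch_allow_work_goal_relevance_to_change = 1, switch_learning = 1))
  p2 <- persona_params("P2")
  expect_equal(unlist(p2$overrides[3:7], use.names = FALSE),
               c(0.9, 0.9, 0, 0, 0))
  p3 <- persona_params("P3")
  expect_equal(unlist(p3$overrides[1:4], use.names = FALSE),
               c(0.5, 0.7, 0.6, 0.6))
  expect_error(persona_params("P4"), "unknown persona")
})

test_that("persona runs share every non-scenario parameter", {
  tab <- names(persona_params("P1")$overrides)
  p1 <- do.call(burnout_params, persona_params("P1")$overrides)
  p3 <- do.call(burnout_params, persona_params("P3")$overrides)
  shared <- setdiff(names(p1), tab)
  expect_identical(p1[shared], p3[shared])
  # at most the seven scenario parameters differ
  differing <- names(p1)[!vapply(names(p1), function(n) {
    identical(p1[[n]], p3[[n]])
  }, logical(1))]
  expect_true(all(differing %in% tab))
  expect_lte(length(differing), 7)
})

test_that("persona runs cover 100 weeks and are bit-reproducible", {
  tr <- persona_run_cached("P1")
  expect_equal(range(tr$times), c(0, 100))
  expect_equal(length(tr$times), 100 / 0.125 + 1)
  six <- c("demands", "mental_effort", "cognitive_and_emotional_functions",
           "self_efficacy", "capacity_for_effort", "stress_activation")
  expect_true(all(six %in% colnames(tr$series)))
  tr2 <- run_persona(persona_params("P1"))
  expect_identical(tr$series, tr2$series)
})

test_that("episode counting applies hysteresis and a minimum duration", {
  t <- seq(0, 99)
  square <- rep(c(0.2, 0.9, 0.2, 0.9, 0.2), each = 20)
  eps <- count_episodes(square, t, 0.7, 0.4, 4)
  expect_equal(nrow(eps), 2)
  expect_equal(count_episodes(rep(0.5, 100), t, 0.7, 0.4, 4) |> nrow(), 0)
  # dips between release and onset do not split an episode
  wiggle <- c(rep(0.2, 10), rep(0.8, 10), rep(0.55, 10), rep(0.8, 10),
              rep(0.2, 60))
  expect_equal(nrow(count_episodes(wiggle, t, 0.7, 0.4, 4)), 1)
  # short blips below the minimum duration are dropped
  blip <- c(rep(0.2, 10), rep(0.9, 2), rep(0.2, 88))
  expect_equal(nrow(count_episodes(blip, t, 0.7, 0.4, 4)), 0)
  expect_error(count_episodes(square, t, 0.4, 0.7, 4), "exceed")
})

test_that("episode counting agrees with an independent state-machine scan", {
  oracle <- function(x, t, on, off, mindur) {
    state <- "out"; res <- NULL; start <- NA
    for (i in seq_along(x)) {
      if (state == "out" && x[i] >= on) { state <- "in"; start <- t[i] }
      else if (state == "in" && x[i] < off) {
        if (t[i] - start >= mindur) res <- rbind(res, c(start, t[i]))
        state <- "out"
      }
    }
    if (state == "in" && t[length(t)] - start >= mindur) {
      res <- rbind(res, c(start, t[length(t)]))
    }
    if (is.null(res)) 0L else nrow(res)
  }
  set.seed(99)
  t <- seq(0, 200, by = 0.5)
  for (i in 1:20) {
    x <- clamp01(0.5 + cumsum(stats::rnorm(length(t), sd = 0.05)))
    eps <- count_episodes(x, t, 0.7, 0.4, 4)
    expect_equal(nrow(eps), oracle(x, t, 0.7, 0.4, 4), info = paste("rep", i))
    if (nrow(eps) > 1) expect_true(all(eps$onset[-1] > eps$end[-nrow(eps)]))
  }
})

test_that("the three personas produce three distinct trajectory classes", {
  labels <- vapply(c("P1", "P2", "P3"), function(id) {
    classify_trajectory(persona_run_cached(id))$label
  }, character(1))
  expect_equal(unname(labels),
               c("single_episode_with_learning", "cyclic", "coping"))
  expect_equal(length(unique(labels)), 3)
})

test_that("classification details match the persona narratives", {
  rep1 <- classify_trajectory(persona_run_cached("P1"))
  expect_equal(rep1$episode_count, 1)
  expect_false(is.na(rep1$settling_week))
  expect_gt(rep1$settling_week, rep1$episodes$end[1])

  rep2 <- classify_trajectory(persona_run_cached("P2"))
  expect_gte(rep2$episode_count, 2)

  rep3 <- classify_trajectory(persona_run_cached("P3"))
  expect_equal(rep3$episode_count, 0)
  # stable self-efficacy once the initial transient has passed
  tr3 <- persona_run_cached("P3")
  se_late <- traj_series(tr3, "self_efficacy")[tr3$times >= 50]
  expect_lt(diff(range(se_late)), 0.1)

  # P3 protects cognition better than P1
  cogmin <- function(tr) min(traj_series(tr, "cognitive_and_emotional_functions"))
  expect_gt(cogmin(tr3), cogmin(persona_run_cached("P1")))

  # P1's settled demands sit below the pre-crash peak
  d1 <- traj_series(persona_run_cached("P1"), "demands")
  expect_lt(d1[length(d1)], max(d1))

  expect_error(
    classify_trajectory(trajectory_set(0:10, cbind(demands = rep(0.5, 11)))),
    "stress_activation")
})
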