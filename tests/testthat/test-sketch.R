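test_that("generated sketches validate and are seed-reproducible", {
  sk <- generate_sketch(seed = 7)
  expect_true(validate_sketch(sk))
  expect_equal(ncol(sk$tracks), 7)
  expect_length(sk$timelines, 3)
  sk2 <- generate_sketch(seed = 7)
  expect_identical(sk$tracks, sk2$tracks)
  expect_false(identical(sk$tracks, generate_sketch(seed = 8)$tracks))
  expect_error(generate_sketch(span_years = 0.5), "span_years")
})

test_that("noise-free archetypes carry the canonical phase motifs", {
  sk <- generate_sketch(seed = 1, noise_sd = 0)
  tt <- sk$times
  bu <- tt <= sk$truth$build_up[2]
  crash <- tt >= sk$truth$crash[1] & tt <= sk$truth$crash[2]
  demands <- sk$tracks[, "amount_of_demands"]
  # demands rise through the build-up and drop through the crash
  expect_true(all(diff(demands[bu]) >= 0))
  expect_true(all(diff(demands[crash]) <= 0))
  expect_true(all(diff(sk$tracks[bu, "effort"]) >= 0))
  # need for recovery stays low for a prolonged stretch, then rises steeply
  nfr <- sk$tracks[, "need_for_recovery"]
  flat <- tt <= 0.6 * sk$truth$build_up[2]
  expect_lt(diff(range(nfr[flat])), 0.01)
  expect_gt(max(nfr[bu | crash]), 0.9)
  # resources decline to a low level
  res <- sk$tracks[, "appropriateness_of_resources"]
  expect_true(all(diff(res[bu]) <= 0))
})

test_that("the reward-withheld mechanism depresses recovery-phase engagement", {
  for (seed in 1:5) {
    sk <- generate_sketch(seed = seed, mechanism = "reward_withheld",
                          noise_sd = 0.05)
    bu <- sk$times <= sk$truth$build_up[2]
    rec <- sk$times >= sk$truth$recovery[1]
    expect_lt(mean(sk$tracks[rec, "engagement"]),
              mean(sk$tracks[bu, "engagement"]))
  }
})

test_that("phase detection recovers the generator's boundaries", {
  sk <- generate_sketch(seed = 1, noise_sd = 0)
  ph <- detect_phases(sk)$phases
  expect_equal(ph$name, c("build-up", "crash", "recovery"))
  span <- max(sk$times)
  expect_lt(abs(ph$start[2] - sk$truth$crash[1]) / span, 0.05)
  expect_lt(abs(ph$end[2] - sk$truth$crash[2]) / span, 0.05)
  # contiguity
  expect_equal(ph$start[-1], ph$end[-3])

  # constant tracks: no crash, low confidence
  flat <- sk
  flat$tracks[] <- 0.5
  phf <- detect_phases(flat)$phases
  expect_equal(phf$name, "build-up")
  expect_lt(phf$confidence, 0.5)
})

test_that("a seeded noisy batch is segmented reliably", {
  ok <- 0
  for (seed in 1:50) {
    sk <- generate_sketch(seed = seed, noise_sd = 0.05)
    ph <- detect_phases(sk)$phases
    if (identical(ph$name, c("build-up", "crash", "recovery"))) ok <- ok + 1
  }
  expect_gte(ok, 45)
})

test_that("sketch features are deterministic and internally consistent", {
  sk <- generate_sketch(seed = 2, noise_sd = 0)
  ft <- sketch_features(sk)
  expect_equal(ft$plateau_months, sk$truth$plateau_months, tolerance = 1)
  expect_equal(ft$demands_peak_month,
               detect_peak_week(sk$tracks[, "amount_of_demands"], sk$times))
  # invariant to a unit rescale of every track
  sk2 <- sk
  sk2$tracks <- sk2$tracks * 1.0
  expect_identical(sketch_features(sk2), ft)
  expect_gt(ft$demands_drop, 0.3)
  expect_gt(ft$need_for_recovery_lag_months, 0)
})

test_that("similarity is 1 on self, bounded, symmetric and discriminating", {
  tr1 <- persona_run_cached("P1")
  self <- as_scenario_sketch(tr1)
  expect_equal(compare_sim_to_sketch(tr1, self), 1)

  crashy <- generate_sketch(seed = 5, noise_sd = 0.02)
  crash_free <- as_scenario_sketch(persona_run_cached("P3"))
  s_crash <- compare_sim_to_sketch(tr1, crashy)
  s_flat <- compare_sim_to_sketch(tr1, crash_free)
  expect_gt(s_crash, s_flat)
  for (s in c(s_crash, s_flat)) {
    expect_gte(s, 0); expect_lte(s, 1)
  }
  # symmetric after mapping
  expect_equal(compare_sim_to_sketch(self, crashy),
               compare_sim_to_sketch(crashy, self))

  bad <- trajectory_set(0:10, cbind(demands = rep(0.5, 11)))
  expect_error(compare_sim_to_sketch(bad, crashy), "missing")
})

test_that("sketches round trip through JSON", {
  sk <- generate_sketch(seed = 3, mechanism = "reward_withheld")
  path <- withr::local_tempfile(fileext = ".json")
  write_sketch(sk, path)
  back <- read_sketch(path)
  expect_equal(back$tracks, sk$tracks)
  expect_equal(back$mechanism, sk$mechanism)
  expect_equal(back$times, sk$times)
})
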