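#' Persona parameterizations of the scenario runs
#'
#' The three packaged personas differ only in seven parameters: the caps
#' and initial values of the two goal stocks plus the three switches. All
#' other parameters are shared.
#'
#' \itemize{
#'   \item P1 "Burnout and learning from it": caps 1/1, both goal values
#'     start at 0.6, all switches on.
#'   \item P2 "Burnout and no learning": caps 1/1, both goal values start
#'     at 0.9, all switches off (the goal variables are frozen).
#'   \item P3 "Under pressure but coping": caps 0.5 (expected
#'     consequences) and 0.7 (work-goal relevance), both goal values start
#'     at 0.6 (clamped to the caps), all switches on.
#' }
#'
#' @param id One of `"P1"`, `"P2"`, `"P3"`.
#' @return An object of class `persona_spec`: list with `id`, `label`, and
#'   `overrides` (the seven persona parameters).
#' @export
persona_params <- function(id) {
  specs <- list(
    P1 = list(label = "Burnout and learning from it",
              overrides = list(maximum_expected_consequences = 1,
                               maximum_work_goal_relevance = 1,
                               work_goal_relevance0 = 0.6,
                               expected_consequences0 = 0.6,
                               switch_allow_expected_consequences_to_change = 1,
                               switch_allow_work_goal_relevance_to_change = 1,
                               switch_learning = 1)),
    P2 = list(label = "Burnout and no learning",
              overrides = list(maximum_expected_consequences = 1,
                               maximum_work_goal_relevance = 1,
                               work_goal_relevance0 = 0.9,
                               expected_consequences0 = 0.9,
                               switch_allow_expected_consequences_to_change = 0,
                               switch_allow_work_goal_relevance_to_change = 0,
                               switch_learning = 0)),
    P3 = list(label = "Under pressure but coping",
              overrides = list(maximum_expected_consequences = 0.5,
                               maximum_work_goal_relevance = 0.7,
                               work_goal_relevance0 = 0.6,
                               expected_consequences0 = 0.6,
                               switch_allow_expected_consequences_to_change = 1,
                               switch_allow_work_goal_relevance_to_change = 1,
                               switch_learning = 1))
  )
  if (!id %in% names(specs)) {
    parameter_error(paste0("unknown persona id '", id,
                           "' (expected P1, P2 or P3)"))
  }
  structure(c(list(id = id), specs[[id]]), class = "persona_spec")
}

#' @export
print.persona_spec <- function(x, ...) {
  cat("<persona_spec> ", x$id, ": ", x$label, "\n", sep = "")
  invisible(x)
}

#' Simulate a persona over the default 100-week horizon
#'
#' Applies the persona's seven overrides to the shared parameter set,
#' builds the full burnout model, and runs it from the shared initial state
#' (normal effort, well rested, confident, healthy stress activation). The
#' output contains all model variables, including the six reported ones:
#' demands, mental effort, cognitive and emotional functions,
#' self-efficacy, capacity for effort and stress activation.
#'
#' @param spec A [persona_params()] spec.
#' @param config A [run_config()]; default 100 weeks at dt = 0.125.
#' @return A [trajectory_set()].
#' @export
run_persona <- function(spec, config = run_config()) {
  stopifnot(inherits(spec, "persona_spec"))
  params <- do.call(burnout_params, spec$overrides)
  model <- build_burnout_model(params)
  run_simulation(model, config, model$reference_state)
}

#' Count burnout episodes in a stress series
#'
#' An episode starts when the series crosses above the onset threshold and
#' ends when it next drops below the release threshold (hysteresis avoids
#' chatter around a single threshold). Episodes shorter than `min_duration`
#' are discarded. An episode still open at the end of the series ends at
#' the final time.
#'
#' @param stress_series Numeric series on \eqn{[0,1]}.
#' @param times Aligned time grid (weeks).
#' @param onset_threshold Level whose upward crossing opens an episode.
#' @param release_threshold Level whose downward crossing closes it; must
#'   be below `onset_threshold`.
#' @param min_duration Minimum episode length (weeks).
#' @return Data frame with columns `onset` and `end` (weeks), one row per
#'   episode, disjoint and ordered.
#' @export
count_episodes <- function(stress_series, times, onset_threshold = 0.7,
                           release_threshold = 0.4, min_duration = 4) {
  if (onset_threshold <= release_threshold) {
    parameter_error("onset_threshold must exceed release_threshold")
  }
  active <- FALSE
  onset <- numeric(0); end <- numeric(0)
  start_t <- NA_real_
  for (i in seq_along(stress_series)) {
    x <- stress_series[i]
    if (!active && x >= onset_threshold) {
      active <- TRUE
      start_t <- times[i]
    } else if (active && x < release_threshold) {
      active <- FALSE
      onset <- c(onset, start_t); end <- c(end, times[i])
    }
  }
  if (active) {
    onset <- c(onset, start_t); end <- c(end, times[length(times)])
  }
  keep <- (end - onset) >= min_duration
  data.frame(onset = onset[keep], end = end[keep])
}

#' Classify a persona trajectory
#'
#' Operationalizes the three qualitative trajectory patterns: `coping`
#' (no burnout episode), `single_episode_with_learning` (exactly one
#' episode followed by settling into a stable state), and `cyclic` (two or
#' more episodes). Episodes are counted on the stress-activation series
#' with hysteresis thresholds; settling uses [detect_settling_week()] over
#' the six reported variables.
#'
#' @param traj A [trajectory_set()] containing the six reported variables.
#' @param thresholds List with `onset`, `release`, `min_duration`,
#'   `settle_band`.
#' @return An object of class `pattern_report`: list with `episodes` (data
#'   frame), `episode_count`, `label`, and `settling_week` (`NA` if the run
#'   never settles).
#' @export
classify_trajectory <- function(traj,
                                thresholds = list(onset = 0.7, release = 0.4,
                                                  min_duration = 4,
                                                  settle_band = 0.02)) {
  needed <- c("demands", "mental_effort", "cognitive_and_emotional_functions",
              "self_efficacy", "capacity_for_effort", "stress_activation")
  missing <- setdiff(needed, colnames(traj$series))
  if (length(missing)) {
    validation_error(paste0("classify_trajectory: missing variable(s): ",
                            paste(missing, collapse = ", ")))
  }
  eps <- count_episodes(traj_series(traj, "stress_activation"), traj$times,
                        thresholds$onset, thresholds$release,
                        thresholds$min_duration)
  horizon <- traj$times[length(traj$times)]
  settle <- detect_settling_week(traj, band = thresholds$settle_band,
                                 vars = needed)
  settled <- settle < horizon
  n <- nrow(eps)
  label <- if (n == 0) {
    "coping"
  } else if (n == 1 && settled && settle >= eps$end[1]) {
    "single_episode_with_learning"
  } else if (n >= 2) {
    "cyclic"
  } else {
    # one episode but no subsequent settling: treat as cyclic-in-progress
    "cyclic"
  }
  structure(list(episodes = eps, episode_count = n, label = label,
                 settling_week = if (settled) settle else NA_real_),
            class = "pattern_report")
}

#' @export
print.pattern_report <- function(x, ...) {
  cat("<pattern_report> ", x$label, " (", x$episode_count, " episode",
      if (x$episode_count != 1) "s", ")\n", sep = "")
  if (x$episode_count > 0) {
    for (i in seq_len(x$episode_count)) {
      cat("  episode ", i, ": weeks ", round(x$episodes$onset[i], 1), " - ",
          round(x$episodes$end[i], 1), "\n", sep = "")
    }
  }
  if (!is.na(x$settling_week)) {
    cat("  settles by week ", round(x$settling_week, 1), "\n", sep = "")
  }
  invisible(x)
}
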