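sketch_track_names <- function() {
  c("amount_of_demands", "effort", "perceived_efficacy",
    "appropriateness_of_resources", "engagement", "need_for_recovery",
    "stress_responses")
}

sketch_timeline_names <- function() {
  c("interventions", "work_developments", "private_developments")
}

# piecewise-linear segment value on a monthly grid
seg <- function(times, t0, t1, y0, y1) {
  w <- clamp01((times - t0) / max(t1 - t0, 1e-9))
  y0 + (y1 - y0) * w
}

run_seeded <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code())
}

#' Generate a synthetic retrospective burnout sketch
#'
#' Emulates the retrospective graphs-over-time task: seven perceived
#' variable tracks plus three labelled event timelines over a 1-10 year
#' span, with the canonical build-up / crash / recovery structure embedded.
#' Archetype tracks are piecewise-linear segments with seeded Gaussian
#' track noise; the ground-truth phase boundaries are returned alongside so
#' segmentation can be scored. The real sketches behind this design are not
#' distributed; every generated record is synthetic.
#'
#' Track motifs: demands rise low-to-high through the build-up and drop
#' suddenly at the crash; effort tracks demands at a higher base; need for
#' recovery stays low for a prolonged time then rises steeply before the
#' crash; resources decline to a low level; the stress response peaks with
#' the crash while perceived efficacy drops; recovery opens with a plateau
#' of lowered (but not absent) activity followed by a gradual return of
#' demands and effort. With `mechanism = "reward_withheld"`, engagement
#' additionally shows a deep drop with prolonged low values.
#'
#' @param seed Integer seed; the same seed reproduces the sketch exactly.
#' @param span_years Sketch span in years, in \eqn{[1, 10]}.
#' @param mechanism Crash mechanism: `"exhaustion"` (effort becomes
#'   impossible) or `"reward_withheld"` (effort invested, reward withheld).
#' @param noise_sd Standard deviation of the Gaussian track noise.
#' @param plateau_months Length of the lowered-activity plateau opening the
#'   recovery phase (1-12 months).
#' @return An object of class `scenario_sketch`: monthly `times`, a
#'   7-column `tracks` matrix on \eqn{[0,1]}, `timelines` (3 labelled event
#'   lists), `mechanism`, and `truth` (ground-truth phase boundaries).
#' @export
generate_sketch <- function(seed = 1L, span_years = 2,
                            mechanism = c("exhaustion", "reward_withheld"),
                            noise_sd = 0.02, plateau_months = 6) {
  mechanism <- match.arg(mechanism)
  if (!is.numeric(span_years) || span_years < 1 || span_years > 10) {
    parameter_error("span_years must be in [1, 10]")
  }
  if (noise_sd < 0) parameter_error("noise_sd must be >= 0")
  if (plateau_months < 1 || plateau_months > 12) {
    parameter_error("plateau_months must be in [1, 12]")
  }
  span <- round(span_years * 12)
  times <- seq(0, span)
  c0 <- round(0.55 * span)                     # crash start (joint peak)
  c1 <- min(span - 2, c0 + max(2, round(0.06 * span)))
  p1 <- min(span - 1, c1 + plateau_months)     # end of recovery plateau
  nfr_up <- round(0.6 * c0)                    # need-for-recovery upturn

  phase <- function(bu_y0, bu_y1, crash_y, plat_y, end_y) {
    ifelse(times <= c0, seg(times, 0, c0, bu_y0, bu_y1),
           ifelse(times <= c1, seg(times, c0, c1, bu_y1, crash_y),
                  ifelse(times <= p1, seg(times, c1, p1, crash_y, plat_y),
                         seg(times, p1, span, plat_y, end_y))))
  }

  tracks <- cbind(
    amount_of_demands = phase(0.20, 0.90, 0.25, 0.25, 0.50),
    effort = phase(0.55, 0.95, 0.20, 0.20, 0.45),
    perceived_efficacy = phase(0.75, 0.65, 0.20, 0.22, 0.65),
    appropriateness_of_resources = phase(0.45, 0.20, 0.20, 0.22, 0.35),
    engagement = if (mechanism == "reward_withheld") {
      phase(0.70, 0.75, 0.15, 0.15, 0.25)
    } else {
      phase(0.70, 0.75, 0.45, 0.45, 0.65)
    },
    need_for_recovery = ifelse(
      times <= nfr_up, 0.15,
      ifelse(times <= c1, seg(times, nfr_up, c1, 0.15, 0.95),
             seg(times, c1, span, 0.95, 0.30))),
    stress_responses = ifelse(
      times <= nfr_up, seg(times, 0, nfr_up, 0.25, 0.45),
      ifelse(times <= c1, seg(times, nfr_up, c1, 0.45, 0.95),
             seg(times, c1, span, 0.95, 0.30)))
  )

  if (noise_sd > 0) {
    noise <- run_seeded(seed, function() {
      matrix(stats::rnorm(length(tracks), sd = noise_sd),
             nrow = nrow(tracks))
    })
    tracks <- clamp01(tracks + noise)
  }

  timelines <- list(
    interventions = data.frame(
      label = c("sick leave", "professional support"),
      time = c(c0 + 1, c1 + 2)),
    work_developments = data.frame(
      label = c("new responsibilities", "reduced hours"),
      start = c(2, c1), end = c(c0, p1)),
    private_developments = data.frame(
      label = "private strain",
      start = max(0, c0 - 6), end = min(span, c0 + 3))
  )

  structure(list(
    times = times,
    tracks = tracks,
    timelines = timelines,
    mechanism = mechanism,
    truth = list(build_up = c(0, c0), crash = c(c0, c1),
                 recovery = c(c1, span), plateau_months = p1 - c1)
  ), class = "scenario_sketch")
}

#' Validate a scenario sketch
#'
#' Checks the record invariants: exactly the seven named tracks, exactly
#' three timelines, track values in \eqn{[0,1]}, and a common time grid.
#'
#' @param sketch A `scenario_sketch`.
#' @return `TRUE` invisibly; throws a validation error otherwise.
#' @export
validate_sketch <- function(sketch) {
  if (!inherits(sketch, "scenario_sketch")) {
    validation_error("not a scenario_sketch")
  }
  if (!identical(sort(colnames(sketch$tracks)), sort(sketch_track_names()))) {
    validation_error("sketch must carry exactly the seven named tracks")
  }
  if (!identical(sort(names(sketch$timelines)), sort(sketch_timeline_names()))) {
    validation_error("sketch must carry exactly the three named timelines")
  }
  if (nrow(sketch$tracks) != length(sketch$times)) {
    validation_error("track length must match the time grid")
  }
  if (any(sketch$tracks < 0 | sketch$tracks > 1)) {
    validation_error("track values must lie in [0,1]")
  }
  invisible(TRUE)
}

#' @export
print.scenario_sketch <- function(x, ...) {
  cat("<scenario_sketch> ", length(x$times) - 1, " months, mechanism '",
      x$mechanism, "'\n", sep = "")
  invisible(x)
}

rolling_mean3 <- function(x) {
  n <- length(x)
  c(x[1], (x[-c(1, 2)] + x[-c(1, n)] + x[-c(n - 1, n)]) / 3, x[n])
}

#' Segment a sketch into build-up, crash and recovery phases
#'
#' The crash is located at the steepest joint (demands + effort) drop; the
#' crash start is the local joint maximum just before it and the crash end
#' the local minimum just after. Everything before is the build-up,
#' everything after the recovery. If no sufficiently deep drop exists, a
#' single build-up phase with low confidence is returned.
#'
#' @param sketch A `scenario_sketch`.
#' @return An object of class `phase_annotation`: data frame `phases` with
#'   columns `name`, `start`, `end`, `confidence`, contiguous and in
#'   canonical order when all present.
#' @export
detect_phases <- function(sketch) {
  validate_sketch(sketch)
  times <- sketch$times
  n <- length(times)
  raw <- (sketch$tracks[, "amount_of_demands"] + sketch$tracks[, "effort"]) / 2
  joint <- rolling_mean3(raw)
  rng <- diff(range(joint))
  d <- diff(joint)
  i_drop <- which.min(d)                      # steepest single-step drop
  drop_ok <- rng > 0.05 && -d[i_drop] > 0.1 * rng

  if (!drop_ok) {
    phases <- data.frame(name = "build-up", start = times[1], end = times[n],
                         confidence = 0.2)
    return(structure(list(phases = phases), class = "phase_annotation"))
  }

  # boundaries on the raw series: the smoothed drop only localizes the
  # crash, smoothing would bias the peak/trough by a grid step
  w <- max(2L, round(0.1 * n))
  lo <- max(1L, i_drop - w); hi <- min(n, i_drop + 1L + w)
  p <- lo - 1L + which.max(raw[lo:i_drop])              # crash start
  post <- raw[(i_drop + 1L):hi]
  q <- i_drop + which(post <= min(post) + 0.05 * rng)[1]  # crash end
  depth <- (raw[p] - raw[q]) / rng
  phases <- data.frame(
    name = c("build-up", "crash", "recovery"),
    start = c(times[1], times[p], times[q]),
    end = c(times[p], times[q], times[n]),
    confidence = clamp01(c(0.5 + depth / 2, depth, 0.5 + depth / 2))
  )
  structure(list(phases = phases), class = "phase_annotation")
}

#' @export
print.phase_annotation <- function(x, ...) {
  for (i in seq_len(nrow(x$phases))) {
    cat(sprintf("  %-9s months %5.1f - %5.1f  (confidence %.2f)\n",
                x$phases$name[i], x$phases$start[i], x$phases$end[i],
                x$phases$confidence[i]))
  }
  invisible(x)
}

#' Scalar features of a sketch
#'
#' Deterministic summary features of the canonical burnout motifs: peak
#' times of demands, effort and stress response; drop magnitudes of demands
#' and perceived efficacy across the crash; length of the lowered-activity
#' plateau (months); and the lag between the need-for-recovery upturn and
#' the crash.
#'
#' @param sketch A `scenario_sketch`.
#' @return Named list of scalar features.
#' @export
sketch_features <- function(sketch) {
  validate_sketch(sketch)
  times <- sketch$times
  tr <- sketch$tracks
  ann <- detect_phases(sketch)
  ph <- ann$phases
  demands_peak <- detect_peak_week(tr[, "amount_of_demands"], times)
  effort_peak <- detect_peak_week(tr[, "effort"], times)
  stress_peak <- detect_peak_week(tr[, "stress_responses"], times)

  has_crash <- "crash" %in% ph$name
  crash_start <- if (has_crash) ph$start[ph$name == "crash"] else NA_real_
  crash_end <- if (has_crash) ph$end[ph$name == "crash"] else NA_real_

  post <- function(x, from) x[times >= from]
  demands_drop <- if (has_crash) {
    max(tr[times <= crash_end, "amount_of_demands"]) -
      min(post(tr[, "amount_of_demands"], crash_start))
  } else 0
  efficacy_drop <- if (has_crash) {
    max(tr[times <= crash_end, "perceived_efficacy"]) -
      min(post(tr[, "perceived_efficacy"], crash_start))
  } else 0

  plateau <- if (has_crash) {
    # plateau ends where the joint activity starts its sustained rise:
    # first post-crash slope exceeding 60% of the steepest later rise
    joint <- rolling_mean3((tr[, "amount_of_demands"] + tr[, "effort"]) / 2)
    idx <- which(times >= crash_end)
    d <- diff(joint[idx])
    if (!length(d) || max(d) < 0.01) {
      times[idx[length(idx)]] - crash_end
    } else {
      rise <- which(d > 0.6 * max(d))[1]
      times[idx[rise]] - crash_end
    }
  } else 0

  nfr <- tr[, "need_for_recovery"]
  nfr_threshold <- min(nfr) + 0.25 * diff(range(nfr))
  nfr_upturn <- times[which(nfr > nfr_threshold)[1]]
  nfr_lag <- if (has_crash) crash_start - nfr_upturn else NA_real_

  list(demands_peak_month = demands_peak,
       effort_peak_month = effort_peak,
       stress_peak_month = stress_peak,
       demands_drop = demands_drop,
       efficacy_drop = efficacy_drop,
       plateau_months = plateau,
       need_for_recovery_lag_months = nfr_lag)
}

#' Render a simulated trajectory as a scenario sketch
#'
#' Resamples a weekly simulation to the sketch's monthly grid and maps
#' model variables onto the seven perceived tracks (demands to amount of
#' demands, mental effort to effort, self-efficacy to perceived efficacy,
#' stress activation to stress responses; need for recovery is rendered
#' from exhaustion symptoms or depleted capacity, engagement from
#' motivation, resources from recovery time). Timelines are empty. The
#' result is a synthetic rendering, marked with `mechanism = "exhaustion"`.
#'
#' @param traj A [trajectory_set()] containing at least the four mapped
#'   variables.
#' @return A `scenario_sketch`.
#' @export
as_scenario_sketch <- function(traj) {
  needed <- c("demands", "mental_effort", "stress_activation", "self_efficacy")
  missing <- setdiff(needed, colnames(traj$series))
  if (length(missing)) {
    validation_error(paste0("cannot map trajectory to sketch; missing: ",
                            paste(missing, collapse = ", ")))
  }
  weeks_per_month <- 365.25 / 12 / 7
  months <- seq(0, floor(max(traj$times) / weeks_per_month))
  res <- function(v) {
    stats::approx(traj$times, traj_series(traj, v),
                  xout = months * weeks_per_month, rule = 2)$y
  }
  have <- function(v) v %in% colnames(traj$series)
  tracks <- cbind(
    amount_of_demands = res("demands"),
    effort = res("mental_effort"),
    perceived_efficacy = res("self_efficacy"),
    appropriateness_of_resources = if (have("recovery")) res("recovery") else
      rep(0.5, length(months)),
    engagement = if (have("motivation_to_meet_demands")) {
      res("motivation_to_meet_demands")
    } else res("self_efficacy"),
    need_for_recovery = if (have("symptoms_of_exhaustion")) {
      res("symptoms_of_exhaustion")
    } else 1 - res("capacity_for_effort"),
    stress_responses = res("stress_activation")
  )
  timelines <- list(
    interventions = data.frame(label = character(), time = numeric()),
    work_developments = data.frame(label = character(), start = numeric(),
                                   end = numeric()),
    private_developments = data.frame(label = character(), start = numeric(),
                                      end = numeric())
  )
  structure(list(times = months, tracks = clamp01(tracks),
                 timelines = timelines, mechanism = "exhaustion",
                 truth = NULL),
            class = "scenario_sketch")
}

#' Similarity between a simulated trajectory and a sketch
#'
#' Aggregates three bounded agreement components: presence and order of the
#' detected phases, concordance of the peak ordering of the four mapped
#' tracks, and co-timing of the crash (on the normalized time axis). The
#' score lies in \eqn{[0,1]}, equals 1 when the sketch was rendered from
#' the trajectory itself, and is symmetric in its arguments after mapping.
#'
#' @param traj A [trajectory_set()] or an already-rendered
#'   `scenario_sketch`.
#' @param sketch A `scenario_sketch`.
#' @return Similarity score in \eqn{[0,1]}.
#' @export
compare_sim_to_sketch <- function(traj, sketch) {
  a <- if (inherits(traj, "trajectory_set")) as_scenario_sketch(traj) else traj
  b <- if (inherits(sketch, "trajectory_set")) as_scenario_sketch(sketch) else sketch
  validate_sketch(a); validate_sketch(b)

  pa <- detect_phases(a)$phases; pb <- detect_phases(b)$phases
  common <- sum(pa$name[seq_len(min(nrow(pa), nrow(pb)))] ==
                  pb$name[seq_len(min(nrow(pa), nrow(pb)))])
  phase_score <- common / max(nrow(pa), nrow(pb))

  mapped <- c("amount_of_demands", "effort", "perceived_efficacy",
              "stress_responses")
  peaks <- function(s) {
    vapply(mapped, function(v) {
      detect_peak_week(s$tracks[, v], s$times) / max(s$times)
    }, numeric(1))
  }
  ka <- peaks(a); kb <- peaks(b)
  pairs <- utils::combn(length(mapped), 2)
  conc <- mean(apply(pairs, 2, function(ij) {
    sign(ka[ij[1]] - ka[ij[2]]) == sign(kb[ij[1]] - kb[ij[2]])
  }))

  crash_time <- function(p, s) {
    if ("crash" %in% p$name) p$start[p$name == "crash"] / max(s$times) else NA
  }
  ca <- crash_time(pa, a); cb <- crash_time(pb, b)
  timing <- if (is.na(ca) && is.na(cb)) 1 else if (is.na(ca) || is.na(cb)) 0 else
    1 - min(1, abs(ca - cb))

  mean(c(phase_score, conc, timing))
}

#' Write / read a scenario sketch as JSON
#'
#' The JSON layout matches the schema shipped at
#' `system.file("extdata", "scenario_sketch_schema.json", package =
#' "burnoutSD")`.
#'
#' @param sketch A `scenario_sketch`.
#' @param path File path.
#' @return `path` (write) or a `scenario_sketch` (read).
#' @export
write_sketch <- function(sketch, path) {
  validate_sketch(sketch)
  obj <- list(times = sketch$times,
              tracks = as.data.frame(sketch$tracks),
              timelines = sketch$timelines,
              mechanism = sketch$mechanism,
              truth = sketch$truth)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_sketch
#' @export
read_sketch <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tracks <- as.matrix(obj$tracks)
  dimnames(tracks) <- list(NULL, colnames(tracks))
  s <- structure(list(
    times = as.numeric(obj$times),
    tracks = tracks,
    timelines = lapply(obj$timelines, as.data.frame),
    mechanism = obj$mechanism,
    truth = obj$truth
  ), class = "scenario_sketch")
  validate_sketch(s)
  s
}
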