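---
title: "A stock-and-flow model of burnout development and recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stock-and-flow model of burnout development and recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burnoutSD)
```

## The modelling problem

Burnout is the outcome of a slowly deteriorating feedback system: demands,
invested effort, recovery, stress physiology and the person's own goals
interact over months to years. Cross-sectional antecedent models (job
demands-resources, effort-recovery, effort-reward imbalance,
challenge-hindrance appraisal) identify the ingredients but not the dynamics
that carry a person from engagement into exhaustion and — sometimes — back
out. `burnoutSD` implements that dynamic account as a system-dynamics (SD)
simulator: stocks accumulate (capacity for effort, stress, symptoms), flows
drain and refill them, and signed feedback loops decide which tendency
dominates when.

Everything in the package runs on dimensionless behavioural variables on
$[0,1]$ (low/mid/high read as 0/0.5/1) over a weekly time axis, integrated
with explicit Euler at `dt = 0.125` weeks by default. SD practice favours
Euler for behavioural models, the weekly phenomena of interest are two
orders of magnitude slower than this step, and the suite verifies the
scheme's first-order convergence, so higher-order integrators are
deliberately out of scope.

## The engine

`model_graph()` describes a model declaratively: variable roles (stock,
flow, auxiliary, constant), equations as R expression strings, stock
net-flow wiring, piecewise-linear `table_function()`s, and a signed causal
edge list. Design choices that matter for reproducibility:

* auxiliaries and flows must be acyclic given the stocks and are evaluated
  in topological order with an **alphabetical tie-break**, so evaluation
  order is never an accident of insertion order;
* declared-bounded variables are clamped to their interval after every
  evaluation/step (default band $[0,1]$) — the behavioural scales have no
  meaning outside it;
* `run_simulation()` is a pure function of (model, config, initial state):
  repeated calls are bit-identical, which the suite asserts;
* every declared edge polarity is checked against a central finite
  difference of the target's equation at the reference state
  (`check_edge_signs()`). The equations contain `min()`/`max()`
  saturations, so an edge routed through an inactive branch has an exactly
  zero derivative at any single state; the check treats zero as consistent
  (a flat response does not contradict a ceteris-paribus polarity) and only
  a strictly opposite sign fails.

Feedback loops are enumerated by a bounded depth-first search anchored at
each cycle's lexicographically smallest variable, which yields each simple
cycle exactly once in a canonical rotation; polarity is the parity of
negative edges. The test suite cross-checks the enumeration against an
independent brute-force subset/permutation search on two hundred random
signed digraphs.

First-order smoothing (`first_order_smooth_step()`) and goal-seeking stocks
(`goal_seek_step()`) share the same arithmetic — the distinction is kept
because goal-seeking targets are endogenous. Numerical honesty note: the
explicit-Euler value after one smoothing time differs from the continuous
exponential by $A e^{-1}/(2n)$ after $n$ steps. At $n = 100$ that bias is
about $1.3\times10^{-3}$ for a 0.7-amplitude transition; the tests assert
the bias against this closed form and require $10^{-3}$ agreement once $n$
is large enough for the bias to fall below it.

## The simplified capacity-effort-demands model

The two-stock illustration model couples a reinforcing and a balancing
loop: effort raises performance, which raises expected demands (a
goal-seeking stock), which pulls effort up again; meanwhile effort drains
the capacity stock, and a saturating lookup `f(capacity)` — flat near full
capacity, collapsing sharply once capacity is nearly spent — limits how
much effort the drained person can still supply:

$$\textit{effort} = \min(\textit{demands},\ f(\textit{capacity})),\qquad
\frac{d\,\textit{capacity}}{dt} = \textit{recovery} - \textit{load}.$$

The packaged reference parameterization was calibrated **once** and frozen:
recovery 0.042/week, load 0.12 per unit effort, performance-to-demand gain
1.10, demand adjustment time 4 weeks, breakpoints
$(0,0.25,0.5,0.75,1)\mapsto(0,0.25,0.85,0.97,1)$, starting well rested
(capacity 0.95, demands 0.35). Under these values the run shows the
canonical overshoot-and-collapse: effort peaks at week `r
detect_peak_week(traj_series(reference_run()$traj, "effort"),
reference_run()$traj$times)`, then tips over as capacity gives out, and the
system settles (every reported series inside a 2% band of its final value)
by week 49.5 at a capacity of 0.29 — far below the well-rested start. The
calibration knobs trade off against each other: a smaller
performance-to-demand gain delays the tipping point, a shorter demand
adjustment time speeds settling; the frozen set keeps the tipping point
after week 24 and settling before week 52 simultaneously.

`detect_settling_week()` defines settling as the earliest grid time after
which every selected series stays within `band` times its **overall
excursion** of its final value. Scaling the band by the excursion rather
than by the final value keeps the definition meaningful for series that
decay toward zero (a final-value-relative band degenerates there, and the
exponential-decay oracle $\tau\ln(1/\text{band})$ only holds for the
excursion reading) and makes constant series settle at the start. If only
the final grid point qualifies, the run is deemed never to settle and the
horizon is returned.

## The full burnout model

The full model wires four processes — regulating demands, regulating
effort, impacts on body and mind, burnout symptoms — into one graph with
five named loops, recovered and labelled by `verify_named_loops()` from
variable-set signatures:

| loop | polarity | mechanism |
|---|---|---|
| pressure to do more | reinforcing | effort raises performance, which ratchets the demand target |
| blinded by motivation | reinforcing | closing the gap boosts self-efficacy, hence motivation, hence effort |
| regulating demands | balancing | a visible gap triggers handing work over, lowering the composed demand |
| limits of the body | balancing | effort depletes capacity, which (belatedly) limits effort |
| learning to adjust goals and perception | balancing | declining symptoms after a crash trigger lasting downward goal adjustment |

The source publications for this structure print the causal diagram and
narrative, not the equations, so every functional form here is a
reconstruction constrained by the printed edge polarities, the
stock-integral/min-constraint/goal-seeking exemplars of the simplified
model, and the three qualitative persona patterns. Each form is the
simplest member of its class meeting those constraints and sits behind a
named rate helper so alternatives can be swapped. The load-bearing choices:

* **Demand composition.** Indicated demand = task load x requirements per
  task x (1 + 0.4 x hindrances), clamped; the demand stock goal-seeks
  toward the larger of that and performance x 1.5 (the pressure loop).
  Coping routes 2 and 3 act as relief terms: task load shrinks with
  (1 - expected consequences) x gap, requirements with (1 - work-goal
  relevance) — high stakes and high goal relevance block the routes.
* **Motivation.** work-goal relevance x expected consequences x
  (0.7 + 0.3 x self-efficacy). The product gates motivation at zero when
  either goal factor vanishes; the self-efficacy factor closes the
  blinded-by-motivation loop as a reinforcing cycle. Its floor of 0.7
  encodes that a spell of missed requirements dents, but does not abolish,
  the willingness to try again after rest — without the floor a first
  crash permanently locks effort low and no relapse cycle is possible.
* **Effort.** $\min(\textit{demands}\cdot m^{0.5},\ f(\textit{perceived
  capacity}))$. Perceived capacity is a first-order lag (7 weeks) of true
  capacity masked upward by motivation (gain 0.25): people notice their
  fatigue late, and more so when strongly motivated. The lag is what turns
  the limits-of-the-body loop from a gentle regulator into an
  overshooting one.
* **Stress and body.** Stress inflow scales with effort and with the
  motivation-weighted gap (a gap only stresses those who care), saturating
  at 1 - stress; relief scales with recovery, where recovery time is
  crowded out nonlinearly by effort (1 - 1.4 x effort, clamped). Capacity
  drains through effort and through stress **above the exhaustion-onset
  threshold** (0.55) only; below it stress is a healthy activation that
  costs nothing. This threshold is the relay that produces relapse cycles:
  above onset the body digs itself into a hole, the forced rest then
  releases stress below the threshold, capacity refills, and a
  non-learning person charges straight back in.
* **Symptoms and learning.** Exhaustion symptoms smooth (1 - capacity)
  over 6 weeks. Once symptoms cross the learning trigger (0.5) a one-way
  latch arms; while symptoms decline and the learning switch is on, the
  two goal stocks goal-seek toward learned resting levels (0.4) — each
  only if its own change switch allows. While un-latched, enabled goal
  stocks instead drift up toward their caps over 15 weeks: success
  inflates the importance attached to work, which is what makes the
  "dynamic" personas overcommit. With all switches off the goal stocks
  have exactly zero net flow and are bit-constant.

The shared non-scenario parameters were calibrated once against the three
persona patterns and frozen as the `burnout_params()` defaults; the
calibration search itself is not part of the package surface.

## Personas and pattern analytics

The three packaged personas differ in exactly seven parameters — caps and
initial values of the two goal stocks plus the three switches — and start
from one shared well-rested state. One hundred weeks at `dt = 0.125`:

* **P1** (caps 1/1, goals 0.6, all switches on) overcommits, crashes once
  (stress crosses 0.7 around week 14), learns, and settles into a
  sustainable regime with demands below their pre-crash peak.
* **P2** (goals 0.9, all switches off) cannot adjust goals or learn; the
  body-limit relay produces a sustained cycle of burnout episodes (six
  onset/release cycles in 100 weeks under the frozen calibration).
* **P3** (caps 0.5/0.7, switches on) is protected by the caps: motivation
  stays moderate, stress never reaches the episode threshold, cognition
  stays intact, self-efficacy stays stable.

`count_episodes()` operationalizes a burnout episode with hysteresis on
the stress-activation series: onset at 0.7, release at 0.4, minimum
duration 4 weeks. The thresholds are declared, not estimated — the source
narratives give no numeric episode definition — and the hysteresis exists
to keep near-threshold chatter from splitting episodes.
`classify_trajectory()` maps episode count and settling into the three
labels (`coping` / `single_episode_with_learning` / `cyclic`); the
classification is invariant to halving `dt`, which the suite checks.

## Synthetic retrospective sketches

No participant sketch data are distributed; `generate_sketch()` is a
declared synthetic stand-in for the retrospective graphs-over-time task:
seven perceived tracks (amount of demands, effort, perceived efficacy,
appropriateness of resources, engagement, need for recovery, stress
responses) on a monthly grid over 1-10 years, plus three labelled
timelines (interventions, work developments, private developments). Tracks
are piecewise-linear archetypes with the canonical build-up / crash /
recovery structure — demands and effort rise and drop suddenly; need for
recovery stays low for a long stretch then rises steeply; the recovery
phase opens with a lowered-activity plateau (default 6 months, the middle
of the reported 1-month-to-1-year range) before demands gradually return —
with seeded Gaussian noise and ground-truth phase boundaries attached. The
`reward_withheld` crash mechanism additionally drops engagement deeply and
keeps it low. What the generator does **not** emulate: idiosyncratic
multi-episode histories, non-stationary sketching scales, and recall
artefacts of real retrospectives — so a passing round trip validates the
segmentation logic, not clinical accuracy.

`detect_phases()` finds the crash at the steepest smoothed drop of the
joint demands+effort track and then places the boundaries on the raw
series (smoothing would bias the peak by a grid step); over one hundred
seeds at track noise 0.05 the segmenter recovers the phase order on all of
them with a mean boundary error of about 1.4% of the span (the acceptance
gate is 90% and 5%). `compare_sim_to_sketch()` scores simulation-sketch
agreement as the mean of three bounded components (phase order, peak-order
concordance of the four mapped tracks, normalized crash co-timing); it is
1 on self-derived sketches and symmetric by construction.

## Degenerate inputs and numerical edges

Non-finite equation values, cyclic auxiliary dependencies (reported with
the cycle named), inconsistent edge signs, inverted episode thresholds,
empty series and header-only CSVs all fail loudly with typed conditions.
Ties in peak detection resolve to the first occurrence; settling of a
constant series is the start time; a sketch without a detectable crash
returns a single low-confidence build-up phase rather than guessing.

## Known limitations

The model is a proof-of-concept reconstruction: its equations are
constrained by printed structure and qualitative patterns, not fitted to
longitudinal measurements, and the persona trajectories should be read as
pattern claims (which loop dominates when), never as quantitative
predictions for a person. Physiological submodels, team/organisation
interaction, intervention optimization and native Vensim/XMILE model
exchange are out of scope.
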