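---
title: "Monitoring home squat exercises from head-pose trajectories: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring home squat exercises from head-pose trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(squatcoach)
```

## The problem

Adherence to prescribed home exercise is a chronic weak point of outpatient
physiotherapy. A head-mounted AR coach can watch a patient perform squats —
the headset streams its own 6-DOF pose, which is a good proxy for the motion
of the upper body — count repetitions, flag execution errors in real time,
and summarize adherence for the treating physiotherapist. `squatcoach`
implements the computational core of such a system: a synthetic motion
generator standing in for the headset tracker, the monitoring engine,
five treatment-adherence dimensions (TADs), a coaching message engine, and
the statistics used to evaluate such systems in user studies.

The five adherence dimensions are:

* **TAD1** session completion rate: completed vs prescribed sessions;
* **TAD2** set completion rate: completed vs prescribed sets;
* **TAD3** exercise repetition rate: completed vs prescribed repetitions;
* **TAD4** temporal accuracy: executed vs prescribed movement velocity;
* **TAD5** spatial accuracy: executed vs prescribed movement trajectory.

## Coordinate conventions and calibration

Coordinates are metric and y-up: the floor is the plane $y = 0$, so the head
height *is* the vertical coordinate. Calibration (`calibrate()`) requires at
least 0.5 s of standing still (vertical spread under 5 cm) and stores

* the standing height $H$ as the mean head height above the floor,
* the footprint anchor (mean horizontal position — the patient is asked to
  stand on virtual footprints and stay there),
* the facing yaw from the mean orientation quaternion.

All deviation directions are resolved in this *facing frame*: "front" is the
direction the patient faces at calibration, "right" is `up x front`. This
makes every detection quantity invariant under rotating the whole scene about
the vertical axis, which the test suite verifies explicitly.

## The synthetic motion model

No published motion model accompanies the system we re-implement, so the
generator states one explicitly. Per repetition the vertical coordinate
follows a raised-cosine dip,

$$ y(u) = H - dH\,\tfrac{1}{2}\bigl(1 - \cos 2\pi u\bigr), \qquad u \in [0, 1], $$

with depth fraction $d$ (default 0.30, i.e. the head descends 30% of standing
height — a typical physiotherapist-demonstrated squat) and rep duration 3 s.
Repetitions are contiguous; each trajectory starts and ends with a 2 s still
stand used for calibration. Defaults that the deployed hardware leaves
unspecified were fixed once at realistic values: 30 Hz tracking (typical for
consumer headsets), i.i.d. Gaussian position noise per axis (0 by default;
5 mm is a realistic tracking jitter), and 2 cm of natural lateral sway.

Injected execution errors are realized geometrically so that ground truth and
detector can be compared rep by rep: a *depth* tag raises the dip bottom a
safety margin above the detection bound, *tempo* tags stretch or compress the
rep duration beyond the tolerance band, and *deviation* tags add a horizontal
raised-sine bump past the deviation radius in the tagged direction. The
generator is seeded and bit-reproducible.

What the generator does **not** emulate: full-body articulation, tracking
dropout, drift, knee kinematics, or fatigue-induced shape changes. A green
round-trip test therefore establishes that the monitor implements its stated
geometry correctly — not that it would survive every artifact of real
hardware.

## Repetition segmentation

Segmentation is a hysteresis state machine on the (lightly smoothed) vertical
coordinate: a rep opens when the head drops below
$(1 - f_\text{enter})H$ and closes when it recovers above
$(1 - f_\text{exit})H$, with $f_\text{exit} < f_\text{enter}$ so that noise
at a single threshold cannot double-count (standard debouncing). Defaults:
enter 0.10, exit 0.05 — conservative values, exposed in `thresholds()`,
because the deployed system's numeric cutoffs were never published.

Threshold crossings alone under-estimate rep duration (they clip the shallow
start and end of the movement), while the tempo comparison wants the full
stand-to-stand time. Boundaries are therefore placed at the midpoint between
one dip's recovery crossing and the next dip's entry crossing of the outer
threshold — exact for symmetric dips performed back to back — with symmetry
about the dip bottom supplying the outermost boundaries. An isolated single
dip has no neighbor to exploit, so it falls back to the crossings themselves
and its duration is an underestimate; tempo judgments on single-rep
trajectories should be treated with care. When a performer rests between
reps, half of each pause accrues to the neighboring reps' measured durations;
the default 30% tempo tolerance absorbs realistic pauses.

The light smoothing (a centered moving average of about 0.15 s) only
stabilizes threshold crossings under sensor noise; bottom heights and
horizontal excursions are measured on raw samples.

## Error detection

For each segmented rep, against the reference profile (bottom fraction
$b_\text{ref}$ and duration $T_\text{ref}$, either prescribed or measured
from a physiotherapist recording via `reference_profile_from_trajectory()`):

* **depth**: fires iff $y_\text{bottom}/H > b_\text{ref} + \delta$
  (default $\delta = 0.05$); magnitude is the fractional exceedance scaled to
  meters.
* **tempo**: fast iff $T < T_\text{ref}(1 - \tau)$, slow iff
  $T > T_\text{ref}(1 + \tau)$ (default $\tau = 0.30$); magnitude in seconds
  beyond the bound.
* **deviation**: at most one event per rep, fired iff any horizontal
  excursion from the footprint anchor exceeds the radius (default 0.15 m),
  labeled left/right/front/back by the *dominant* exceedance in the facing
  frame. One event per rep (rather than per sample) matches the granularity
  of spoken per-rep feedback and keeps weekly error counts well defined.

Error kinds within a rep are unique, so a rep contributes at most one depth,
one tempo and one deviation event.

## Adherence computation

`completion_rates()` computes TAD1–TAD3 as capped percentages: a session
counts toward TAD1 when at least one set was completed (the published trial
counted a 2-of-3 vacation week without partial credit); a set counts when it
reached the prescribed rep count; per-set rep credit is capped at the
prescription, and surplus reps are logged but earn no credit, so
over-performance can never push a rate above 100%. TAD4 and TAD5 are
operationalized as the percentage of completed reps free of tempo errors
(TAD4) and free of depth/deviation errors (TAD5) — the source system defines
these dimensions as actual-vs-prescribed accuracy without giving a formula,
and error-free rep fractions are the natural dashboard rendering of that
idea. Exact values are kept internally; displays round to whole percent
(11/12 prints as 92%).

Weekly error counts (`weekly_error_aggregate()`) group events by the
session's week index and zero-fill empty weeks; their sum always equals the
total event count. The published per-week error box plot values are not
recomputable from the publication (the raw logs are unpublished), so the
conservation property is what the tests pin down. Likewise the published
"errors in the first/last three sets, 8 vs 4" row is reproduced as raw
counts only — the denominators behind its printed percentages are not
stated.

## Coaching engine

`realtime_cue()` maps each error kind deterministically to a corrective
utterance; the insufficient-depth cue is the system's canonical
"A little bit lower.". `countdown_and_progress()` reproduces the counting
script: the last three reps of a set are counted down and the set boundary
gets a completion-and-break message. `schedule_reminders()` plans the
smartphone channel: `round(rate x weeks)` messages, the remainder spread to
the earliest weeks (17 messages over 4 weeks gives 5, 4, 4, 4 and a mean of
4.25/week), days drawn with seeded jitter, intents rotating through reminder,
psychoeducation and progress, and text variants randomized under a
no-immediate-repeat rule. Message texts are catalog content (editable JSON in
`inst/extdata/`), not code, because the full deployed scripts were never
published; they carry behavior-change-technique (BCT) tags such as BCT 19
(feedback on behavior). `progression_rules()` makes tutorials skippable and
explanations short from week 2 once at least one session is on record.

## Evaluation statistics

`wilcoxon_one_sample()` tests Likert responses against the neutral scale
value (default 4). Zero differences are discarded, ties get midranks, and for
effective $n \le 25$ the null distribution of the positive-rank sum is built
by convolution over the doubled midranks — arithmetically identical to
enumerating all $2^n$ sign assignments, which is what the test suite's
independent oracle does. The two-sided p doubles the smaller tail, capped
at 1. Beyond $n = 25$ a normal approximation with tie correction and
continuity correction is used. `base::wilcox.test` cannot produce exact
p-values under ties, which is why the exact path is authored here; it serves
as a cross-check oracle on tie-free samples.

A note on the type-I acceptance check: with discrete Likert data an exact
test is conservative, and at small samples visibly so (empirical size about
0.038 at $n = 10$). The check simulates the lab-study scale ($n = 35$
raters), where discreteness is mild and the empirical size lands inside a
four-standard-deviation Monte-Carlo band around the nominal 0.05.

`t_one_sample()` works from summary statistics
($t = (\bar{x} - \mu)/(s/\sqrt{n})$, $df = n - 1$), matching how such tables
are reported. The Net Promoter Score uses the instrument's standard 0–10
item (promoters 9–10, detractors 0–6; configurable, since the deployed scale
was not stated) and the published category bins: a score of at most 0 "needs
improvement", up to 30 "good", up to 70 "great", above that "excellent".

## Numerical and degenerate-input choices

* Calibration fails loudly (classed condition) on under 0.5 s of data or
  more than 5 cm vertical spread; flat trajectories yield an
  unusable-reference condition; all-neutral samples a degenerate-sample
  condition.
* Threshold crossings are linearly interpolated between samples.
* Boundary NPS scores land in the bin whose printed range contains them
  (0 is "needs improvement", 30 "good", 70 "great").
* All randomness (noise, reminder jitter, variant choice) flows from
  explicit integer seeds; identical seeds give bit-identical outputs.

## A worked session

```{r}
prof <- sim_profile(noise_sd = 0.005, seed = 42)
rx <- exercise_prescription(sessions_per_week = 3, weeks = 4,
                            sets_per_session = 3, reps_per_set = 10)
plan <- error_plan(c(rep("none", 4), "depth", rep("none", 20), "dev_left",
                     rep("none", 4)))
sim <- simulate_squat_session(prof, rx, plan)
calib <- calibrate(subset_trajectory(sim$trajectory, 0, 1.9))
ref <- reference_profile(0.70, 3.0)
record <- monitor_session(sim$trajectory, rx, calib, ref)
record
record$errors
```

## Known limitations

Head pose is a proxy: errors expressed only below the neck (knee valgus,
heel lift) are invisible to this geometry, which is why the deployed system's
knee-alert scenario stays out of scope. The simulator's symmetric dips make
the boundary-placement rule exact; strongly asymmetric real executions would
bias measured durations by a fraction of the asymmetry. Reference comparison
is scalar (bottom fraction, duration) rather than full-trajectory DTW; the
publication does not specify which the deployed system used, and scalar
features are sufficient for the published error taxonomy.
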