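---
title: "Modelling reach adaptation from prediction and performance errors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling reach adaptation from prediction and performance errors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachadapt)
```

## The scientific problem

When a reach is perturbed — the cursor is rotated, the target jumps —
two distinct error signals can arise. A *sensory prediction error*
(SPE) is the mismatch between the cursor motion the motor system
predicted and what it saw; it is thought to drive slow, implicit
recalibration of the visuomotor map. A *task performance error* (TPE)
is the binary failure to hit the target; competing accounts hold that
TPEs independently drive implicit learning, that they gain-modulate
SPE-driven learning, or that they merely trigger deliberate re-aiming
strategies. Error-clamp designs dissociate the two signals: the cursor
follows a fixed direction regardless of the hand, so the visual error
is constant, and target size or position manipulations decide whether
the clamped cursor hits or misses.

`reachadapt` packages the computational machinery for this programme:
the learning models, the trial schedules of four such experiments, the
kinematic reduction of raw trajectories to cycle-averaged hand
deviations, the constrained fitting and bootstrap procedures, and a
synthetic cohort generator that closes the loop for parameter-recovery
studies.

## Models and state timing

All models are linear state-space learners updated once per 10-trial
cycle, the resolution at which the data are averaged and fitted. The
state `x(n)` is the predicted (baseline-corrected) hand deviation on
cycle `n`; the update from cycle `n` uses the drive present on cycle
`n`, so the first learning cycle is predicted at the pre-learning
level and the response builds from the next cycle on. The initial
state is 0 at the first baseline cycle because the data are
baseline-corrected.

Because the clamp holds the visual error constant, the learning-rate ×
error product cannot be separated and is estimated as one lumped drive
parameter (`B_spe_drive`, `B_tpe_drive`, degrees/cycle). Drives act
only on cycles where the corresponding error is present: learning
cycles for the SPE under a clamp, learning cycles on which the clamped
cursor geometrically misses the (possibly jumped) target for the TPE.
On no-feedback washout cycles there is no cursor, hence no SPE drive;
we also zero the TPE drive there, since without a cursor there is no
outcome information either (only the SPE zeroing is forced by the
design; the TPE zeroing is this package's choice and is inert in
practice because those cycles carry no TPE in any built design).
Feedback-washout cycles are excluded from fitting altogether
(`fit_mask`): once the clamp is removed the error varies with the hand
and the lumped-drive parameterization no longer applies.

Two printed variants of the Independent Error model's SPE update exist
(retaining the process's own state vs the net output). We default to
self-retention, which preserves the additive decomposition
`x = x_spe + x_tpe`; the net-retention variant is available via
`simulate_independent(..., retention = "net")` for sensitivity
analyses. Similarly, the TPE update is implemented as a first-order
recursion in its own state, the form consistent with the additive
model. In the Interaction model the gains are fixed at 1 on TPE-present
cycles by definition and take the fitted values `G_A`, `G_B` elsewhere.

## Fitting

Fits minimize the unweighted sum of squared residuals between a model
trace and the *group-mean* cycle series, over baseline, learning and
no-feedback washout cycles. Parameters are box-constrained: retention
factors in [0, 1]; lumped drives in [0, `drive_bound_deg`], where the
bound is the maximum error angle the design can impose (10° for the
10°-jump experiments; generalized to 30° for the 30°-clamp experiment,
where the original bound's rationale — the largest possible per-trial
error — implies that value); gains in [0, 3], wide enough to contain
plausible estimates and their CIs while excluding unstable dynamics.

The optimizer is L-BFGS-B restarted from 20 seeded uniform draws inside
the box (first start at the box midpoint), best objective wins, ties
going to the first found. On these smooth 2-parameter problems the
multi-start is insurance against the rare boundary-basin start; tests
verify agreement with an exhaustive grid search (steps 0.01 on
retention, 0.05 on drives) to within one grid step of objective.

The two sequential protocols mirror the experimental logic:

* **Independent Error**: fit the SPE process alone to the TPE-free
  group; freeze those estimates; fit `A_tpe`, `B_tpe_drive` to the
  TPE-exposed group's net output.
* **Interaction**: fit `A_spe`, `B_spe_drive` to the TPE-exposed group
  with gains pinned at 1 (they are inert there); freeze; fit `G_A`,
  `G_B` to the TPE-free group.

`R²` and RMSE are computed over the fitted (masked) cycles by default —
the fit domain — with the mask argument of `goodness_of_fit()`
available to score other windows.

### Bootstrap

95% CIs are percentile intervals from refits to cohorts resampled by
participant with replacement (the conventional unit when the estimand
is a group-mean fit; trial resampling would break the cycle structure).
Stage-1 frozen parameters stay at their full-sample estimates
throughout, matching a protocol that bootstraps only the stage-2
group's data. Bootstrap refits start from the full-sample point
estimate plus a reduced number of random restarts (default 3 total):
the resampled objectives are small perturbations of the original, so
the full 20-start battery would only repeat the same optimum. Results
are deterministic given the seed.

## Kinematic pipeline

Raw tablet trajectories are low-pass filtered with a 10-Hz Butterworth
filter applied forward and backward (zero phase). The order is
configurable and defaults to 4, the common choice in reach kinematics;
edge transients of the forward-backward pass are suppressed by
odd-symmetric reflection padding. Velocity comes from central
differences on the filtered positions (one-sided at the ends).
Movement onset is the first sample at which speed crosses 5% of the
trial's peak; RT is onset time minus the go cue. Hand deviation is the
signed angle (counterclockwise positive, wrapped to (−180°, 180°])
between the start→original-target line and the start→hand line at peak
speed, with the peak searched between onset and the first crossing of
the 10-cm reach distance (where the cursor froze), falling back to the
whole trial.

Exclusions: trials with no movement (peak speed below 2 cm/s — the
floor is a package choice; the experiments only report "did not
initiate a movement"), stylus lifts, and absolute deviations strictly
greater than 85°. Baseline bias is each subject's mean deviation over
all valid baseline trials (both sub-blocks) and is subtracted from
every trial. Cycle means use valid trials only; an all-invalid cycle
propagates as missing and is skipped by the fit mask. Phase metrics
average exactly the defining 10-trial windows (first/last 10 learning
trials, first 10 of each washout sub-block, last 10 washout trials; RT
change = first 10 learning minus last 10 baseline trials).

For the clockwise-perturbation groups, deviations are negated at load
(`read_trial_table()`) so compensation is positive in every design and
groups can be pooled; schedules already store jumps sign-normalized.

## Synthetic cohorts

The generator emulates the behavioural structure the analysis assumes,
at two resolutions. `generate_cycle_traces()` adds independent
Gaussian per-cycle noise to a model trace — the cheap path for fitting
studies. `generate_raw_trials()` builds full trajectories: straight
reaches along the intended angle (strategic aim + implicit state +
trial-level Gaussian angular noise), a minimum-jerk radial profile
covering 12 cm at 100 Hz (any profile with a unique interior speed
maximum would do), and RTs that are lognormally jittered around a
300-ms median, raised by 150 ms on strategy trials to reflect the
time cost of deliberate re-aiming (within the range of early-learning
RT elevations reported for jump-responding groups). The profile is
positioned so the analytic 5%-of-peak crossing falls on the programmed
onset, making the programmed RT recoverable by the pipeline's own
onset rule to within one sample.

Aim policies encode the instructed behaviour: `aim_original` /
`ignore_jump` aim at the original target, `aim_jumped` re-aims at the
jumped target after a configurable lag (default 2 learning trials,
reflecting that re-aiming emerges within a few trials). The implicit
state rides on top of the strategic aim in all cases.

Noise defaults (3° trial-level, 1.5° cycle-level) are fixed, realistic
values chosen to produce group SEM bands comparable to published
learning curves; they are not estimates from data. What passing
recovery tests show is that *given* this structure — straight reaches,
stationary Gaussian noise, deterministic policies — the pipeline and
fitter are unbiased at the study's cohort sizes (10–15 subjects). Real
data add curvature, online corrections, non-stationary noise and
subject heterogeneity that the generator deliberately omits; recovery
on synthetic cohorts is therefore a necessary, not sufficient,
validation.

In recovery runs on strategy cohorts, `run_recovery()` subtracts the
known strategic component before fitting, so the fitted parameters
describe the implicit process that generated them — legitimate only
because ground truth is available by construction.

## Numerical choices and degenerate inputs

* Optimizer tolerance: `factr`-style relative objective tolerance of
  1e-9; parameter recovery on noiseless series is exact to ~1e-3 or
  better.
* Zero-variance observed series: `R²` is undefined and returned as `NA`
  with a warning; RMSE is still reported.
* A cycle with no valid trials yields `NA` and is dropped from the fit.
* `asymptote()` requires retention < 1; simulations accept the closed
  [0, 1] box.
* Angle wrapping maps to (−180°, 180°]; a deviation of exactly 85° is
  retained by the exclusion rule (strict inequality).
* The fixed pseudo-random target order shared by all participants is
  realized by a fixed default seed recorded on the schedule.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script simulations use the designs' real
trial counts (320- and 400-trial schedules) with cohorts of 15
subjects; stochastic checks use 100 replicate cohorts for recovery
error and 50 replicate cohorts × 1000 bootstrap resamples for CI
coverage — sizes at which Monte-Carlo error is small relative to the
thresholds being checked, while a full run stays in the minutes range
on one core. Headline bootstrap analyses in application code default
to 10,000 resamples.

## Known limitations

* The within-trial timing of the target jump (mid-reach) is a schedule
  attribute only; within-trial dynamics and online corrections are not
  modelled.
* No Kalman/Bayesian learners, two-rate fast/slow dynamics, or
  trial-varying error-sensitivity functions; errors are lumped
  constants under the clamp.
* Model comparison is by experimental design (which model's
  predictions survive each manipulation), not information criteria.
* Bayes factors occasionally reported alongside frequentist tests in
  this literature are not computed here.
* The deposited behavioural dataset of the motivating experiments is
  not redistributed; `run_reproduction()` provides the loader and
  protocol to re-fit it when available locally.
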