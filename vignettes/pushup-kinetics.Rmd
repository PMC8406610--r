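---
title: "Whole-body kinetics of the plyometric push-up from one or two force platforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-body kinetics of the plyometric push-up from one or two force platforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pushupkin)
```

## The measurement problem

During a push-up the body is supported at two contact sets — hands and feet —
so the total vertical ground reaction force (GRF) is the sum of both
components. Whole-body (center-of-mass, COM) vertical kinetics follow from
Newton's second law: with `F(t)` the total vertical GRF, `m` body mass and
`g` gravity,

    F(t) = m (g + a(t)),

and by the impulse–momentum theorem the COM velocity from a stationary start
at `t_start` is

    v(t) = (1/m) * integral from t_start to t of (F(tau) - m g) dtau,

with whole-body power `P(t) = F(t) v(t)`.

Many labs have only one force platform. The common workaround places it under
the hands and **assumes the feet force is constant** at its static starting
value, `F_feet = BW - F_hands(start)`. This package implements both
computations side by side:

* **two-platform method**: `F(t) = F_hands(t) + F_feet(t)`, both measured;
* **one-platform method**: `F(t) = F_hands(t) + (BW - F_hands_static)`.

The scientific point is that the constant-feet assumption fails
systematically: as the performer descends, the COM travels along an arc
around the fixed toes and shifts load onto the hands, so the measured feet
force drops below its static value through most of the movement and only
rises again near takeoff. The one-platform method therefore overestimates
the feet impulse, hence velocity, hence power. The package makes that bias
measurable, on real exports or on synthetic recordings with known ground
truth.

## Pipeline and its parameters

`analyze_trial()` runs, in order:

1. **Filtering** — 4th-order low-pass Butterworth, 100 Hz cutoff, applied
   forward and backward (zero phase, unit DC gain). Only the cutoff is a
   scientifically reported constant; the order and the zero-phase choice are
   this package's decisions. Zero phase matters because events are detected
   by threshold crossings: a causal filter would delay every crossing by the
   group delay. We use the nominal cutoff per pass with no double-pass
   cutoff correction, and reflect the trace at both ends (each filtering
   pass is also run relative to its starting value) so that no startup
   transient contaminates the static baseline window. At a 100 Hz cutoff and
   1000 Hz sampling the passband (< ~10 Hz, where push-up signal content
   lives) is flat to well under 1%.
2. **Baseline** — means of the filtered traces over the first 0.5 s
   (configurable), which must be quiescent (SD < 10 N per trace, a generous
   bound for a static hold). In two-platform mode body weight is
   `hands_static + feet_static` and mass is derived; in one-platform mode
   mass must be supplied and `feet_static = m g - hands_static`. Whether the
   "starting position" reference should be a single sample or a window mean
   is not standardized; we use the window mean, which is the lower-variance
   choice and exact on quiescent data.
3. **Phase detection** — on the filtered hands trace: the push-up begins at
   the first sample strictly more than 15 N below the static hands force,
   and ends (takeoff) at the first subsequent sample strictly below 15 N.
   First crossing, strict inequalities, sample resolution, no debouncing:
   the simplest fully reproducible reading of the threshold rules. The 15 N
   reference for onset is the static baseline — the only force value
   available as a reference before movement begins. Phases shorter than
   0.1 s are rejected as physiologically implausible. Note the inherent
   detection delay: any force threshold is crossed only once the movement
   has unloaded the hands by that amount, so with a smooth acceleration
   onset the detected start lags the true movement start by tens of
   milliseconds (≈45 ms at the simulator's defaults). The velocity error
   this induces is negligible (< 0.01 m/s) because the integrand is tiny
   near onset, and we verify detection instead against the analytically
   root-found crossing time, where agreement is exact to the sample.
4. **Kinetics** — velocity by cumulative trapezoidal integration of
   `F - m g` over the phase with `v(start) = 0` (the impulse–momentum
   theorem requires a known initial velocity; participants hold a static
   position, so zero), both endpoint samples included; power as the
   elementwise product.
5. **Variables** — eight outcomes per method, forces normalized by body
   weight (dimensionless BW), power by body weight in newtons (W/BW,
   numerically equal to velocity at that sample): peak hands GRF, peak
   whole-body GRF, peak velocity, peak power, feet GRF at start, mean feet
   GRF over the phase, and whole-body GRF and velocity at the sample of
   peak power. Peaks are maxima of the signed upward-positive series
   (descent-phase negative velocity can never win); ties resolve to the
   first occurrence. For the one-platform method the mean feet GRF equals
   the start value by construction, and the hands-derived and start
   variables are identical across methods.

Two useful identities connect the methods and are asserted in the tests:

* impulse difference: `v_one(t) - v_two(t) = (1/m) * integral of
  (feet_static - F_feet)`, exactly (both sides are the same trapezoid sums);
* dominance: if `F_feet(t) <= feet_static` throughout the phase, then
  `v_one >= v_two` pointwise, so the peak-velocity and peak-power ordering
  follows.

The pipeline is homogeneous of degree zero under joint rescaling of forces,
mass and the detection threshold; because the 15 N threshold is an absolute
force, rescaling forces alone shifts the detected phase edges slightly.

## The synthetic push-up generator

No public raw data exist for this movement, so `simulate_trial()` constructs
mechanically consistent recordings from closed forms, giving every pipeline
stage an analytic oracle:

* **COM acceleration** `a(t)`: zero during a 1 s quiet hold; a raised-cosine
  negative lobe (descent, default peak −3 m/s² over 0.40 s); a raised-cosine
  positive lobe (push, default peak +4.3 m/s² over 0.70 s); then a
  smoothstep tail falling to −0.9 g over 0.12 s as the hands unload and the
  upper body becomes ballistic. Raised cosines are continuous and
  differentiable and integrate in closed form, so the ground-truth velocity
  is exact, not numerical.
* **Load sharing** `s(t)` (feet share of total force): starts at the static
  share (default 0.34), descends by a cubic smoothstep to a dipped value
  (default dip 0.08) during the descent, holds through the push, and rises
  to 0.90 during the tail. Then `F_feet = s·m(g+a)`,
  `F_hands = (1−s)·m(g+a)`: force conservation holds exactly pre-noise, the
  feet force shows the characteristic dip-then-rise, and the hands force
  falls through the 15 N takeoff threshold inside the tail (the exact
  crossing is root-found and stored as ground truth).
* **Noise**: additive white Gaussian per platform (default SD 5 N for
  cohorts, a realistic figure for strain-gauge platforms at 1000 Hz); no
  platform-resonance model, since the 100 Hz filter removes most realistic
  structured noise anyway.

Defaults were calibrated once, from the published cohort-level pattern these
simulations are meant to emulate: static feet share 0.34, peak whole-body
force ≈ 1.44 BW (peak push acceleration 0.44 g), two-platform peak velocity
≈ 0.9 m/s, phase-mean feet share ≈ 0.30, one-platform peak velocity
≈ 1.4 m/s. They are conditions of the simulated experiment, not tuning
knobs.

`simulate_cohort()` draws per-participant parameters from sex-specific
truncated normal distributions (`cohort_spec()`): males heavier
(77 vs 63 kg), loading the hands more (static feet share 0.33 vs 0.36,
deeper dip 0.09 vs 0.06) and pushing harder (peak acceleration 4.77 vs
3.77 m/s², chosen so mean peak velocities land near 1.07 and 0.72 m/s).
Seeding is hierarchical — participant `i`, trial `j` uses
`seed + 1000 i + j` — so streams are independent and every byte is
reproducible.

**What the generator does not emulate**: horizontal forces and the true
rigid-body mechanics of the arm–trunk–leg chain; within-participant
technique variability across trials (trial-to-trial variation is sensor
noise only); platform drift or resonance; landing after flight. Passing
tests therefore demonstrate the correctness of the computations and the
direction and rough magnitude of the one-platform bias under plausible
load-sharing trajectories — not agreement with any specific human cohort.
One visible consequence: with the default dip (0.08) the measured feet
force at the push peak slightly exceeds the assumed constant, so the
simulated one-platform peak *force* comes out marginally lower than
two-platform, whereas published human means show the opposite (and tiny)
difference; the velocity and power biases, which are the substantive
findings, reproduce robustly.

## Statistics

`build_comparison()` reproduces the method-comparison statistical layer on a
cohort's variables table. Trials are averaged per participant first (the
standard guard against pseudo-replication; the aggregation rule is this
package's choice). Method rows use paired t-tests, sex rows independent
pooled-variance t-tests, each with mean difference and 95% CI; Shapiro–Wilk
normality p-values are reported but never gate anything.

Cohen's d uses the pooled-SD form `|m_a − m_b| / sqrt((sd_a² + sd_b²)/2)` for
both paired and independent comparisons, with bands trivial (< 0.2), small
(< 0.5), moderate (< 0.8), large (≥ 0.8). Published worked examples
reproduce under this form to two decimals from printed means and SDs
(e.g. `cohens_d(0.90, 0.23, 1.39, 0.37)$d` = `r round(cohens_d(0.90, 0.23, 1.39, 0.37)$d, 2)`);
a difference-score variant for paired data is available as
`cohens_d_paired()`. Correlations default to Spearman with strength bands
(minor ≤ 0.3 < moderate ≤ 0.5 < large ≤ 0.7 < very large ≤ 0.9 < perfect);
the regression column is an OLS fit predicting the two-platform value from
the one-platform value, reporting slope, intercept and Pearson r² (so the
printed r² is internally consistent with the regression even when the
correlation column is rank-based). Variables identical across methods by
construction (peak hands GRF, feet GRF at start) carry blank comparison
cells. Significance is α = 0.05 with no multiplicity correction, matching
standard practice in this literature.

Calibration of the inference is checked by simulation at the variable level
(n = 34 pairs, measurement-difference SD 0.1): the paired test's type-I
error over 2000 null cohorts must land in [0.03, 0.07], and 95% CI coverage
of a known 0.49 m/s method difference over 1000 cohorts in [0.93, 0.97].

## Numerical choices and degenerate inputs

* Trapezoidal integration error is O(dt²): on raised-cosine accelerations at
  1000 Hz the velocity error is below 1e-5 m/s, and halving the step cuts it
  ≈4×, both asserted in the tests.
* Sampling rate is inferred from the file's time column (median step; steps
  must be uniform within 1% jitter and strictly increasing), never trusted
  from configuration; a mismatch with the expected rate only warns.
* Zero-variance paired differences make the t statistic undefined: flagged
  `degenerate`, p = NA, never an exception mid-table.
* Constant vectors are rejected by `correlate()` and (for x)
  `simple_regression()`; both SDs zero is rejected by `cohens_d()`.
* Results files print numerics at 15 significant digits so a write-read
  round trip preserves values to better than 1e-9 relative.

## Problem sizes used in the checks

The shipped verification suite simulates trials of ≈2.2 s at 1000 Hz
(≈2200 samples), cohorts of 34 participants for ground-truth recovery, 100
randomized trials for the dominance property, 1000 randomized traces for the
phase-detection scan oracle, and 2000/1000 value-level cohorts for the
inference calibration — sizes chosen to exercise the estimators at the
study's own scale while keeping the full suite fast enough to run on every
change.

## Known limitations

* Single-repetition trials only; repeated push-ups in one record and the
  landing after flight are out of scope.
* Vertical forces only; no center-of-pressure or 3-axis channels, no
  proprietary binary force-plate formats.
* The regression equations a comparison produces are, like any such
  equations, population-specific; the synthetic cohort is a model, so its
  coefficients should not be transferred to human data.
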