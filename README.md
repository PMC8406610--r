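# pushupkin

Whole-body kinetics of the plyometric push-up from force-platform
recordings, for biomechanists and strength-and-conditioning scientists who
need velocity and power outcomes from this movement — and who need to know
how much those outcomes are biased when only one platform (under the hands)
is available.

## The science in brief

During a push-up the body is supported at the hands and the feet, so the
total vertical ground reaction force (GRF) is `F(t) = F_hands(t) +
F_feet(t) = m (g + a(t))`, with `a(t)` the vertical center-of-mass
acceleration. By the impulse–momentum theorem, from a stationary start,

```
v(t) = (1/m) ∫ (F(τ) − m g) dτ ,      P(t) = F(t) · v(t).
```

With two synchronized platforms both force components are measured
(**two-platform method**). With a single platform under the hands the feet
force must be assumed constant at its static value `BW − F_hands(static)`
(**one-platform method**). That assumption is wrong in a specific way: as
the performer descends, load shifts from the feet onto the hands, so the
measured feet force runs *below* its static value through most of the
movement. The one-platform method therefore overestimates the feet impulse,
hence whole-body velocity and power.

The package implements the full pipeline for both methods — zero-phase
100 Hz Butterworth filtering, static-baseline estimation, 15 N
threshold-based phase detection (onset: hands force 15 N below static;
takeoff: hands force below 15 N), trapezoidal impulse–momentum velocity,
power, and eight body-weight-normalized outcome variables — plus a
mechanistic synthetic GRF generator with closed-form ground truth, and the
method-comparison statistics (paired/independent t-tests, pooled-SD Cohen's
d with interpretation bands, Spearman correlations with strength bands,
OLS regression to predict two-platform values from one-platform values).

## Worked example

```r
library(pushupkin)

# one noiseless synthetic trial at the default calibration
sim <- simulate_trial(sim_params(noise_sd_N = 0))
fit <- analyze_trial(sim$recording)
fit
#> Plyometric push-up kinetics
#>   trial:    P1 / T1
#>   body weight: 688.7 N (70.2 kg); static split hands 66% / feet 34%
#>   phase:    1.046-2.202 s (1157 samples @ 1000 Hz)
#>   two_platform: peak v 0.91 m/s, peak power 0.96 W/BW, peak GRF 1.44 BW
#>   one_platform: peak v 1.41 m/s, peak power 1.52 W/BW, peak GRF 1.40 BW
```

The one-platform method reports a peak velocity of 1.41 m/s against the
true (two-platform) 0.91 m/s — a ~0.5 m/s overestimate caused entirely by
the feet-force dip. At cohort level (17 + 17 simulated participants, three
statistics rows shown):

```r
coh  <- simulate_cohort(n_per_sex = 17, seed = 42)
vars <- analyze_cohort(coh)
build_comparison(vars, grouping = "method")
#> Push-up method-comparison table (grouping: method; a = two_platform, b = one_platform)
#>
#>   peak_wholebody_velocity_mps             0.88 +/- 0.27 vs  1.36 +/- 0.40   d = 1.42 (large), p = 0.0000
#>   peak_wholebody_power_WperBW             0.94 +/- 0.32 vs  1.47 +/- 0.46   d = 1.34 (large), p = 0.0000
#>   mean_feet_grf_BW                        0.30 +/- 0.04 vs  0.34 +/- 0.04   d = 1.16 (large), p = 0.0000
```

Velocity and power are overestimated with large effect sizes, while the
start-position feet share (0.34 BW) and peak hands GRF are identical across
methods by construction — the structure of a method-validity table. Stored
regressions convert one-platform measurements into predicted two-platform
values:

```r
comp <- build_comparison(vars, grouping = "method")
predict(comp, 1.40, "peak_wholebody_velocity_mps")
#> [1] 0.900675
```

Real exports are read with `read_recording()` (CSV/TSV with `time_s`,
`fz_hands_N`, optionally `fz_feet_N`; the sampling rate is inferred from the
time column), and `write_results()` emits the per-trial variables and series
tables. Batch work goes through `cmd_simulate()` / `cmd_analyze()` /
`cmd_compare()` or the thin shell wrapper in `inst/cli/pushupkin`.

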