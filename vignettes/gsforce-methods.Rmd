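---
title: "Turn kinetics and force application effectiveness in giant slalom: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Turn kinetics and force application effectiveness in giant slalom: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsforce)
```

This vignette documents the models, conventions and numerical choices behind
`gsforce`. The package turns two raw sensor streams from a giant-slalom run
— dual ski-mounted force plates at 200 Hz and a body-worn GNSS
centre-of-mass (COM) trajectory at 10 Hz, on independent clocks — into
per-turn kinetic and kinematic metrics and a stepped statistical model of
turn performance, and ships a synthetic generator with ground truth so the
whole chain is testable without field data.

## Coordinate frame and the physics of a turn

All geometry lives in a slope-fixed Cartesian frame: `x` lateral (along the
contour line), `y` the horizontal projection of the fall line (positive
downhill), `z` altitude. The slope is an inclined plane with relief `α`.
With `ξ` the along-slope fall-line distance and `w` the lateral coordinate
on the plane, world coordinates are `x = w`, `y = ξ·cosα`, `z = −ξ·sinα`.

**Radial force.** The component of the snow-reaction force (SRF) that turns
the skier is, per unit mass and expressed in bodyweight (BW) units,

$$F_r = \frac{1}{g}\left(\frac{v^2}{r} \pm g\,\sin\alpha\,\cos\beta\right),$$

the sum of the centripetal term and the radial component of gravity on the
inclined plane. Two conventions here were genuinely open and are fixed as
follows:

- **β is the heading angle to the contour line** (the across-slope
  horizontal direction), not to the fall line. Newton fixes this choice:
  the in-plane gravity component `g·sinα` points down the fall line, so its
  projection on the (in-plane, velocity-orthogonal) radial direction is
  `g·sinα·cos(angle to contour)`. It is maximal in a traverse and vanishes
  when the skier heads straight down the fall line — which only the contour
  convention reproduces with a cosine. The package computes
  `cosβ = |v_x| / |v|` from the velocity channel.
- **The sign of the gravity term** is resolved from geometry: with `N_c`
  the in-plane unit normal pointing at the instantaneous turn centre,
  `F_r = v²/(r·g) − (g⃗·N_c)/g`. Gravity pointing *toward* the centre
  reduces the radial force the snow must supply; pointing away it adds.
  In code this collapses to `F_r = v²/(r·g) − s·sinα·T_x`, with `T_x` the
  lateral component of the unit velocity and `s` the signed horizontal
  curvature sense (`+` = centre on the skier's left). Both the simulator's
  ground truth and the estimator use this identical resolution, so the
  force-realization tests close the loop to within interpolation error.

**Turn radius.** `r` is estimated samplewise as the circumradius of three
trajectory points spaced 60 frames (0.3 s at 200 Hz) apart, capped at
`r_max = 1000` m for near-collinear triples so that straight gliding yields
a finite flag value rather than an infinite radius. The per-turn `r` is the
samplewise mean, and is therefore dominated by the near-switch samples
where curvature passes through zero: it is reported for completeness, but
it is *not* a stable recovery target and is never used directly — the
radial force uses `v²/r`, which weights the capped samples by (near) zero.
The stable per-turn geometric statistic is the apex (minimum) radius, which
the simulator records in its truth table and the arc fit recovers within
1% on noise-free runs.

**Energy dissipation.** Per-turn performance is indexed by
`Δe_mech/v_in = Δ(v²/2 + g·z)/v_in` between the two turn switches, negative
when energy is dissipated. Point values of `v` and `z` at the switch times
are taken from the spline-resampled GNSS velocity channel and the
*unfiltered* resampled altitude. Deriving `v` by differentiating the
heavily filtered positions (1.5 Hz low-pass and a 1 s Savitzky–Golay
window) attenuates the 0.3–0.7 Hz turn oscillation by O(1%), which on a
specific kinetic energy of ~120 J/kg corrupts `Δe_mech` by orders of
magnitude more than the conservation tolerance below; GNSS/IMU-fusion
velocity (as commercial sport units provide) does not have this problem.
Position-derived velocity remains available via
`synchronize(velocity_source = "position")`.

## Conditioning chain

Per run: (1) per-boot 3×3 calibration matrices map raw channels to newtons;
(2) each channel is zeroed against the mean of an unloaded pre-run window
and divided by bodyweight (total system mass × g); (3) per-limb resultants
`√(Fx²+Fy²+Fz²)` are low-passed with a 2nd-order Butterworth at 8 Hz;
(4) the 10 Hz trajectory is clock-aligned and cubic-spline resampled onto
the 200 Hz force grid; (5) positions are smoothed with a 2nd-order
Savitzky–Golay filter (201-frame window) followed by a 2nd-order
Butterworth at 1.5 Hz.

Numerical choices:

- **Zero phase by default.** The Butterworth stages run forward–backward,
  because any phase lag would misalign force against trajectory; a single
  causal pass is available (`filter_spec(zero_phase = FALSE)`), in which
  case the amplitude response follows the bilinear-transformed (frequency
  prewarped) second-order magnitude curve.
- **Edge handling.** Filters run over reflected padding
  (`3·fs/cutoff` samples), each pass anchored at its first sample so the
  zero-state startup transient vanishes on constant segments; the
  Savitzky–Golay stage uses its polynomial edge fits.
- **Clipping.** Filtered resultants are magnitudes; negative filter
  undershoots (e.g. around the jump spikes) are clipped to zero.
- **Clock synchronization** is coarse-then-fine: the pre- and post-run jump
  impulses are detected on both accelerometer channels (threshold
  `baseline + 0.4·(max − baseline)`, 2 s isolation, first and last cluster
  taken so run-phase loading and unequal impulse heights cannot displace
  them); the peak-time difference gives a coarse offset valid over many
  seconds, then the cross-correlation lag within ±100 frames of each
  impulse pair, with parabolic sub-frame refinement and averaged over the
  two events, gives the final offset. A secondary correlation peak within
  5% of the maximum raises an ambiguity warning.

## Turn segmentation

Turn switches are the inflections of the lateral trajectory. The default
detector finds sign changes of the *second* time-derivative of the filtered
lateral coordinate. A literal third-derivative detector is provided as an
alternative (`method = "third_derivative"`), but on any quasi-sinusoidal
path its zeros coincide with the turn apexes, a quarter period away from
the switches, so it serves for cross-checks of counts and rhythm rather
than as the boundary marker. Crossings must leave a hysteresis band (10% of
the robust derivative magnitude, with an absolute floor of `1e-3` m/s² so a
noise-free straight run yields zero switches) on both sides, and crossings
closer than `min_turn_duration = 0.6` s (well under the ~1.7–1.8 s turn
times) to the previously accepted one are suppressed, first-in-cluster
wins. Turns are numbered 1-based from the first detected switch; the
analysis retains turns 3–16 of an 18-gate course (the skier has stopped
skating by turn 3; turn 16 is the last before the finish approach) and
labels them *speed* (3–5, 15–16), *overspeed* (6–10), *flat* (11–14).

## The synthetic generator

The simulator emulates the study conditions: an 18-gate course of ~25°
relief, 200 Hz plates with per-boot calibration matrices and raw-unit
offsets, a 10 Hz COM stream on a clock offset by up to ±5 s, pre/post-run
jump impulses on both accelerometer channels, a ~2:1 outside:inside limb
split, and additive Gaussian noise plus band-limited 10–25 Hz "vibration"
so the 8 Hz force filter does meaningful work.

- **Path**: a straight approach joins a cosine lateral oscillation
  `w = A·cos(2πξ/λ)` with half-period equal to the gate spacing; gates sit
  at the apexes. Defaults `gate_spacing = 26` m and `A = 4.6` m give turn
  times ≈ 1.8 s, path length ≈ 28 m per turn and apex radii ≈ 15 m. The
  straight approach makes the motion-onset kink invisible to the lateral
  switch detector. There is no ski–snow contact model: trajectory, speed
  and force are made mutually consistent by construction, which is exactly
  what the downstream analysis needs (and no more).
- **Speed** follows the specific-energy balance along the path:
  `d(v²/2)/dσ = g·sinα·dξ/dσ − μg − k·v²`. `dissipation_coeff` (μ, default
  0.30) is an effective friction coefficient — energy lost per metre is
  `μ·g` J/kg — and `drag_k` (default 0.004 m⁻¹) a speed-dependent loss
  standing for aerodynamic drag and speed-dependent snow work. A per-turn
  *fraction* of mechanical energy would be ill-posed (mechanical energy is
  altitude-datum dependent), and pure Coulomb friction has no stable
  operating speed on constant relief: the quadratic term gives each athlete
  an equilibrium speed, so heterogeneous cohorts neither stall nor run
  away. The linear ODE is solved exactly by its integrating factor
  `exp(2k·σ)` with trapezoidal quadrature on a 2 cm grid, so frictionless
  runs conserve energy to machine precision. Dissipation so large that
  `v²` would go non-positive aborts with a diagnostic.
- **Force**: the net SRF vector is `m(a − g⃗)` from the analytic
  kinematics, so the emitted signal is dynamically exact. It is split into
  two limb vectors whose vector sum preserves `m(a − g⃗)` exactly while
  their *magnitude sum* realizes the target total force
  `F_r / rf_capability` (floored at `|m(a − g⃗)|`, since a magnitude sum
  cannot be smaller than the net) at the configured outside:inside ratio —
  a two-link law-of-cosines construction in the plane spanned by the net
  force and the tangent. The outside ski is the one opposite the turn
  centre; attribution switches at the turn boundaries.
- **Cohort** draws (defaults in `cohort_spread()`): dissipation
  0.285–0.315 bracketing the course equilibrium, `rf_capability`
  0.62–0.74, limb split 1.75–2.35, mass N(84, 8) kg, line amplitude factor
  0.96–1.04, clock offset ±5 s. The line factor gives the cohort real
  path-length variance (so the Level-1 stepwise has a live `L` candidate);
  it also means energy-based athlete ranking is not perfectly determined by
  the dissipation coefficient alone — the isolation property (rank
  correlation exactly 1) is therefore tested with the line spread fixed,
  while the default heterogeneous, noisy cohort is required to reach rank
  correlation ≥ 0.9.

What the generator does *not* emulate, and hence what passing tests do not
show about real data: GNSS multipath/dropout and fusion artefacts
(noise is white Gaussian), snow-condition drift between runs, pole pushes
and skating in the first turns, sub-turn technique phases, torque/moment
channels, and any systematic miscalibration of the plates.

## Statistics

- **Normality screen**: Shapiro–Wilk per variable plus a robust outlier
  flag (|z| > 3.5 on median/MAD). Nothing is auto-deleted; exclusion is an
  explicit analyst action.
- **Correlations**: Pearson r with Fisher-z 95% CI; magnitude labels at
  0.1/0.3/0.5/0.8. Variables whose cohort SD is below 0.1% of their scale
  (e.g. the energy index of a dissipation-free cohort) are refused as
  degenerate rather than correlated on numerical noise.
- **Stepwise regression**: forward selection with backward elimination,
  p-to-enter 0.05 and p-to-remove 0.10 (the common defaults of the
  point-and-click packages used for this kind of analysis; both
  configurable). Variables are z-scored first, so coefficients are
  standardized β (with one predictor, β equals Pearson r identically);
  R²-change is recorded at each entry and telescopes to the model R². An
  empty model is a valid, explicitly reported outcome ("no clear
  prediction"). The test suite checks the selector against an
  exhaustive-subset stability oracle: the selected set must be one in
  which every member stays below p-to-remove and no outsider passes
  p-to-enter.
- **Repeated-measures ANOVA**: one-way within-subject F across the three
  sections; all pairwise paired comparisons Holm-corrected; Cohen's d from
  the mean difference over the pooled SD of the two sections (a
  difference-SD variant `d_z` is reported alongside, since the variant is
  a genuine field convention choice); magnitude labels at 0.2/0.5/0.8.
  With ≥3 levels the Greenhouse–Geisser ε and corrected p are reported,
  the uncorrected F being primary.
- **Stepped model**: Level 1 `T ~ (Δe_mech/v_in, L)`; Level 2 correlations
  of `F_r` with `T` and `Δe_mech/v_in`; Level 3 `F_r ~ (F_tot, RF)`;
  Level 4 `F_tot ~ (F_out, F_diff)`; each fitted on the course dataset and
  the three sectional datasets. Cohorts below 10 athletes attach an
  instability warning to the whole report.

## Problem sizes and tolerances

The package's verification suite runs 15-athlete cohorts on the 18-gate
default course (each run ≈ 50 s of 200 Hz force data), which keeps a full
simulate-to-report pipeline under ten seconds while leaving every
statistical contrast well resolved. Key numeric contracts, all exercised by
the tests: frictionless energy conservation through the *full* conditioning
pipeline to `|Δe_mech/v_in| < 1e-4` on interior turns (checked on a
low-relief, wide-turn course, because a dissipation-free 25° course
accelerates beyond any physically meaningful speed); clock-offset recovery
to a median ≤ 1 frame (5 ms) over 100 random ±5 s offsets; arc-radius
recovery of a 30 m circle to 0.1% noise-free and 3% under the configured
0.05 m position noise after pipeline-style conditioning; emitted-force
radial decomposition matching ground truth within 0.5%.

## Known limitations

The trajectory model is kinematic, not a contact model; sectional
differences between course segments arise only from course position and
cohort heterogeneity, so the generator is not calibrated to reproduce any
particular published sectional contrast. The per-turn mean radius is
reported but statistically fragile (see above). The two-decimal magnitude
labels and stepwise criteria follow common practice rather than a unique
standard; both are configurable. Statistical levels are fitted
independently, with no multiplicity control across the level structure —
deliberately matching the analysis design this package implements.
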