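---
title: "The chairsts measurement model, pipeline and simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The chairsts measurement model, pipeline and simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chairsts)
```

## The measurement problem

Sit-to-stand (STS) trunk kinematics — how far and how smoothly the trunk
flexes forward before seat-off and extends upright afterwards — are a
clinically useful marker of lower-limb function and frailty. The reference
instrument is optical motion capture, which is confined to a laboratory. A
chair with two embedded time-of-flight laser range finders (one in the
seat aimed at the thigh, one in the backrest aimed at the trunk) can
measure the same angles anywhere, if the two scalar distances can be
turned into segment angles. chairsts implements that conversion, the full
concurrent-validity pipeline against marker-based angles, and a synthetic
trial generator that exercises every stage without hardware.

## The two-link model and its frame

All geometry lives in the sagittal plane. The coordinate frame — left
implicit by the measurement idea but fixed here so that the inverse
formulas are literal identities of the forward optics — has its origin at
the knee joint centre, x positive toward the backrest (posterior), y
positive upward from the seat plane. The seat plane is `y = 0`, the
backrest plane `x = l_seat`. The seat sensor sits at
`(l_s1 + l_offset, 0)` and fires along `(-cos phi_s1, +sin phi_s1)`; the
backrest sensor sits at `(l_seat, l_s2)` and fires along
`(-sin phi_s2, -cos phi_s2)`.

The thigh is a link of length `l_thigh` rotating about the knee; the trunk
is a link rising from the hip at angle `theta_trunk` from vertical
(flexion, i.e. forward lean, positive). Inverting the seat beam gives
`theta_thigh`, placing the hip on the thigh circle gives `(x_hip, y_hip)`,
and inverting the backrest beam through the hip gives `theta_trunk` (see
`?thigh_angle_from_distance`, `?hip_position`,
`?trunk_angle_from_distance`, and the README for the formulas).

Assumptions the model makes, and that the simulator can selectively break:

* the knee centre is fixed at a known offset from the seat edge
  (`knee_shift_mm` breaks this, ramped over the extension phase);
* the beams reflect off the model lines themselves, not off clothing or
  tissue in front of them (`surface_offset_mm` breaks this);
* the pre-set model thigh length matches the user (`body_thigh_mm` in
  `simulate_trial()` breaks this);
* the motion is sagittal. Lateral weight shift cannot be represented
  directly; the weight-shift presets carry only its in-plane signature
  (timing asymmetry plus an optional thigh-distance offset).

`atan` rather than `atan2` is used in the inversions, matching the
measurement model: where an inversion denominator is non-positive the
model has no meaning (the beam's hit point is at or past the knee plane,
or at or below the hip), so the sample is flagged invalid rather than
angle-wrapped. A consequence worth knowing: the thigh inversion is
singular for a perfectly vertical thigh (denominator exactly zero), so the
final standing samples of a trial can be invalid on the chair route. This
is a property of the instrument model, not of the implementation.

## Key parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `phi_s1` | 63.5 | deg | seat-sensor installation angle from the seat plane |
| `l_s1`, `l_offset` | 130, 50 | mm | sensor-to-seat-edge and edge-to-knee lengths |
| `phi_s2` | 90 | deg | backrest-sensor angle from the backrest plane |
| `l_seat`, `l_s2` | 550, 465 | mm | seat depth and sensor height |
| `l_thigh` | 403 | mm | model thigh length (446 fits taller users) |
| `seat_height` | 400 | mm | metadata only, no kinematic role |
| `sensor_max_range` | 2000 | mm | ToF-class ceiling; beyond it a sample is invalid |
| filter order / cutoff | 4 / 6 | – / Hz | Butterworth low-pass, zero-phase by default |
| onset threshold | 1 | deg | trunk rise above the quiet-sitting baseline |
| baseline window | 0.5 | s | quiet-sitting span averaged for the baseline |

The default geometry is the reference instrumented chair. The onset
threshold is the standard 1° rule; the baseline is a 0.5 s mean (robust to
single-sample noise), and a crossing must start a non-decreasing run of 3
samples so that an isolated noise spike cannot trigger onset — the
threshold itself stays exactly 1°.

## The pre-processing and validation pipeline

Distances and marker trajectories are treated identically: 4th-order
Butterworth low-pass at 6 Hz at the native rate, then the marker
trajectories are spline-resampled to the 30 Hz laser rate, then angles are
computed (`process_distances()`, `process_markers()`). Zero-phase
(forward–backward) filtering is the default because phase lag would bias
event timing; a causal mode is available via
`filter_spec(zero_phase = FALSE)`. The 6 Hz cutoff is the nominal design
cutoff of a single pass; the two-pass magnitude response is its square.

`validate_trial()` then:

1. restricts both series to their jointly valid time span — agreement can
   only be assessed where both systems report data (see the singularity
   note above);
2. segments each series by its own trunk events: onset, maximum flexion,
   maximum extension;
3. computes trunk waveform similarity per phase and thigh similarity over
   the whole onset-to-maximum-extension window, phase-normalising unequal
   segment lengths by spline resampling to the shorter segment's sample
   count;
4. computes flexion/extension excursions for both systems and their
   absolute and percentage errors.

"Waveform similarity" is the zero-lag normalised (Pearson) coefficient of
the time-aligned phases. Published waveform "cross-correlations" are
sometimes the peak over small lags instead; since the estimator is
ambiguous, `lag_mode = "max"` searches lags within ±0.2 s, but zero lag is
the documented default. The percentage excursion error is taken relative
to the reference (marker-based) excursion. Per-condition pooling of
repeated trials Fisher-transforms the coefficients, averages on the z
scale and back-transforms (`fisher_mean()`); coefficients of magnitude
exactly 1 — which arise legitimately for noiseless synthetic data — are
clipped to 1 − 1e-7 with a warning, since the transform cannot represent
the ceiling.

## Numerical choices

* **Phase boundaries on plateaus.** The flexion peak is the strict first
  argmax (ties broken by earliest index), keeping peak timing
  sample-exact. The extension end is the earliest post-peak sample within
  `end_tol = 0.05°` of the post-peak minimum: after standing the trunk
  angle plateaus, and the literal global minimum would land on an
  arbitrary late sample under float- or residual-filter-level wiggle.
  0.05° is far below any meaningful angular resolution.
* **Filter edges.** Odd-reflection padding of 3× the filter order at both
  ends (preserves level and slope across the boundary), and each pass runs
  on the level-shifted signal (first sample subtracted, added back after;
  exact because the DC gain is 1), which cancels the zero-initial-state
  startup transient that would otherwise corrupt short trials.
* **Resampling.** Cubic splines ("fmm"), which reproduce cubic
  polynomials exactly and the band-limited trajectories here to well below
  0.001 of amplitude.
* **Degenerate inputs.** Zero-variance segments, empty series, monotone
  post-onset series and coincident markers raise informative errors;
  invalid samples propagate as flags, and isolated invalid runs can be
  linearly interpolated (`fill_invalid()`) before filtering.
* **Angles are degrees at every interface**, radians only inside
  trigonometric kernels.

## The synthetic trial generator

`generate_trajectory()` builds the ground truth: 0.5 s quiet sitting,
minimum-jerk trunk flexion to the programmed amplitude, minimum-jerk
extension to a small overshoot past vertical, 0.5 s standing hold; the
thigh holds its seated baseline until peak trunk flexion, then rises to
vertical synchronously with the extension phase (approximating seat-off to
upright). Minimum-jerk profiles are the standard smoothness model for
point-to-point human movement and have zero velocity and acceleration at
both ends. With a seed, amplitude and duration get a ±5% per-trial jitter.

The seven condition presets (normal, increased/decreased anterior tilt,
slow, fast, right/left weight shift) are configurable package defaults
representing typical adult STS kinematics — 50° flexion over 2 s for
normal, 70°/30° for the tilt conditions, 4 s/1 s for the speed conditions —
not measured values from any subject.

Two generator choices deserve justification:

* **Seated thigh baseline, 8° (`thigh_baseline_deg`).** An exactly
  horizontal thigh line through the knee is degenerate for the seat beam
  (the ray meets it at the sensor itself, distance zero). Real seated
  thighs present their under-surface a few degrees above the seat plane
  (tissue thickness, slight knee-below-hip posture), so the generator
  starts the thigh at 8° rather than 0°.
* **The trunk is ray-cast as a half-line from the hip.** Hits above the
  C7 level are accepted as neck/head returns. With a finite trunk segment
  the backrest beam (fixed at 465 mm above the seat) would miss the trunk
  entirely at large flexion angles, where the trunk top drops below the
  sensor height; the half-line keeps every movement condition measurable,
  matching the fact that a real beam would still hit the body. The thigh,
  by contrast, is a finite knee-to-hip segment, and misses are invalid
  samples.

Virtual markers (lateral femoral condyle at the knee, greater trochanter
at the hip, sacrum and C7 on the trunk line) track the *actual* body pose,
so knee-axis translation moves marker positions but leaves marker-derived
angles exact — which is precisely why it produces a chair-vs-marker
discrepancy concentrated in the extension phase.

What the generator does **not** emulate: lateral (3D) motion and the
80 mm lateral offset of a real seat sensor, soft-tissue deformation beyond
a scalar surface offset, muscle dynamics, momentum strategies, multiple
repetitions, and real sensor artefacts (quantisation, dropouts, specular
misses). Passing the noiseless identity tests therefore shows the
geometry, signal chain and statistics are self-consistent — not that the
instrument would achieve those numbers on humans.

## Problem sizes used in the tests and acceptance script

The acceptance script inverts 10,000 random poses for the round-trip
check, validates one noiseless trial per condition (seven trials of
roughly 3–5 s at 30 Hz), four knee-shift settings
(0/10/20/30 mm), and 100 noisy seeds for the thigh-length comparison
(subject thigh 446 mm, model settings 403 vs 446 mm, 10 mm surface offset,
2 mm distance noise); Monte-Carlo statistical checks in the test suite use
a few hundred to a thousand replicates. These sizes give comfortable
margins on every property while keeping a full run in the tens of
seconds.

## Known limitations

* The extension phase of the chair model is structurally less trustworthy
  than the flexion phase whenever the knee translates — the package
  quantifies this but cannot correct it without a knee-tracking sensor.
* The model reports the thigh *line* angle; near-vertical thighs approach
  the inversion singularity, and the final standing samples may be
  invalid.
* Percentage excursion errors are undefined when the reference excursion
  is zero; they are reported as missing.
* The weight-shift presets are an in-plane proxy for an inherently 3D
  behaviour.
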