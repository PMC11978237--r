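---
title: "Methods: validating smartphone pelvic kinematics against motion capture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating smartphone pelvic kinematics against motion capture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pelvicmotion)
```

This vignette documents the scientific and numerical choices behind
`pelvicmotion`: the measurement model, the synthetic-data generator that
stands in for laboratory recordings, the processing and statistical
pipeline, and what the package's tests do and do not establish about real
data.

## The measurement problem

During single-leg squats (SLS) and step-downs (SD15/SD20: 15 cm and 20 cm
blocks), excessive pelvic motion and sway are clinically meaningful
performance markers. Two instruments observe the same latent pelvis pose:

* **MOCAP branch** — four reflective markers on the bilateral anterior and
  posterior superior iliac spines, tracked at 250 Hz in laboratory
  coordinates (gold standard);
* **Smartphone branch** — a handset on the sacrum logging three orientation
  channels (roll, pitch, azimuth from the device's fused orientation sensor)
  and three acceleration channels at 100 Hz.

One laboratory frame is used throughout: vertical (up +), mediolateral
(left +), anteroposterior (anterior +), matching the device channel
semantics for the stated mounting (landscape, screen outward, camera left).
Pelvic angles use one sign convention everywhere — for right-leg stance,
positive transverse = forward contralateral rotation, positive frontal =
contralateral pelvic drop, positive sagittal = anterior pelvic tilt — and
one intrinsic Euler sequence, transverse (about vertical) → frontal (about
anteroposterior) → sagittal (about mediolateral). Because the simulator and
both processing branches share the sequence and sign table, ground-truth
recovery is exact by construction and is asserted by round-trip tests rather
than by convention tables.

## The synthetic cohort generator

No raw recordings from the motivating study are deposited, so the package
ships a generator whose defaults *are* the study conditions; it is
first-class, tested code, not a fixture.

**Protocol.** 5 repetitions per task; nominal 4-s down-and-up tempo; ≥ 2-s
rests; 5 s quiet standing before the task (plus 3 s after, used by the
heading-drift QC). Each repetition is a raised-cosine descent/ascent — a
smooth, band-limited waveform the protocol description does not constrain
further — with an optional flat plateau at maximal depth to exercise the
plateau-midpoint peak rule. Every angle channel is the per-plane peak
amplitude times the same normalised profile, so true peak angles equal the
drawn amplitudes.

**Kinematic scales.** Per-task, per-plane peak-angle locations default to
the published smartphone task medians (e.g. SLS transverse −6.4°, SD20
frontal +4.5°). Their spread is split into a participant intercept shared
across tasks (SD 4.5/3.0/6.8° for transverse/frontal/sagittal) plus a
smaller task-specific deviation (2.5/1.1/2.2°), chosen so that both the
total between-participant spread (published IQRs) and the within-participant
task contrasts (published paired-difference IQRs) are on the reported scale.
This correlation structure matters: with independent draws per task, the
small SD15→SD20 frontal step (~1°) would not be detectable at n = 52,
contrary to the published post hocs.

**Pace.** True repetition duration is drawn once per participant
(SD 0.35 s, truncated to [2.5, 6] s) around the 4-s metronome target.
Participants in the motivating study were consistently faster than the
metronome with a wide IQR; a degenerate (constant) duration would also make
duration agreement statistics meaningless, since the between-participant
variance in their numerator would be zero.

**Sway.** Mediolateral displacement is a three-sinusoid mixture in the
1.5–2.5 Hz band under the repetition envelope, with amplitude calibrated
numerically so the SD of the true mediolateral acceleration over a
repetition hits a per-task target (defaults 0.15/0.17/0.19 m/s², the
published MOCAP medians, with participant/task spread 0.045/0.02 m/s²).
The band sits above the 1 Hz analysis high-pass and below the 6 Hz
differentiation pre-filter, so both branches measure it with little
attenuation.

**Depth.** Not reported by the study; defaults 0.14/0.18/0.22 m
(SD 0.03 m) are an assumption on the scale implied by 60–80° knee flexion.
Angle-recovery behaviour does not depend on it; segmentation does (see
limitations).

**Imperfections.** Isotropic marker noise (default 0.3 mm); phone
accelerometer noise (0.02 m/s²); phone orientation noise (0.2°); a constant
mounting offset (default zero); slow heading drift on azimuth only (default
zero — the motivating study saw visible drift in 1 of 52 participants);
gravity in the acceleration channels (switchable to "linear acceleration"
semantics; outcomes are insensitive to the choice, which the tests assert).

**What is not emulated:** soft-tissue artifact, marker occlusion/label
swaps, irregular phone timestamps, balance-failure repetitions,
magnetometer disturbance other than linear drift, and any systematic
hardware bias between the branches. Passing tests therefore demonstrate
algorithmic correctness and statistical calibration under the stated noise
model — not that a particular handset is valid; with clean simulated inputs
the agreement analysis *should* and does return near-perfect ICCs for
orientation.

## Processing choices

**Zero-phase filtering.** All filters are Butterworth designs applied
forward-backward (two passes), because outcomes are defined at time-aligned
events and one-pass phase lag would bias peak timing. The implementation
initialises each pass at its steady state for the signal's first value and
extends the signal by odd reflection scaled to the filter time constant
(3/cutoff seconds), so a constant passes a high-pass as exactly zero and a
40-s recording is usable even with the 0.1 Hz drift cutoff.

**MOCAP branch.** The pelvis frame takes the mediolateral axis from the
ASIS pair, the anteroposterior axis from mid-PSIS toward mid-ASIS
(orthogonalised), vertical completing the right-handed triad; angles are
decomposed relative to the mean frame over the first second of quiet
standing, so a participant standing slightly rotated reads zero. The
centroid of the four markers gives vertical/mediolateral displacement;
displacement is low-passed at 6 Hz before double differentiation (central
differences, exact for quadratics) because white marker noise
double-differentiated at 250 Hz would otherwise swamp the 0.15 m/s²-scale
sway signal; the sway band itself (≤ 2.5 Hz) loses < 0.5% amplitude.

**Phone branch.** Azimuth is unwrapped across the ±180° seam (residual
per-sample steps above 90° — unphysical at 100 Hz — raise a
corrupt-orientation error) and re-referenced to its quiet-standing median,
so the arbitrary compass zero never enters outcomes. Vertical displacement
is estimated by double integration with the 0.1 Hz high-pass applied at
each step — three applications (acceleration, velocity, displacement) by
default, switchable to two. Crucially, the integrated channel is the
*lab-vertical* projection of the specific force using the device's own
roll/pitch: without this projection, gravity modulated by pelvic tilt
(≈ g·(1−cos θ), i.e. ~0.3 m/s² at 15°) enters at the squat frequency and
can cancel most of the true vertical acceleration for strongly tilted
participants. The heading does not enter the vertical projection, so
magnetometer quality is irrelevant to it.

**Segmentation.** The reference protocol identified events visually; this
package replaces that with a parameterised automaton on the
vertical-displacement channel: candidate repetitions open where displacement
falls 10 mm below baseline, extend outward to crossings of the 5 mm exit
threshold (hysteresis), with sub-sample crossing times by linear
interpolation; spans shorter than 1 s or shallower than 30 mm are
discarded; the peak is the displacement minimum, or the temporal midpoint
of a bottom plateau (within 2 mm for ≥ 0.2 s). The baseline is the 0.5-s
window of minimal summed angle variance inside the pre-task quiet span, and
detection starts where the quiet span ends — the protocol's task start —
which keeps backward-spread filter distortion of the integrated phone
displacement from being read as movement. Every constant is a
`segmentation_params()` field. Because threshold crossings lie inside the
true movement span, detected durations are systematically slightly shorter
than true durations — the same direction as the published phone-vs-MOCAP
duration bias.

**Outcomes.** The 200-ms peak window includes all samples within ±100 ms
inclusive, making it symmetric about the peak; its mean then equals the
instantaneous value at the peak for signals linear through it (an
asymmetric half-open window would bias the mean by half a sample interval
times the slope). Angle deltas subtract each branch's own baseline, which
is what cancels constant mounting offsets. Medians over repetitions use the
standard even-count convention.

## Statistical choices

* **Bias gate:** Shapiro-Wilk on paired differences at α = 0.05 selects
  paired *t* versus Wilcoxon signed-rank (zeros dropped); all-zero
  differences are reported as degenerate with no p-value.
* **ICC:** two-way average-measures forms computed from the mean squares
  directly (formulas in the README); consistency CIs use the exact F pivot,
  absolute-agreement CIs the Satterthwaite-approximated F with
  Spearman-Brown step-up. Estimates are tested to 1e-10 against a
  brute-force `aov()` decomposition, and the consistency CI's 95% coverage
  is verified by simulation at a known true ICC. A significant bias selects
  the consistency model (offsets would otherwise dominate the agreement
  question the ICC is answering there), a non-significant bias selects
  absolute agreement; the gate is overridable and the chosen model is
  printed per row to keep it auditable.
* **Categories** apply to the CI lower bound: < 0.5 poor, [0.5, 0.75)
  moderate, [0.75, 0.9] good, > 0.9 excellent.
* **Between-task tests:** repeated-measures ANOVA when every task's values
  pass Shapiro-Wilk, with Greenhouse-Geisser df correction applied when
  Mauchly's test rejects at 0.05 (fractional dfs in the published results
  imply the correction was in use there); otherwise Friedman. Significant
  overall tests trigger the three pairwise gated comparisons with
  Bonferroni m = 3. The ANOVA/epsilon path is cross-checked against
  `anova.mlm(..., test = "Spherical")`.
* **Differences are oriented MOCAP − phone**, so "the phone reads less
  anterior tilt" appears as positive sagittal bias.
* Heading-drift QC compares transverse medians between the pre- and
  post-task quiet windows (threshold 5°); failing recordings are excluded
  from transverse-plane rows only, with exclusion counts reported, and
  recordings whose displacement never crosses the detection threshold are
  flagged and excluded rather than aborting the study (strict mode turns
  both into errors).

## Problem sizes

The shipped tests run the full pipeline at cohort sizes 2–12 for unit and
property checks, 12 participants × 10 seeds × 3 noise levels for the
noise-monotonicity property, and one 52-participant cohort for
injected-effect recovery; CI calibration uses 1000 simulated 15-participant
tables. The acceptance script simulates one 52-participant, three-task
cohort. These sizes put every statistic in the regime the design targets
while keeping a complete run in minutes on one core.

## Known limitations

* **Phone start/end timing.** With isolated 4-s repetitions separated by
  full rests, the triple 0.1 Hz zero-phase high-pass flattens the base of
  the displacement pulse; the outer threshold crossings are genuinely
  unrecoverable from the integrated waveform, and phone-detected durations
  run markedly shorter than MOCAP's (the published bias direction, with a
  protocol-dependent magnitude). Peak times, which the orientation outcomes
  depend on, are preserved to within ~one sample. Duration agreement
  statistics on simulated cohorts should be read with this mechanism in
  mind.
* **Frontal-plane sensitivity.** The frontal task contrast between SD15 and
  SD20 is ~1°; detecting it depends on the assumed within-participant
  correlation structure, exactly as in the motivating study.
* The segmentation constants (10 mm / 30 mm / 1 s) are assumptions standing
  in for visual identification; depths near the 30 mm floor (very shallow
  squats) are undetectable by construction, particularly on the attenuated
  phone waveform.
* The simulator draws participant effects as Gaussians and renders noise as
  white; real sensor error is coloured and participant distributions are
  skewed (the published medians/IQRs are asymmetric).
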