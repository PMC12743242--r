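---
title: "Estimating gait events and spatiotemporal metrics from a lumbar accelerometer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating gait events and spatiotemporal metrics from a lumbar accelerometer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A single accelerometer worn over the lower lumbar spine (≈ L5) rides close
to the body's center of mass (CoM) and is one of the cheapest ways to
measure how a person walks outside a gait laboratory. Everything clinically
interesting — cadence, step and stride times, step length, gait speed —
derives from two families of quantities:

* **foot-contact events**: initial contact (IC, heel strike) and final
  contact (FC, toe-off) of the feet, read from the morphology of the
  anterior-posterior (AP) and vertical acceleration;
* **CoM vertical excursion**: the few centimetres the trunk rises and falls
  each step, which an inverted-pendulum model converts into step length.

`lumbargait` implements an adaptive estimation pipeline for single walking
bouts, a legacy comparator detector, a kinematic signal simulator with
exact ground truth, and the evaluation statistics used to score detectors
(event matching, sensitivity/precision/F1, MAE, ICC(2,1)).

## The pipeline

`estimate_gait()` runs five stages.

**1. Axis identification.** The vertical channel is the one whose absolute
mean acceleration is largest (gravity dominates it); its sign is chosen so
the stored channel mean is negative, i.e. the sensor reads −g at rest. All
channels are band-passed to the walking band (0.25–7.5 Hz, fourth-order
Butterworth) and the AP axis is the non-vertical channel with the largest
absolute normalized cross-correlation against the vertical; its sign is
flipped when the peak correlation is negative, which pins the AP polarity
the contact detector expects. A two-rotation tilt correction computed from
the per-channel means then levels the frame; rotations preserve signal
energy exactly.

**2. Mean step frequency.** The AP signal is transformed with a Gaussian
first-derivative continuous wavelet transform (CWT) at 10 scales whose
central frequencies span 0.5–5.0 Hz, the per-scale coefficients are summed
sample-wise into a "CWT power" signal, and a windowed (5 s, 50 % overlap)
autocovariance is computed. The first autocovariance peak beyond 0.2 s in
each window estimates that window's step time; the bout mean step time
`t̄_step` is the median of the window estimates (lower-midpoint convention
for even counts, so the estimate is an observed lag) and the mean step
frequency is its inverse. This single number drives every adaptive
parameter downstream.

Two open choices here were resolved as follows. The per-scale coefficients
are combined as a *signed* sum (a config switch restores the rectified
variant): rectification doubles the effective frequency content of the
power signal, and because an autocovariance built from harmonics `k·f` is
always stationary at half the period, any substantial even-harmonic power
creates a spurious local maximum at `T/2` that the "first peak" rule then
picks — estimating double the true cadence. The ten scales are linearly
spaced in target frequency, which covers the band evenly.

**3. Contact detection (adaptive).** The AP signal is low-passed at 20 Hz.
FC events: integrate to AP velocity, apply the CWT at the scale
corresponding to `f_CWT = 3.0 · f̄_step` (see *Scale relations* below), and
take peaks with prominence above `0.6 σ_Wn` (σ_Wn is the SD of the whole
coefficient series — an amplitude-free unit) separated by at least half the
mean step time. IC events: apply the CWT to the AP acceleration itself,
producing a smoothed jerk; for each FC, search backward (bounded by the
previous FC) for the latest positive-to-negative jerk zero-crossing and the
latest prominent jerk minimum before that crossing; the IC is the midpoint
of the two. The midpoint rule is robust to the flattened AP peaks of slow
walking. Zero-crossings are localized with sub-sample linear interpolation
and peaks are refined by parabolic interpolation, since timing errors of a
single sample (8 ms at 128 Hz) are material at the accuracy this method
reaches.

A margin of `0.1 · t̄_step` immediately before each FC is excluded from the
backward search: the FC's own velocity-CWT maximum is also a jerk
zero-crossing, and without the margin the search can collapse onto the FC
itself. Peaks within `2 · scale` samples of either signal edge are
discarded as edge effects of the reflective extension.

**4. Step assembly and quality control.** Steps are groups of one IC and
the two following FCs (opposite then same side). Three physiological rules
screen candidates, parameterized by the maximum stride time `t_max_stride`
and the loading factor `C_loading`:

1. initial double support `t_bip < C_loading · t_max_stride`;
2. stance `< t_max_stride / 2` plus the rule-1 limit;
3. stride time `< t_max_stride`.

In dynamic mode (default) the two parameters scale with the bout mean step
time `x`: `t_max_stride = 2x + 1` (about two standard deviations above the
expected mean stride time, which is `2x`) and `C_loading = 0.17x + 0.05`
(the loading fraction falls as walking speeds up). The legacy static pair
(2.25 s, 0.2), whose loading limit is 0.45 s, remains available. Continuity
requires each retained step's same-side FC to be the next step's
opposite-side FC; breaks partition the bout into runs, and stride-level
metrics (stride time, stride length, speed) are computed within runs only.
When two ICs would claim the same first FC the later one wins — the earlier
IC would imply an implausibly long loading phase.

**5. Spatial model and metrics.** Per step, the vertical channel over
`[IC, IC_next]` is mean-removed, double-integrated (cumulative trapezoid),
and linearly detrended *through the window endpoints*. Over one
near-periodic step the endpoint line equals the integration-drift ramp
exactly; a least-squares line would tilt the asymmetric height curve (its
minimum sits in the short double-support phase, its maximum in the long
single-support phase) and was measured to inflate the excursion by ~9 % on
simulated bouts. Height excursions are read off as max − min over the step
(`Δh`) and over its two sub-phases (`δ_bip` over [IC, FC_opp], `δ_sup` over
[FC_opp, IC_next]).

Step length uses circular-arc chord geometry. Model 1 (single inverted
pendulum of leg length `l_leg = 0.53 · height`):

&nbsp;&nbsp;`S = 2 √(2 l_leg Δh − Δh²)`.

Model 2 (default) adds a normal pendulum of effective length `l₂` during
double support:

&nbsp;&nbsp;`S_bip = 2 √(2 l₂ δ_bip − δ_bip²)`, &nbsp;
`S_sup = 2 √(2 l_leg δ_sup − δ_sup²)`, &nbsp; `S = S_bip + S_sup`,

with `l₂ = 1.1 · l_leg · (t_bip / t_sup)` evaluated at the bout medians of
the phase durations (the constant 1.1 relates the length ratio of the two
phases to their time ratio). Excursions exceeding their pendulum length —
a numerical artifact of noisy bouts — are clamped to 0.95 of the length
with a warning. Stride length is the sum of two consecutive step lengths,
gait speed is stride length over stride time, and cadence is `60 / t_step`
per row; bout summaries are medians across steps (midpoint convention).

The legacy comparator detector decimates the vertical channel to 50 Hz
(zero-phase antialiasing low-pass, then cubic spline interpolation),
integrates, and smooths with the CWT at scale 8 — the scale of a 1.25 Hz
wavelet central frequency at 50 Hz under the `scale = 0.2 · fs / f`
convention used throughout. Peaks above half the SD of the smoothed signal
are its IC estimates; a second CWT pass yields smoothed jerk whose peaks
are its FC estimates. The package stores vertical acceleration with a
negative gravity mean, so this detector flips the channel internally to
make upward acceleration positive: its IC landmark is then the loading hump
that follows the true IC, which is precisely why it lags the AP-based
detector.

## Scale relations

The two adaptive CWT stages need a rule mapping the bout's step frequency
to a wavelet central frequency, `f_CWT = a · f̄_step + b`. The packaged
defaults, `a = 3, b = 0` for both stages, were obtained by running
`calibrate_scale_relation()` — a per-bout sweep minimizing
`(1 − F1) + λ · RMSE` against reference events, followed by a least-squares
affine fit — on simulated bouts spanning 1.2–2.2 Hz. A caveat worth
stating: on the simulator the cost surface is a broad plateau (any
`f_CWT ≈ 2–4 · f̄_step` detects essentially perfectly), so the calibration
identifies a plateau member rather than a sharp optimum; the default sits
where the generator's own morphology contract places the landmarks. Users
with reference-labelled recordings can recalibrate and override via
`gait_config(scale_relation = ...)`.

## The simulator

`simulate_bout()` is kinematic: trajectories are prescribed, ground truth
is exact by construction, and the detectors only ever see accelerations.

* **Vertical channel.** The CoM height follows circular pendulum arcs — a
  normal-pendulum arc of length `l₂ = 1.1 · l_leg · t_bip/t_sup` during
  double support, an inverted-pendulum arc of `l_leg` during single
  support — traversed by a smooth periodic forward velocity whose phase
  integrals match the per-phase travel. Splitting the forward travel in
  proportion to the pendulum lengths makes the arc slopes match at the
  transitions, so the height profile is C¹; a short periodic Gaussian
  smoothing (SD 2 % of the step time) removes the residual curvature jumps
  so that the *sampled* acceleration double-integrates back to the height
  trace to better than 1 % RMS. The acceleration is the spectral second
  derivative of that profile, plus gravity in the stored sign convention
  (channel mean ≈ −9.80665 m/s²). Because the generator and the spatial
  model share the same chord geometry, the planted step length, the planted
  phase excursions, and the model-2 inversion are mutually consistent — the
  10 % recovery requirement tests the pipeline, not a modelling mismatch.
* **AP channel.** A prescribed periodic waveform carrying the landmarks the
  detector definitions require: a sharp derivative-of-Gaussian complex
  whose smoothed-jerk minimum and zero-crossing straddle the true IC (the
  complex is positioned so their midpoint lands on the IC under the nominal
  smoothing scale), and a Gaussian push-off bump positioned so the smoothed
  velocity-CWT maximum falls exactly on the true FC (solving
  `B'(x) = −bg'(t_FC)` on a dense cycle grid, where `B` is the smoothed
  bump and `bg` the smoothed bump-free background). A step-frequency
  component phase-locked to the vertical fundamental anchors the
  cross-correlation sign rule; partial trims of the bump's first two
  harmonics keep that anchor dominant and the autocovariance period
  unambiguous. This is a testability contract, not biomechanics: the
  morphology is *designed* so that the published landmark definitions are
  exactly right on noiseless data.
* **Third channel** is medio-lateral sway at stride frequency; tilt is a
  known rotation; noise is seeded white Gaussian, with
  `noise_sd_for_snr()` converting a target SNR into a noise SD.

What passing tests on this generator do **not** show: robustness to
pathological gait, turning, asymmetry between feet, soft-tissue artifacts,
or sensor drift — none of which the generator emulates. They show that the
implementation realizes the published landmark definitions, thresholds and
formulas faithfully, with the stated invariances (amplitude, translation,
determinism), and that the full chain recovers planted parameters at
realistic noise levels.

## Evaluation tools

`match_events()` matches detected to reference events greedily in reference
time order, each reference taking its nearest unmatched detection within
±0.15 s (a 0.3 s total window). For event trains whose spacing exceeds the
window — the gait regime — this equals the maximum-cardinality assignment,
which the test suite confirms against a brute-force oracle. Events outside
an optional analysis region are excluded on both sides (detections there
are not false positives, mirroring events off an instrumented walkway;
reference events there are not false negatives). Signed errors are
detected − reference, MAE is computed over matched events only, and
zero-denominator metrics are reported as `NA`, never 0.

`icc_2_1()` is the single-measure two-way random-effects absolute-agreement
intraclass correlation from the classical ANOVA decomposition, with
F-distribution confidence bounds (Satterthwaite degrees of freedom). The
test suite checks it against mean squares obtained independently from
`aov()`.

## Numerical choices

* All filtering is zero-phase (forward–backward, odd-reflection padding,
  steady-state initial conditions). One-pass IIR phase lag would bias event
  times by tens of milliseconds, which is the entire error budget.
  Padding extends four time constants of the lowest cutoff; for the
  0.25 Hz band edge the pole sits close enough to the unit circle that
  double-precision rounding bounds forward/backward commutation near 1e-8.
* The wavelet is L2-normalized with exact zero mean in discrete form; the
  scale convention `scale = 0.2 · fs / f_target` (rounded to 0.1) fixes
  1.25 Hz at 50 Hz ↦ scale 8.
* Peak prominences follow the standard definition (descend both sides to
  the lowest point before a higher peak); minimum-distance filtering keeps
  the higher peak.
* Problem sizes: simulated test bouts are 20–30 s at 128 Hz (34–66 steps),
  the fixture grid is 3 speeds × {clean, SNR 10 dB} × {0°, 5° tilt}, and
  oracle comparisons use up to 20 subjects (ICC) and 8 events (matching);
  these sizes give stable statistics while keeping the whole suite fast.

## Known limitations

* A single lumbar sensor cannot lateralize steps; left and right are
  interchangeable throughout.
* The pipeline assumes the input is a walking bout; it does not segment
  walking from free-living data, detect turns, or handle pauses beyond QC
  rejection.
* Dynamic QC thresholds assume the loading-time-versus-step-time relation
  of ordinary walking; strongly pathological gait may violate it.
* The spatial model estimates step length up to pendulum-model bias;
  model 2 reduces but does not eliminate the classical underestimate of
  model 1.
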