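---
title: "Closed-loop bimodal vagus neuromodulation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop bimodal vagus neuromodulation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vagusloop)
```

`vagusloop` simulates a closed-loop experiment in which a single electrode on
the vagus nerve either stimulates (lowering heart rate) or applies 10 kHz
KHFAC conduction block (raising it), under a fuzzy logic controller that holds
heart rate at a setpoint against a ramping synthetic vagal tone. This vignette
documents the model, every tunable that matters, the choices made where the
design was genuinely open, and what the simulation can and cannot say about
the in-vivo system.

## The controller

At each 2 Hz update the controller reads the rolling heart-rate estimate and
computes the error `ΔHR = HR − SP` (bpm) and its slope
`mHR = (ΔHRₙ − ΔHRₙ₋₁) / 0.5` (bpm/s). Fuzzification uses:

* **Error zones.** `Below(x) = 1 / (1 + exp(k·(x − m_b)))` and its mirror
  `Above`, with midpoints `m_b = −5`, `m_a = +5` bpm and steepness
  `k = 0.8` /bpm; `Near = max(0, 1 − Below − Above)`. For any valid
  configuration (`m_b < m_a`, shared `k`) the complement is nonnegative, so
  the three memberships sum to 1 wherever Near is active. The midpoints set a
  ±5 bpm dead zone around the setpoint; the parameters are config-exposed
  because only the qualitative three-zone shape, not its numbers, is
  constrained by the source design.
* **Slope zones.** Complementary trapezoids with `Decreasing = 1` at or below
  −1 bpm/s and `Increasing = 1` at or above +1 bpm/s, linear between.

Five rules with singleton outputs map these to a `cout` increment:
(Above, Increasing) → +1, (Above, Decreasing) → +0.4, (Near, Any) → 0,
(Below, Increasing) → −0.4, (Below, Decreasing) → −1. The orientation is the
standard damping one: push hard while the error is growing, ease off while it
is recovering; it produces the four large/small plateaus of the response
surface. Centre-of-area defuzzification with singletons is
`ΔCout = Σᵣ i(r)·o(r)`, where `i(r)` multiplies the rule's input memberships
and the Near rule uses the error membership alone (the "Any" slope zone is
read as no slope factor, one of two defensible readings). The increment is
clamped to [−1, 1] and integrated as `cout ← cout + (G / f_update)·ΔCout`,
so the gain `G` (bpm/s) is exactly the maximal slew of the commanded
heart-rate effect — this is the only reading under which gains 2/5/10
correspond to 2/5/10 bpm/s. `cout` is clamped to ±200 by default
(anti-windup; the magnitude needed in a trial is about half the
normalization span, ~130).

Two small consequences of smooth sigmoids are worth knowing. First, strict
sign correctness (`ΔHR > 0 ⇒ ΔCout ≥ 0` for *every* slope) cannot hold for
any strictly positive sigmoid pair combined with asymmetric singletons
(±1 vs ±0.4): for errors inside (0, ~0.6) bpm with a fully Decreasing slope
the Below tail (weight −1) slightly outweighs the Above tail, giving
`ΔCout ≈ −0.005`. The tests therefore assert exact sign correctness for
`|ΔHR| ≥ 1` bpm and `|ΔCout| < 0.05` inside the dead zone. Second, at
`ΔHR = SP` exactly, the symmetric tails cancel and `cout` is stationary.

## Calibration and the `cout` → waveform map

The stimulation sweep applies 1–30 Hz in 1 Hz steps, holding each step 15 s
(five plant time constants at the default `τ = 3` s) and reading the rolling
estimator at the end of the dwell; an OLS fit of heart-rate drop vs frequency
gives the sensitivity in bpm/Hz, excluding any saturated plateau at the top
of the sweep. The block sweep, under maximal 30 Hz perturbation, raises the
10 kHz amplitude in 0.1 mA p-p steps until the resting baseline is recovered.
Onset ("the heart rate began to rise") is judged against the running plateau
mean with a 2 bpm threshold — the in-vivo criterion is not recorded, so this
is our choice and it is config-exposed — with two robustness refinements
adopted after characterising the estimator on the synthetic bench:

* a rise must persist for two consecutive amplitudes (a single rolling-window
  reading has ~2 bpm of beat-jitter noise, so one 3σ spike per ~50 sweeps
  would otherwise trigger a false onset);
* the reported starting block current is the crossing of the fitted rising
  line with the plateau level (back-extrapolation), which removes the
  threshold detection lag of up to `2 bpm / S_block` mA for low-sensitivity
  animals; the raw grid value is retained alongside.

The fitted segment runs from the starting point to the first reading within
2 bpm of baseline, so the fully blocked flat tail never leaks into the slope.
Across 100 synthetic animals with beat jitter this recovers the stimulation
slope within 10%, the onset within one 0.1 mA step, and the block slope
within 15% (the acceptance suite re-runs exactly this check).

The conversion is then `freq = clamp(cout / S_stim, 0, 30)` Hz for positive
`cout` (50 µs pulses at the maximal-threshold amplitude) and
`amp = |cout| / S_block + A_start` (capped at 10 mA p-p) for negative
`cout` — adding the starting block current skips the sub-blocking dead zone.
Mode switching at sign changes is instantaneous with no hysteresis: the
in-vivo reports suggest block→stim transitions are slower and hint at an
asymmetric threshold without defining one, so the plain scheme is
implemented. One caveat follows from error propagation: an onset estimation
error of δ mA shifts every block response by `S_block·δ` bpm, so for small
commands (|cout| ≈ 5) the realized effect can deviate from `cout` by more
than 15% whenever `δ > 0.75 / S_block` — unavoidable at a 0.1 mA sweep
resolution. The round-trip property (command ≈ cout bpm within 15% over
|cout| ∈ [5, 60]) is therefore verified with noiseless sweeps, which is what
it states about the conversion logic.

## The synthetic plant

Heart rate relaxes with a single time constant toward a target set by the
instantaneous vagal drive:

```
D  = clamp( min(S_p · f_perturb, max_drop) · T(amp) + S_c · f_stim, 0, max_drop )
HR_target = baseline − D
HR ← HR_target + (HR − HR_target) · exp(−dt/τ)
```

`T(amp)` is the block transmission factor: 1 at or below the starting block
current, then `1 − S_block·(amp − A_start)/max_drop`, clamped to [0, 1].
Saturation is applied to the perturbation pathway *before* the transmission
factor; with that ordering the heart-rate recovery slope under maximal
perturbation equals `S_block` exactly for every animal (applying `T` first
and clamping afterwards creates a dead region and a distorted slope whenever
`30·S_p > max_drop`). Block attenuates only perturbation-evoked activity:
the control electrode is either stimulating or blocking, never both, so the
control stimulation term is never gated by `T`.

Beats are emitted by integrating the instantaneous rate `HR/60` and placing
an R event at each integer crossing of the integral; each inter-beat interval
is then perturbed by `Normal(0, 2 ms)`, truncated at a 20 ms physiological
floor. The 2 ms default is small but deliberately non-zero: it propagates
into ~1–2 bpm of noise in the 2 s rolling estimate (more at low heart rates,
where fewer intervals fall in the window), which is what exercises the
estimator averaging and the calibration robustness. The estimator itself
takes the mean of the R–R intervals whose *later* R event falls in the
half-open window `(t − 2 s, t]` — mean of intervals then reciprocal, matching
the "mean R–R interval, converted to bpm" description literally — and holds
the last valid estimate over data gaps.

**Population model.** Animals are drawn with stimulation sensitivity,
starting block current and block sensitivity from truncated normal
distributions on the reported ranges ([5, 12] bpm/Hz, [0.5, 3] mA,
[14.5, 160] bpm/mA). Because truncation to an asymmetric range shifts the
mean (naively, the block-sensitivity mean would land at 73.6 instead of
64.3 bpm/mA), the underlying location of each distribution is solved
numerically so that the *truncated* mean equals the reported cohort mean
(9.2, 1.8, 64.3) — the reported statistics are, after all, statistics of
range-limited samples. The standard deviation cannot be matched
simultaneously: a truncated normal on [14.5, 160] cannot exceed the uniform
limit of ~42 bpm/mA, short of the reported 45, so the mean is prioritised.
Baseline heart rate is `Normal(400, 30)` bpm (a typical anesthetized-rat
range), the control-electrode sensitivity equals the perturbation
sensitivity (same nerve, same electrode design), and
`max_drop = min(30·S_p, 0.9·baseline)`. `τ` defaults to 3 s; baseline drift
after the responsiveness check, observed inconsistently in vivo, is not
modeled (keeping trials deterministic given a seed).

## Protocol and numerics

A trial measures the anchors (≤ 30 s of maximal control-electrode
stimulation for the 0% anchor; 120 s of recovery — the stated minimum wait,
fixed for determinism — then the resting estimate as the 100% anchor;
anchors closer than 20 bpm raise an unresponsive-plant error), fixes the
setpoint at the anchor midpoint in bpm for the whole trial, and runs 840 s
of closed loop: 120 s pre-control, 1→30 Hz at 1 Hz per 10 s, the mirrored
down-ramp, 120 s post-control. The plant advances in 0.05 s substeps between
controller updates using the exact exponential update (so the integration is
unconditionally stable and `dt`-exact for piecewise-constant inputs); a 3 s
rest pre-roll populates the estimator window before `t = 0`, and the `t = 0`
row logs the initial state, giving 1681 rows at 2 Hz. One master seed fans
out to per-component streams (animal draws, calibration noise, anchor noise,
trial beats) through fixed offsets, so adding a noise source never perturbs
existing streams and identical seeds give bit-identical trials.

Per-trial metrics use the 40–60% normalized band: time to band (first sample
under the upper edge), time in band (inter-sample intervals attributed to
their right edge), and the excursion count — the number of alternations
between maximal runs strictly above the upper edge and strictly below the
lower one, so repeated same-side exits never count as oscillation. A trial is
Oscillations at ≥ 5 alternations, else Slow if more than half the 840 s
controller-on window is outside the band, else Stable; the oscillation check
takes precedence. Partial excursions at trial end count like any other run
(the alternation rule makes the end-effect at most one count). Rank-sum
comparisons use the exact Mann–Whitney distribution for group sizes ≤ 12
without ties and the tie-corrected normal approximation otherwise, at
α = 0.005 as printed in the source analysis (possibly a typographical
variant of 0.05; it is config-exposed).

## What the bench does and does not show

The simulated trials reproduce the *ordering* phenomena: median time-to-band
decreases with gain, higher gain yields more time at setpoint, and all
quantities scale as the gain-as-slew-bound analysis predicts. The problem
sizes used throughout the test suite are 20 synthetic animals × 3 gains at
τ = 3 s plus 10 animals at τ = 6 s for the stability check, 100 animals for
calibration recovery, and 10,000 draws for the population means.

Two in-vivo behaviours do **not** emerge under this plant, and the acceptance
suite reports them as failures rather than weakening the checks:

* **Low-gain Slow trials.** The perturbation ramp demands a sustained
  correction rate of only ~0.9 bpm/s (one sensitivity step per 10 s), below
  even the damped slew of the G = 2 controller, so tracking error stays a few
  bpm — far inside a band whose half-width is ~25 bpm on this plant's
  normalization span. G = 2 trials spend only the initial descent
  (~110–150 s) outside the band, not the > 420 s the Slow label requires.
* **High-gain oscillations.** The slope input is derivative action and the
  small-singleton (0.4) approach limits slew toward the setpoint, so the
  braking overshoot is roughly `0.08·G·τ` — about 5 bpm at G = 10, τ = 6 —
  an order below the band half-width. A first-order lag, however large
  within a physiological range, cannot make this loop ring.

Both behaviours in vivo plausibly ride on mechanisms outside this model:
slow block→stim mode transitions, calibration drift over hours, onset
activation, and a normalization span several-fold smaller in bpm than the
linear-to-30 Hz construction used here. Modeling any of those would be
speculation the source does not quantify, so the bench keeps the minimal
plant and reports the discrepancy honestly. Equally out of scope: baroreflex
and sympathetic compensation, respiratory sinus arrhythmia, anesthesia
depth, electrode impedance, and raw ECG synthesis (the plant emits R events
directly).

```{r example, eval = FALSE}
animal <- sample_animals(1, seed = 42)
cal <- calibrate_plant(animal, seed = 42)
trial <- run_trial(animal, gain = 5, seed = 42, calib = cal)
glance(trial)
autoplot(trial)
```
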