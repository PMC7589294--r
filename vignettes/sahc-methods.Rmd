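---
title: "Modelling and analysing gravitational-gradient centrifugation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and analysing gravitational-gradient centrifugation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sahcgrad)
```

## The problem

Short-arm human centrifugation (SAHC) is a candidate "artificial gravity"
countermeasure for spaceflight deconditioning.  Because the arm is short,
the centripetal acceleration varies steeply along the body: the g-level at
a point at distance $r$ from the rotation axis is $\omega^2 r / g_0$, so a
supine/standing person on a short arm experiences much more g at the feet
than at the head.  Moving the rotation axis position (RAP) from above the
head (P1) to the crown (P2) or down to heart level (P3) while holding the
foot-level g fixed reshapes this gradient — at P3 the head is on the far
side of the axis and experiences *headward* (−Gz) acceleration — and with
it the hydrostatic loading of the carotid and aortic baroreceptors, the
footward fluid shift, cerebral perfusion, and ultimately orthostatic
(g-) tolerance.

`sahcgrad` implements (i) the hydrostatic forward model of this geometry,
(ii) the signal-processing and statistical pipeline used to analyse
physiological responses to centrifuge runs, and (iii) a synthetic trial
generator with known ground truth so that the entire pipeline can be
validated end to end without human data.

## Hydrostatic model

Body positions are measured in metres from the sole of the foot (foot = 0).
The default reference body is 1.73 m tall with the heart at 1.24 m, aortic
baroreceptor at 1.30 m, carotid baroreceptor at 1.51 m and eye level at
1.62 m; arbitrary anthropometries are accepted, and `scale_body()` rescales
the landmarks affinely with stature.  The axis sits at height $h_a$ (P1:
stature + 0.49 m; P2: crown; P3: heart), and the radius of any point at
height $h$ is $r = |h_a - h|$.

Given the prescribed foot-level g, the spin rate solves
$\omega^2 r_{foot} = g_{foot}\, g_0$.  In the rotating frame the pressure
gradient along the radius is $dP/dr = \rho\, \omega^2 r$, so the pressure
offset of a point from heart level is

$$\Delta P = \rho\, k_{BP}\, \frac{\omega^2}{2}\,(r_p^2 - r_{heart}^2),$$

with $\rho = 1050$ kg/m³ (blood), $k_{BP} = 0.0075$ (Pa → mmHg) and $g_0 =
9.81$ m/s² exactly.  Note the factor ½ from integrating $\omega^2 r$: the
corresponding published table footnote omits it, but the printed pressure
values (166/148/115 mmHg at the foot for P1/P2/P3 at 2.4 g) are only
reproduced *with* the ½, so the implementation includes it.  The standing
comparator is linear, $\Delta P = -\rho\, k_{BP}\, g\, g_0\, (h -
h_{heart})$.  Signs follow the +Gz convention (positive footward) and
$\Delta P > 0$ means pressure above heart-level pressure.

The g-gradient is reported as $100\,(g_{foot} - g_{head})/g_{foot}$ using
the signed head-level g, so a headward head g yields a gradient above
100%.  The head landmark is an explicit parameter (default: crown) because
published gradient figures are not consistent with a single landmark: the
P1 head g-level of +0.5 matches the crown, the P3 value of −0.7 matches
eye level, and the quoted +81% P1 gradient is not reproducible from the
crown geometry (we obtain ≈78%).  We therefore do not guess a single
"correct" landmark and expose the choice instead.

```{r}
body <- body_landmarks()
p3 <- centrifuge_config("P3", g_foot = 2.4, body = body)
signed_g_at(p3, body, "eye")
g_gradient(p3, body, head_landmark = "eye")
hydrostatic_delta(centrifuge_config("P1", 2.4, body), body, "foot")
```

## Preprocessing

Channels (HR, MAP, SV, TPR, CO at beat-like ~1 Hz; calf circumference and
cerebral tissue saturation index at 10 Hz) are cleaned in three stages:

1. **Artifact scan** (`scan_artifacts()`): a sample is invalid when it
   falls outside wide physiological plausibility limits (HR 25–240 bpm,
   MAP 20–200 mmHg, SV 5–200 ml, TPR 100–6000 dyn·s·cm⁻⁵, cTSI 0–100%,
   CO 0.5–15 l/min; calf circumference within ±30 mm of its early-record
   level) or when it jumps by more than `max_sd_multiple` (default 3)
   whole-record SDs relative to the previous valid sample.  The SD is
   computed over in-limit samples so spikes do not inflate their own
   threshold, and a sample that agrees with its immediate raw predecessor
   is never flagged by the change rule — otherwise one borderline level
   shift would invalidate every following sample until the signal happened
   to return to its old level.  Validity is summarised over 10 s
   inspection frames.
2. **Gating**: a channel is resampled only if more than 95% of its samples
   are valid; otherwise that channel (and only that channel) is rejected.
3. **Resampling** (`resample_clean()`): a cubic interpolation spline
   (Forsythe–Malcolm–Moler end conditions; exact for cubic polynomials) is
   fitted through the valid samples only and evaluated on a uniform 4 Hz
   grid confined to the valid time range.  Masked samples provably never
   influence the output.

Time zero is the start of the constant-speed run phase; the default
schedule is 600 s baseline, 120 s ramp-up, 600 s run, 120 s ramp-down,
600 s recovery, i.e. baseline occupies [−720, −120) s.  The baseline
reference is the mean of the final 300 s of the baseline, and responses
are summarised as mean 2-minute epoch deltas tiling ramp-up through
recovery (12 epochs: 1 ramp-up, 5 run, 1 ramp-down, 5 recovery).  The
final run epoch is the "minute 10" value used in end-of-run summaries.
Empty epochs are reported as missing, never as zero.

## Pre-syncope classification

A run is PSS+ when any of: (i) a sustained concurrent reduction of HR and
MAP during rotation; (ii) a reported symptom (nausea, paleness,
dizziness); (iii) participant-requested termination.  The earliest
criterion met is recorded.  MAP stands in for "blood pressure" because it
is the continuously recorded pressure variable.

Criterion (i) is deliberately a *duration* rule on the decline itself
rather than a sliding-window correlation: local least-squares slopes
(centered 4 s windows) of both channels must be negative over an interval
whose effective duration — span minus the slope window, compensating the
dilation a centered window adds at the edges of a decline — reaches 15 s.
Brief sign interruptions (≤ 4 s) are bridged because autocorrelated
physiological noise produces slope excursions of a few seconds even inside
a genuine fall.  The net smoothed drop over the interval must exceed
`max(3 × noise scale, 5 bpm / 5 mmHg)` in each channel, where the noise
scale is the robust spread (MAD) of 15 s changes of the smoothed signal —
the drift the channel produces over the criterion's own timescale — and
the mean decline rate must reach 0.25 unit/s so that a slow run-phase
trend accumulating the same net change over minutes does not masquerade as
an acute pre-syncopal event.  With these rules a ≤ 14 s drop can never
trigger the criterion, while a 16 s concurrent drop above the amplitude
floor always does.

## Inference layer

* `fit_lmm()` fits `delta ~ time * position * g` with per-participant
  random intercepts by **maximum likelihood** (not REML), because p-values
  come from likelihood-ratio tests between models differing in fixed
  effects, which are invalid under REML.  Position is coded numerically as
  the axis distance from heart level in multiples of the heart-to-crown
  distance (P3 = 0, P2 = 1, P1 = 2).  Dropping an effect removes it and
  every interaction containing it; the LRT statistic is
  $2(\ell_{full} - \ell_{reduced})$ against the χ² with the
  parameter-count difference as df.  Rank-deficient fixed-effect designs
  fail loudly, naming the collinear terms.
* `epoch_anova_tukey()` performs the per-epoch secondary analysis: one-way
  ANOVA across positions followed by Tukey HSD pairwise comparisons
  (studentized range).  No multiplicity adjustment beyond Tukey is
  applied.
* `pss_chi_squared()` is the Pearson chi-squared test (no continuity
  correction) on the PSS+/PSS− table by position; df follows the table
  shape.
* `delta_correlation()` gives Pearson correlations between paired
  final-run-epoch deltas across runs (e.g. ΔCC vs ΔHR).

## Synthetic trial generator

`sim_config()` defaults describe the emulated trial: 15 participants
(the number of complete data sets), positions P1/P2/P3 × foot-level g
1.0/1.7/2.4 (one run each; 135 runs), the five-phase profile above, and
per-channel end-of-run response means calibrated to the published
tenth-minute deltas at +2.4 Gz (ΔHR +50/+24/+8 bpm, ΔCC +5.46/+4.11/+2.23
mm, ΔcTSI −2.85/−1.88/−0.95% for P1/P2/P3, with the published SDs).
Design choices the source data do not constrain, fixed once here:

* **Response shape**: linear rise to half the plateau during ramp-up, then
  exponential approach (τ = 60 s) to a plateau whose final-epoch mean
  equals the configured delta; linear fall during ramp-down and
  exponential recovery.  Only the final-run-epoch mean is a calibrated
  quantity.
* **Dose dependence**: effects scale linearly with foot-level g (zero at
  zero g), interpolating between the 1.0 and 2.4 g conditions.
* **Variance split**: the published between-run delta SD is split into a
  per-participant responsiveness intercept (fraction 0.6 of the
  mid-position SD) plus run-to-run variation, both scaling with g like the
  mean; a separate baseline intercept per participant cancels in deltas
  but exercises the mixed model's random intercept.
* **Noise**: AR(1) with a 2 s correlation time and channel-specific
  marginal SDs (e.g. 2 bpm HR, 0.4% cTSI).  Autocorrelation matters:
  white noise at 10 Hz would make consecutive-sample jumps that the
  artifact change rule correctly treats as glitches, and it would be an
  unrealistic model of beat-to-beat variability or NIRS drift.
* **Artifacts**: out-of-range spikes injected at rate 0.01 per sample
  (configurable), exercising the limits rule and the 95% gate.
* **Pre-syncope**: a per-run logistic probability
  `plogis(-3.2 + 1.5 g - 1.2 · offset)` (offset 0/1/2 for P1/P2/P3),
  rising with g and falling from P1 to P3 — PSS+ rates of roughly
  0.34/0.16/0.06 by position pooled over g, a clearly position-dependent
  pattern of the kind the emulated trial reports, chosen so the
  chi-squared recovery of the ordering has high power at n = 15.  40% of
  PSS+ runs carry a synthesized concurrent HR/MAP drop (30 bpm / 25 mmHg
  over 20 s with 20 s rebound, placed so it ends before the final run
  epoch), 40% a symptom event, 20% a termination flag.
* **Determinism**: every run draws from its own substream seeded from
  (root seed, participant, position, g); identical configuration gives
  bit-identical runs.

What the generator does *not* emulate: beat-to-beat waveform morphology,
baroreflex feedback dynamics (responses are prescribed trajectories, not
closed-loop physiology), between-day session effects, motion-sickness
physiology, and NIRS optics.  Passing recovery tests therefore shows that
the pipeline correctly measures the structures it is pointed at — not that
real cardiovascular regulation behaves like the generator.

## Numerical choices and degenerate inputs

* Spline end conditions are FMM; the boundary error of any classical
  cubic-spline end condition is larger than the interior error, which is
  why validation bounds are asserted away from the first/last knot
  intervals.
* The 95% validity gate is strict (`fraction > 0.95`); a channel at
  exactly 95% is rejected.
* Epochs with no clean samples yield `NA` deltas with a zero sample count.
* `lrt()` on identical models returns statistic 0 with p = 1 (df 0);
  non-nested models are an error.
* Zero variance in a correlation input, empty channel series, all-zero
  contingency margins, and baselines shorter than the reference window are
  all signalled as typed conditions rather than returning numbers.
* Grid alignment: the 4 Hz grid is anchored to multiples of 0.25 s in
  absolute time, so epoch boundaries land identically across channels and
  runs.

## Problem sizes used in the validation suite

The packaged tests run the full pipeline at the trial's own scale
(n = 15, all positions) where the property under test concerns the trial
structure: parameter recovery averages 100 simulated trials restricted to
the 2.4 g runs and the three channels the recovery targets (HR, CC,
cTSI); pre-syncope ordering recovery uses 100 trials with the HR/MAP
channels; mixed-model type-I error uses 1000 null replicates of a
10-participant design with four epoch times per run, a size at which the
ML likelihood-ratio test is expected to be close to nominal.  The
variance-grid likelihood oracle uses a 4-participant toy on a 200 × 200
log-spaced grid, resolving the log-likelihood to well under 0.01.

## Known limitations

* The hydrostatic model is static: no pulsatility, no venous/arterial
  distinction, no baroreflex dynamics, no hydrostatic-indifference-point
  migration.
* The pre-syncope signal criterion is an operationalization of a clinical
  judgement; its thresholds (15 s, 5 bpm / 5 mmHg, 0.25 unit/s) are
  package defaults, exposed as parameters, not clinically validated
  cut-offs.
* Published human-trial statistics (fixed-effect tables, χ² and F values)
  are not reproducible without the raw trial data; they enter only as
  generator calibration.
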