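---
title: "Methods: degradation models, pipelines, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: degradation models, pipelines, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the degradation models and their assumptions, the analysis pipeline, the
numerical choices made where the underlying procedures leave freedom, and
what the synthetic-data generators do and do not establish.

## Hearing-impairment simulation

The simulator approximates three characteristics of moderate sensorineural
hearing loss: impaired frequency selectivity (broadened auditory filters),
elevated absolute thresholds, and loudness recruitment. It deliberately
models *signal* consequences, not physiology: the output is an ordinary
waveform that, when heard by a normal listener, carries the degraded
narrowband envelopes and the reduced, recruitment-shaped loudness an
impaired listener would receive from the original.

### Filterbank and envelope stage

Auditory filters are modelled as 4th-order gammatones on an ERB-spaced
grid: center frequencies start at 80 Hz and step one ERB-number unit
(`21.4 log10(4.37 f/1000 + 1)`) up to 10 kHz, giving 33 channels. Normal
filters have an equivalent rectangular bandwidth of
`ERB(f) = 24.7 (4.37 f/1000 + 1)` Hz; impaired filters are twice as broad
(`bandwidth_scale = 2`), representative of a moderate loss.

The filters are realized in the frequency domain with the analytic
gammatone magnitude response `[1 + ((f - cf)/b)^2]^-2` and zero phase,
rather than as time-domain IIR cascades. This choice has three
consequences the package relies on:

* the realized ERB equals the design ERB essentially exactly (the 2-ERB
  invariant is checked by numerical integration of `|H(f)|^2` in the test
  suite, at a 5% tolerance that in practice is met with large margin);
* band signals carry no group delay, so summing bands after per-band
  multiplication needs no delay compensation;
* suppressing negative frequencies makes the inverse FFT directly the
  analytic band signal, whose modulus and phase are the Hilbert envelope
  and fine structure — envelope extraction and filtering are one
  operation.

`impose_impaired_envelopes()` computes target envelopes once, from the
2-ERB analysis of the original input, and holds them fixed. Each iteration
re-analyzes the current output with the 1-ERB (normal) bank, extracts fresh
fine structure, multiplies the fixed targets back on, and sums bands. Ten
iterations are the default. Iterating matters because normal auditory
filtering partially restores a signal's own narrowband envelopes from its
fine structure; the fixed-point of the iteration is a waveform whose
*normal-hearing analysis* yields the impaired envelopes.
`envelope_correlation()` quantifies success as the mean band-wise Pearson
correlation between the normal-hearing envelopes of the processed signal
and the 2-ERB targets of the reference, excluding bands whose target
envelope RMS is below −60 dB re full scale (correlation is undefined on
silence). With the zero-phase filterbank the first multiplication already
lands close to the fixed point, so the iteration gain is small but
non-negative on average; the acceptance script measures the 10-iteration
correlation on ten speech-shaped noises.

### Loudness stage

`loudness_transform()` works on short-time spectra: Hann-windowed frames of
`2^round(log2(0.023 * rate))` samples (≈23 ms; 512 at 22.05 kHz) at 50%
overlap. The periodic Hann window satisfies the constant-overlap-add
property at this hop, so unity gains reconstruct the input exactly; gains
vary per frame and band, which is the usual weighted overlap-add
approximation. Bins are grouped into six octave bands centered at
250–8000 Hz with edges at geometric midpoints; bins below the lowest and
above the highest edge take the nearest band's gain.

Loudness is mapped on the categorical-unit (CU) scale with
piecewise-linear stand-in curves: the normal curve rises 0→50 CU between
the normal threshold (0 dB HL, with a configurable RETSPL table defaulting
to all zeros, i.e. HL ≡ SPL) and a 105 dB SPL uncomfortable-loudness
anchor; the impaired curve rises 0→50 CU between the band's audiometric
threshold and the same anchor. The published average-impaired
categorical-loudness datasets are not reproduced here; the stand-in keeps
the two anchors that define the behavior — loudness zero at the elevated
threshold, normal loudness at the anchor — and hence the expansive
(slope > 1) recruitment characteristic.

Per frame and band, input level L maps to the output level at which a
normal listener's loudness equals the impaired loudness of L. Two
refinements: the mapping never amplifies (`min(L, map(L))`), and below the
impaired threshold the recruitment slope is continued downward instead of
clamping at the normal threshold. The clamp variant would park every
sub-threshold input exactly *at* normal audibility (0 CU), a knife-edge
where measurement noise decides audibility; continuing the slope makes
"inaudible in, inaudible out" a robust, testable property, and makes the
realized audiometric threshold a well-defined boundary:
`simulated_threshold()` bisects the full transform with calibrated pure
tones to 0.05 dB and recovers the audiogram at all six frequencies.

Level calibration follows presentation practice: an `audio_signal` carries
`calibration_spl`, the dB SPL of a stated reference RMS (by default the
signal's own long-term RMS, matching calibration of stimuli to 65 dB SPL).
After both stages, `rms_equalize()` restores the intact input's RMS within
0.01 dB, so degradation never rides on an overall level change.

The full chain contains no random number generator; outputs are
bit-identical across runs.

## Scotoma simulation

The visual degradation is a *relative* central scotoma: the region under
the mask is blurred, not removed, since central field defects are mostly
experienced as blur or distortion rather than a hole.

* **Blur.** `gaussian_lowpass_frame()` applies an isotropic Gaussian whose
  amplitude response is 0.5 at the cutoff (default 0.15 cycles/deg, full
  width at half maximum), i.e. `sigma = sqrt(ln 2) / (sqrt 2 * pi * f)` ≈
  1.249° ≈ 55.8 px at 44.65 px/deg. The horizontal pixels-per-degree is
  used for both axes: the display is near-isotropic (44.65 vs 43.55
  px/deg) and a single sigma keeps the filter isotropic. Frames are
  reflectively padded before the FFT, preserving mean luminance at the
  edges. A cutoff so low that the 3-sigma kernel exceeds the frame is
  rejected.
* **Mask.** `build_scotoma_mask()` generates the 731 × 497 px alpha mask
  (≈17° × 11.5°): a half-ellipse with a flattened vertical edge (plane at
  −0.72 of the horizontal semi-axis), its boundary perturbed by seeded
  low-order sinusoidal harmonics (k = 2…6) — "semi-circular, yet
  irregular", and exactly reproducible per seed. The binary shape is
  rescaled so it spans its bounding box exactly, then alpha falls from 1
  to 0 over a 40-px raised-cosine ring of the Euclidean distance
  transform. The four trial orientations are axis flips and form a Klein
  four-group; orientation is fixed within a trial and randomized across
  trials by the caller.
* **Compositing.** `composite_scotoma()` blends
  `out = (1 − α)·frame + α·blurred` with the mask's bounding-box center on
  the (rounded) gaze sample; off-screen parts are cropped, so gaze far
  outside the display leaves the frame untouched. `render_degraded_clip()`
  pairs each frame with the temporally nearest gaze sample (1000 Hz gaze
  against 25 fps video by default), which bounds the gaze-to-frame timing
  error at half a frame interval.

## Schedule and behavioral scoring

`build_schedule()` reproduces the design: 12 emotions (three per
valence × arousal quadrant) × 8 actors = 96 stimuli, each presented once
per condition; 6 blocks of 8 condition sub-blocks × 16 trials; 64 practice
trials from 2 separate practice actors in a fixed condition order. Condition
order follows a balanced Latin square of order 8 (row-column construction),
with the row rotated by participant *and* block so orders are
counterbalanced both within and across participants — the exact
counterbalancing variant is not fully determined by the design description,
and this is the package's choice. An optional `split_actors` flag
implements the two-session variant in which each condition shows four
actors in blocks 1–3 and the other four in blocks 4–6, keeping the design
balanced after one session.

Accuracy is scored as the unbiased hit-rate
`Hu = correct^2 / (occurrences × responded)` = recall × precision, which
discounts hits earned by over-using a response; `Hu = 0` when the response
was never used (the formula's limit, avoiding 0/0). Hu is
arcsine-transformed before modelling. Chance level for k alternatives is
1/k; note that under pure guessing mean Hu sits near chance², not chance —
the test suite checks this against a direct multinomial simulation written
from the defining formula alone.

## Eye-tracking pipeline

Events arrive pre-parsed (fixations, saccades, blinks); the package does
no velocity-based event detection. Per trial the pipeline:

1. windows events to the first 1000 ms after stimulus onset (the duration
   of the shortest stimulus), *truncating* straddling events at the
   boundary for duration accounting — whether the original analysis
   truncated or dropped straddlers is not stated, so truncation is the
   default with a `truncate` flag;
2. discards trials containing a single blink strictly longer than 300 ms;
3. removes saccades with amplitudes strictly above the 49.6° display
   diagonal;
4. optionally keeps only correctly answered trials.

AOIs are rebuilt per frame from tracked landmarks using fixed corner
rules: eye boxes from the eyebrow points down to the eye–nose border (the
midpoint of left-pupil and nose-tip y), merged into one eyes region; the
nose from that border to the nose–mouth border (midpoint of right-nostril
and mouth-top y), sides at the nostrils; the mouth from its corner points
down to mouth-bottom. Everything is expanded by 10 px per side except
across the two shared borders, so the face AOIs tile without gap or
overlap. Hands are 80-px boxes centered on single hand track points (the
extent is not derivable from a point track and is configurable), trimmed
wherever they would overlap a face AOI by shrinking the edge that loses
the least area. Point-in-AOI tests are half-open vertically
(`top <= y < bottom`), so a point on a shared border belongs to exactly one
AOI. Fixations are resampled to 1-ms time-points (the native 1000 Hz
tracker rate) at the fixation's reported position and tested against the
temporally nearest frame's rectangles; per-trial proportions over eyes,
nose, mouth, hands, and the implicit elsewhere remainder sum to exactly 1,
and trials with no fixation time-point are flagged and excluded.

## Model selection

`fit_mixed_model()` wraps ML (not REML) `lmer` fits with sum-to-zero
factor coding. ML is required for AIC comparisons across fixed-effect
structures; sum-to-zero coding is what type-III tests presuppose.
Convergence failures and singular fits are *flags*, not errors: a fit is
singular when `lme4::isSingular()` triggers, any random-effect SD falls
below 1e-4 of the outcome SD, or any random-effect correlation exceeds
0.999 in magnitude (the detection thresholds are the package's choice).
`aic_ladder()` walks candidates from simple to complex and accepts a rung
only if it converged, is non-singular, and lowers the current AIC by at
least 2 (a drop of exactly 2 is accepted). `wald_anova()` produces the
type-III Wald chi-square deviance table via `car::Anova`;
`posthoc_contrasts()` produces pairwise estimated-marginal-mean contrasts
via emmeans with Bonferroni or FDR correction, on asymptotic (z) degrees
of freedom — appropriate for ML fits, at the cost of mild small-sample
anti-conservatism that the type-I calibration test tolerates explicitly.

## Synthetic data: what it emulates, and what passing tests show

All generators are pure functions of (parameters, seed).

* `gen_speech_like_audio()`: Gaussian noise with a −6 dB/oct spectral tilt
  above 500 Hz, amplitude-modulated by a lognormal envelope whose
  modulation energy lies in the syllabic 2–8 Hz band. It matches speech in
  exactly those statistics the envelope stage manipulates — broadband
  spectrum and slow envelopes — and nothing else (no harmonic structure,
  formants, or phonetics).
* `gen_actor_trackpoints()`: the full landmark set on a fixed facial
  layout with smooth sinusoidal whole-face and independent hand motion.
  Anatomical ordering (eyebrows above pupils above nose tip above mouth)
  holds by construction, so AOI assembly is exercised on valid geometry;
  it does not model expression-dependent deformation.
* `gen_gaze_trace()`: an alternating fixation–saccade renewal process.
  Durations and amplitudes are Gamma with shape 4 (right-skewed and
  positive, as in the eye-movement literature; only means are anchored to
  published group statistics), landing direction is biased toward the face
  center under intact video and away from it under degraded video (the
  compensatory eccentric-viewing strategy), and blinks are Poisson with
  lognormal durations. Defaults: saccadic amplitude means 2.83°/6.54°
  (young, intact/degraded video) and 1.58°/2.78° (older); fixation
  durations place young-intact at 450 ms — a typical face-viewing value,
  since absolute levels are not published — and apply the published
  differences (−126 ms for older adults; degradation shortens by 225 ms in
  young and 11 ms in older adults); blink rate 0.1 /s.
* `gen_responses()`: correct with the cell's configured probability
  (defaults follow the qualitative result ordering A < V < AV, degraded ≤
  intact, older ≈ 0.12 below young); errors decay with valence–arousal
  quadrant distance (factor 0.35 per step) times a per-emotion response
  bias, so Hu genuinely diverges from the raw hit-rate. Each participant
  carries a stable ability offset (normal, SD 0.3 on the log-odds scale):
  without it the participant random-intercept variance is exactly zero,
  every `(1|participant)` model is a singular fit, and the AIC ladder
  rightly rejects all additions — the offset is what makes the mixed-model
  machinery meaningfully testable, and real participants differ in just
  this way.

Passing tests therefore show that the pipeline recovers known parameters
from data with the right gross statistics; they cannot certify behavior on
real recordings (tracker noise, parsing errors, expression dynamics,
listener idiosyncrasies are all absent).

## Problem sizes and numerical tolerances

Simulation-backed checks run at deliberately modest sizes: audio tests use
1-s signals at 22.05 kHz (the filterbank needs ≥ 20 kHz; FFT lengths are
padded to powers of two), the iteration property uses 20 seeds, the
acceptance script uses ten 2.5-s signals, end-to-end accuracy recovery
uses 3 replicates of 6 + 6 participants, and the Wald type-I calibration
uses 100 null replicates of 30 × 8 observations. Key tolerances: RMS
equalization to 0.01 dB; realized-ERB ratio to 5%; blur half-amplitude to
2% on grating probes; threshold bisection to 0.05 dB; Monte-Carlo
recoveries to ~2% with the stated trial counts.

## Known limitations

Monaural processing only; no hearing-aid compensation or perceptual
validation against listeners; the loudness curves are parameterized
stand-ins anchored at threshold and discomfort, not fitted
categorical-loudness data; the scotoma models blur only (no
metamorphopsia) and its exact irregular outline is a seeded invention with
the documented size, softness, and semi-circularity; no real-time
rendering or tracker interface; no raw-sample gaze parsing; post-hoc
degrees of freedom are asymptotic.
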