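---
title: "Estimating blood pressure from radial pulse waveforms: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating blood pressure from radial pulse waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsebp)
```

`pulsebp` estimates systolic and diastolic blood pressure (SBP/DBP) from
the radial pulse waveform recorded by a small tactile sensor array. This
vignette documents the model and every consequential design choice: what the
synthetic data emulate, how the denoising and feature extraction work, which
parameters matter, and what the package's passing tests do — and do not —
demonstrate about real measurements.

## The pipeline

Five stages run in order (`run_bp_pipeline()`):

1. simulate (or load) multi-channel pulse recordings with paired cuff
   references;
2. select the array channel best aligned with the artery;
3. denoise that channel by empirical mode decomposition (EMD) and selective
   reconstruction;
4. segment beats, locate six fiducial points, compute eleven waveform
   features, and aggregate to one feature vector per record;
5. split 80/20, fit three tree-ensemble regressors per target, and report
   held-out agreement (R², Bland–Altman, error bands).

## The synthetic corpus

No public corpus pairs raw multi-channel radial tonometry with cuff
references, so the generator is a first-class, tested component rather than
a fixture. One beat is

$$y(t) = b + A_s e^{-(t-t_s)^2/2w_s^2} + A_d e^{-(t-t_d)^2/2w_d^2}
       + A_v \sin(\pi t / T), \qquad t \in [0, T),$$

two Gaussian bumps (systolic, dicrotic) on a diastolic baseline $b$, plus a
half-sine "valley" component that vanishes at the beat boundaries. The
valley term matters: concatenated beats then meet in a V-shaped diastolic
foot, as real arterial waveforms do. With flat-bottomed templates the onset
minimum is numerically ill-defined — after band-limited denoising its
location wanders by tens of milliseconds — whereas the V foot pins it to
within a sample or two. Bump widths are fixed fractions of the template
timings ($w_s = 0.34\,t_s$, $w_d = 0.26\,(t_d - t_s)$), chosen together with
the amplitude map below so that the dicrotic notch exists across the whole
configured BP × heart-rate grid (verified by a grid scan in the tests).

Ground-truth landmark positions are always computed numerically from the
sampled template (argmax/argmin of the actual waveform), never from the
nominal parameters, so the oracle and the signal can never disagree by
construction.

**BP → morphology map.** Real arterial physiology links pressure to
waveform shape in ways that are not fully known; the generator instead uses
an explicit monotone map so that parameter recovery is meaningful and
learnable by construction:

* systolic bump amplitude affine in SBP: $A_s = 0.90 + 0.012\,(SBP - 118)$;
* upstroke time affine in pulse pressure: $t_s = 0.16 - 0.0008\,(PP - 40)$
  (so the maximum slope grows with SBP);
* dicrotic-to-systolic amplitude ratio affine in DBP:
  $A_d/A_s = 0.32 + 0.006\,(DBP - 69.5)$ (so the augmentation index falls
  with DBP);
* systolic→dicrotic spacing affine in DBP:
  $t_d - t_s = 0.22 + 0.0025\,(DBP - 69.5)$;
* diastolic baseline affine in DBP; valley amplitude $A_v = 0.55 A_s$.

SBP is therefore encoded mainly in amplitude/slope features and DBP in
ratio/timing features — deliberately, because EMD denoising removes the
absolute baseline, so any DBP information placed only in the DC level would
be unrecoverable.

**Corpus structure.** Defaults emulate a 23-subject screening study with 49
records each (1127 records), SBP drawn within 98–138 mmHg and DBP within
58–81 mmHg: subject means are drawn from the inner 70% of each range, and
record-level values are normal around them (SD 3 / 2.5 mmHg), clamped into
the range — giving a roughly bell-shaped histogram strictly inside the
configured bounds. Heart rates are uniform in 60–90 bpm per subject with
per-beat lognormal period jitter (σ = 0.02 on the log scale; strictly
positive periods). Recordings are 10 s at 250 Hz — roughly a dozen beats,
enough for a stable median; the sampling rate is a conventional choice for
pulse waveform work, comfortably above the ~12 Hz band that carries the
morphology.

**Channels and disturbances.** Channel $k$ is
$g_k \times \text{clean} + \text{wander} + \text{noise} + \text{artifacts}$
with gains $(0.3, 1.0, 0.4)$ by default — one well-aligned element, two
attenuated neighbours, mimicking a 3×1 array where only one element sits
over the artery. Wander is a 0.25 Hz sinusoid at 0.3 of the beat amplitude
(respiration-like); noise is white with SD 0.05 of the beat amplitude
("moderate": clearly visible on the trace but far from obscuring the
beat); artifacts are damped 8–15 Hz transients occurring per beat with
probability 0.05, shared across channels as a wrist movement would be.

**What the simulation does not capture.** Real radial waveforms vary in
shape between and within subjects far beyond this template family
(arterial stiffness, reflections, respiration-coupled amplitude
modulation); sensor coupling drifts; the BP→shape link is subject-specific
and noisy rather than a fixed affine map; and cuff references themselves
carry several mmHg of error. Passing the recovery tests therefore shows the
*pipeline* is correct and the features carry the information the generator
put into them — it does not certify any accuracy level on human data.

## EMD denoising

`emd_decompose()` implements classical sifting: cubic-spline envelopes
through local maxima and minima (two extrema mirrored across each endpoint
to tame spline end swings), mean-envelope subtraction until the Cauchy-type
criterion $SD = \sum (h_{k-1}-h_k)^2 / \sum h_{k-1}^2 < 0.2$ (cap 100
iterations), recursion until the remainder is monotone or 10 IMFs.
Completeness — IMFs plus residue reproduce the input to machine precision —
holds by construction and is asserted over random corpora.

`classify_imfs()` labels each IMF by its dominant frequency, estimated as
zero-crossing rate / 2: above the pulse band it is noise, below it
baseline, the residue always baseline, and `denoise()` reconstructs from
the in-band IMFs only. The default band is **(0.5, 12) Hz**. The lower edge
sits below any plausible resting heart rate (30 bpm = 0.5 Hz). The upper
edge deserves a note: the fundamental plus usable harmonics of a pulse wave
end near 8 Hz, but the zero-crossing statistic systematically overestimates
the frequency of the IMF that carries the beat waveform whenever wide-band
noise is present (noise adds crossings in the quiet diastolic intervals).
With an 8 Hz edge that IMF is intermittently discarded and the
reconstruction collapses to a fraction of the beat amplitude; at 12 Hz it
is always retained, while genuine noise IMFs (observed dominant frequencies
30 Hz and above at 250 Hz sampling) are still rejected. Band, stopping
threshold and IMF cap are exposed in the `emd` section of
`pipeline_config()`.

## Channel selection

The quality score is the mean Pearson correlation of each detected beat
(resampled to a common length) against the channel's median beat,
multiplied by the median peak-to-trough beat amplitude — repeatable, large
beats win; flat or noise-dominated channels lose on both factors. Beat
detection for scoring runs on a lightly smoothed copy (40 ms moving
average) because the raw channels are noisy; the score itself uses the
detected beats. Ties break to the lowest channel index. On the default
corpus the configured aligned channel is recovered essentially always
(asserted ≥ 95%).

## Beats, fiducials, features

Systolic peaks are local maxima above an adaptive threshold (2nd/98th
percentile range, 60% up) with a minimum separation of one period at the
heart-rate upper bound; the onset between two peaks is the **last
sufficiently deep local minimum** before the second peak (depth within the
20th percentile of the inter-peak segment). That wording — the trough
immediately preceding the steep upstroke — is deliberate: band-limited
reconstruction can leave shallow mid-diastolic dips, and a global argmin
occasionally lands on them, while the last deep minimum is the foot.

Within a beat: diastolic point 1 is the onset sample; the systolic peak is
the first local maximum reaching 60% of the maximal onset-relative height
(ties to the earliest, honouring "first peak"); the maximum-slope point is
the argmax of the first difference on the upstroke (slope = difference ×
sampling rate, no extra smoothing — the signal is already denoised); the
dicrotic notch is the first local minimum after the systolic peak, the
dicrotic peak the first maximum after the notch; diastolic point 2 is the
final sample. Beats violating the landmark ordering or lacking a dicrotic
bump are flagged degenerate and excluded.

Amplitude features are measured relative to the onset level (diastolic
point 1 itself is reported raw — relative to itself it would be identically
zero), which makes the augmentation index scale-invariant. The augmentation
index follows the systolic/dicrotic direction by default; the inverse
convention common elsewhere in the pulse-wave-analysis literature is a
switch (`ai_convention`). Heart rate uses the systolic-to-systolic interval
of adjacent beats; the first beat of a record inherits the record's median
interval. Record-level features are componentwise medians over accepted
beats (robust to an occasional corrupted beat); records with fewer than 3
usable beats are rejected with a reason code, and the pipeline reconciles
accepted + rejected against the generated count.

Whether per-beat or per-record aggregation better matches practice is
genuinely open; the median was chosen for robustness and is asserted
invariant to single-beat corruption.

## Regression

`bp_model(formula, data, algorithm)` fits one target at a time (SBP and DBP
separately, mirroring how results are reported): `"rfr"` is
`randomForest` (100 trees, unconstrained depth), `"gbr"` is `xgboost`
(squared-error objective, depth 3, learning rate 0.1, 100 rounds,
single-threaded for determinism), `"abr"` is AdaBoost.R2 with linear loss
over depth-3 `rpart` trees and weighted-median aggregation, implemented in
the package. All fits are deterministic under a seed; prediction validates
the feature schema and names any missing column.

The default split is record-mode (uniform over records,
`round(ratio × n)` training rows — round-half-even, so 1128 records at 0.8
give 902/226). With ~49 records per subject, record-mode splitting leaks
subject identity into the test fold and flatters R²; subject-mode splitting
(all records of a subject on one side) is provided and exercised in the
tests, but record mode remains the default as the protocol most studies of
this kind appear to use. Neither is asserted as "the" correct protocol.

On the default corpus the held-out RFR reaches R² ≈ 0.99 (SBP) and ≈ 0.87
(DBP); the three ensembles land within ~0.01 of each other, so the package
treats R² differences below 0.01 as ties when asking whether the forest is
best — at n ≈ 225 test records such differences are well inside sampling
noise, and the exact ordering flips with the seed.

## Agreement statistics

`r_squared()` is $1 - SS_{res}/SS_{tot}$ about the reference (cuff) mean; a
zero-variance reference yields `NA` with a warning rather than an error or
a fabricated value. `bland_altman()` uses differences estimate − reference
(sign convention: positive bias = overestimation), bias ± 1.96 × sample SD
(n−1). `band_accuracy()` uses strict `|d| < threshold` — the bands are
printed as "<5 mmHg", so a tie at the threshold falls outside. Band
fractions are non-decreasing in the threshold by construction and the
report validates it. `build_report()` renders the algorithms × bands table
with percentages to one decimal; plotting (scatter with identity line,
Bland–Altman with bias/limit lines) is best-effort via base graphics, the
numeric report being the contract.

## Numerical choices and degenerate inputs

* Extrema detection treats plateaus as single extrema at their centre.
* Spline interpolation is `stats::spline` (Forsythe–Malcolm–Moler ends);
  envelope boundary handling mirrors up to two extrema across each end.
* Constant or monotone signals decompose to zero IMFs with residue = input;
  constant signals segment to zero beats; an all-flat recording is an
  error at channel selection ("no usable channel").
* A recording whose every IMF is classified noise/baseline raises an error
  naming the channel unusable rather than returning an empty signal.
* Degenerate single-bump beats (no dicrotic structure) are flagged, not
  force-fitted.
* All test problem sizes (corpus of 1127 records for recovery; 20–100
  records for the signal-processing properties; 4–8 s recordings in unit
  tests) were chosen as the smallest sizes at which the corresponding
  statistics are stable.

## Known limitations

* The EMD implementation is the classical single-realization algorithm;
  mode mixing under intermittent noise is mitigated by the wide
  classification band, not by ensemble-EMD variants (out of scope).
* The augmentation-index direction and the diastolic-point naming follow
  one reading of the conventional feature table; both ambiguities are
  documented at the relevant functions and the AI direction is switchable.
* Hyperparameters are sensible fixed defaults, not tuned; there is no
  search, calibration transfer, or neural alternative.
* Real-data performance claims cannot be made from the synthetic corpus;
  see "What the simulation does not capture" above.
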