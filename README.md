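# pulsebp

Cuffless blood-pressure estimation from radial pulse waveforms measured by a
multi-element tactile sensor array.

A pressure sensor pressed over the radial artery records the arterial pulse
wave — one beat runs from the diastolic onset through the systolic peak, the
dicrotic notch and the dicrotic peak back to the next onset. The shape and
timing of those landmarks carry information about systolic and diastolic
blood pressure (SBP/DBP), so a regression model trained against simultaneous
cuff references can estimate BP from the waveform alone. `pulsebp`
implements that analysis end to end for researchers working with (or
prototyping) tonometric sensor arrays:

1. **Synthetic corpus generation** — multi-channel pulse recordings with a
   known beat template, heart-rate jitter, baseline wander, wide-band noise
   and motion artifacts; exactly one array channel is well-aligned with the
   artery. Reference pressures span 98–138 mmHg (SBP) and 58–81 mmHg (DBP),
   and the mapping from BP to waveform morphology is explicit, so every
   downstream stage can be validated against ground truth.
2. **Hilbert–Huang preprocessing** — empirical mode decomposition (EMD):
   cubic-spline envelope sifting splits each channel into intrinsic mode
   functions (IMFs); the signal is reconstructed from the IMFs whose
   dominant frequency (zero-crossing rate / 2) lies in the pulse band,
   discarding high-frequency noise and low-frequency baseline wander.
3. **Channel selection** — each channel is scored by mean beat-to-beat
   correlation against its median beat times beat amplitude; the
   best-aligned element wins.
4. **Feature extraction** — per beat, six fiducial points (diastolic points
   1/2, maximum-slope point, systolic peak, dicrotic notch, dicrotic peak)
   and eleven features: heart rate, five amplitudes, maximum upstroke slope,
   augmentation index (systolic/dicrotic amplitude ratio), and the intervals
   T1 (onset→systolic), T2 (systolic→dicrotic), T3 (dicrotic→beat end).
   Record-level features are beat medians.
5. **Regression and agreement** — random forest (RFR), gradient boosting
   (GBR) and AdaBoost.R2 (ABR) regressors fit on an 80/20 train/test split,
   evaluated by R², Bland–Altman bias and limits of agreement
   (bias ± 1.96 SD), and the fraction of errors within <5/<10/<15 mmHg.

## Worked example

```r
library(pulsebp)

cfg <- pipeline_config(
  simulation = list(n_subjects = 8, records_per_subject = 15),
  seed = 11)
res <- run_bp_pipeline(cfg)
print(res)
```

```
bp_pipeline_result: 120/120 records featurized (0 rejected), split mode record
aligned channel 2 selected on 100.0% of records

SBP estimation accuracy (n = 24):
                                         R2   <5 mmHg  <10 mmHg  <15 mmHg
Random Forest Regression (RFR)        0.949    100.0%    100.0%    100.0%
Gradient Boosting Regression (GBR)    0.942    100.0%    100.0%    100.0%
Adaptive Boosting Regression (ABR)    0.938    100.0%    100.0%    100.0%

DBP estimation accuracy (n = 24):
                                         R2   <5 mmHg  <10 mmHg  <15 mmHg
Random Forest Regression (RFR)        0.736     91.7%    100.0%    100.0%
Gradient Boosting Regression (GBR)    0.707     91.7%    100.0%    100.0%
Adaptive Boosting Regression (ABR)    0.673     91.7%    100.0%    100.0%
```

Each row is one ensemble regressor; `R2` is the coefficient of determination
between cuff reference and estimate on the held-out fold, and the three band
columns give the percentage of test records whose absolute error is strictly
below 5, 10 and 15 mmHg. The channel-selection line confirms that the
quality score recovered the configured well-aligned array element.

Individual stages are exported for use on your own data: `denoise()`,
`select_best_channel()`, `segment_beats()`, `detect_fiducials()`,
`featurize_recording()`, `split_dataset()`, `bp_model()` (with `predict`,
`summary` methods), `r_squared()`, `bland_altman()`, `band_accuracy()`,
`build_report()`. Waveform and feature tables travel as plain CSV
(`write_waveform_csv()`, `write_feature_csv()`); configurations as YAML
(`read_pipeline_config()`).

## Scope

The package operates on waveform time series; sensor physics (the
piezoresistive element, its fabrication and characterization) is out of
scope, as are hemodynamic (Windkessel-style) simulation, Hilbert spectral
analysis, ensemble-EMD variants, and AAMI/BHS grading protocols. See
`vignettes/bp-estimation-methods.Rmd` for the model details, tunable
parameters, and known limitations.
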