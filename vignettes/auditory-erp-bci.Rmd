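---
title: "Auditory oddball ERP-BCI analysis with a single prefrontal EEG channel"
author: "erpbci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditory oddball ERP-BCI analysis with a single prefrontal EEG channel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpbci)
```

## The paradigm and the analysis problem

An auditory oddball brain-computer interface presents a stream of five
natural sounds (duck, singing bird, frog, seagull, dove), each rendered
from a distinct azimuth (0, 45, 90, 135, 180 degrees) over earphones. The
user attends one of the five sounds — the *target* — and silently counts
its occurrences. Attended stimuli evoke enhanced event-related potentials
(ERPs): a negative deflection around 200–350 ms (N200) and a positive
deflection that here may fall anywhere between 350 and 1000 ms
(P300-family). Decoding *which* sound the user attends from a single
prefrontal EEG channel (Fpz referenced to the left earlobe, 512 Hz) turns
the paradigm into a five-command communication device.

One *trial* consists of 30 *sequences*; each sequence is an independent
random permutation of the five sounds, presented at a 300 ms
stimulus-onset asynchrony (150 ms sound + 150 ms silence). A trial
therefore has 150 stimulus events (30 per sound), spans 45 s, and fixes
one target. A *run* is five trials, one per target; the offline dataset
of one subject is three runs (15 trials, 2,250 one-second epochs).

Single epochs at this electrode are too noisy to classify reliably. The
pipeline instead classifies the *grand-average waveform* — the pointwise
mean of the 30 epochs of one sound within one trial — while the
classifier is *trained* on single-epoch features so that it sees the
single-trial variability.

## Spatialization

Azimuths 0, 90 and 180 degrees are rendered by interaural level
differences (ILD) alone; 45 and 135 degrees additionally delay the far
ear by the interaural time difference

$$\mathrm{ITD}(\theta) = \frac{r}{c}\,(\theta + \sin\theta),$$

with $r = 0.9$ and $c = 340.0$ taken verbatim from the paradigm
definition and $\theta$ the azimuth in radians (`computeITD()`). Both
constants are configurable; note that $r = 0.9$ is kept exactly as
printed even though it is large for a head radius in meters — the
resulting delays (3.95 ms at 45 degrees) are simply what the printed
parameters imply. The ILD gain table is a package default (0/−20 dB at
the extremes, −3/−9 dB at the oblique azimuths, symmetric at center),
since the original gains were tuned by ear and never published; it is
fully configurable through `spatializationParams()`. Delays are rounded
to whole samples (no fractional-delay filtering), and
`normalizeStimuli()` equalizes peak amplitude across the five stereo
files so loudness alone cannot mark a sound.

## The synthetic-data generator

No public recording of this paradigm exists, so the package ships a
generator (`simulateSubject()`, `simulateRecording()`) whose defaults
encode the study conditions; it is first-class, tested code, not a test
fixture.

* **ERP morphology.** A subject's target response is a sum of two
  Gaussian bumps (`erpTemplate()`): negative, mean −1.35 uV at 281 ms
  (sd 35 ms wide); positive, mean +1.88 uV at 748 ms (120 ms wide).
  Subject-to-subject variability draws latencies and amplitudes from
  normal distributions with the published grand-average means and SDs
  (281 ± 38 ms, −1.35 ± 0.67 uV; 748 ± 205 ms, +1.88 ± 1.71 uV),
  truncated to the component search windows and to minimum absolute
  amplitudes (0.4 / 0.5 uV) so that every simulated subject carries a
  detectable ERP. Per-event amplitude jitter is lognormal with a
  coefficient of variation of 0.3. The non-target response defaults to
  flat zero (near-flat in the real recordings) and can be given small
  bumps to emulate atypical subjects.
* **Noise.** Background noise is half white, half 1/f-shaped by
  variance, with a total standard deviation of 4.5 uV. The level is a
  compromise fixed by two constraints: single epochs should be hard to
  classify while 30-epoch averages are clean, and raw trials must stay
  inside the +40.0/−25.0 uV artifact screen with probability above 0.99
  (the screen sits only 5.6 noise SDs below zero, which caps how loud
  the background can be). Under these defaults single-epoch
  discriminability is well above floor; the screen bound prevents
  pushing it all the way to chance.
* **Overlap.** Because the SOA (0.3 s) is shorter than the epoch (1 s),
  consecutive responses overlap and sum, exactly as in the real
  paradigm; no correction is applied. One consequence is accepted
  openly: even noiseless grand averages carry bleed from neighbouring
  target events, which can displace a late, broad positive peak by a few
  samples. Peak-recovery validation therefore uses schedules whose
  targets do not overlap one another, and references the peaks of the
  noiseless template waveform (the bump-center parameter is not the
  composite waveform's extremum when the two bumps interact).
* **Artifacts.** Default recordings pass the amplitude screen; the
  screen is exercised by `injectArtifact()`, which adds a 50 ms
  raised-cosine excursion. A simulated trial that fails the screen is
  re-recorded with fresh randomness, mirroring the experimental
  protocol.
* **Determinism.** All randomness flows through R's seeded generator;
  a subject *is* its seed.

What the generator does **not** emulate: biophysical dipole geometry,
ocular artifacts (the paradigm records eyes-closed), electrode-shift
nonstationarity within a session, and fatigue drift. Passing tests on
synthetic data therefore validate the *pipeline arithmetic and
machinery*, not the real-EEG detection rates, which are anchored instead
through the published performance tables bundled in
`referenceBenchmarks()`.

## Preprocessing

The chain order is fixed: 50 Hz notch → 0.5–10 Hz Butterworth band-pass
→ epoching with 100 ms pre-stimulus baseline correction → (averaging,
when grand averages are needed) → downsampling to 16 features.

* The notch is a second-order IIR with quality factor 30, applied
  zero-phase; no design was specified, and at 20 dB+ attenuation the
  choice is immaterial for the 0.5–10 Hz band that survives anyway.
* The band-pass is realized as cascaded order-4 high-pass and order-4
  low-pass sections rather than a single band-pass design: the low edge
  (0.5 Hz of a 256 Hz Nyquist) makes one-shot transfer-function designs
  numerically fragile. Filtering is forward–backward (zero-phase) by
  default, the standard for offline ERP work, because it preserves
  latencies; each pass is −3 dB at the cutoffs. A causal mode is
  available for online emulation.
* Epochs are half-open windows `[onset, onset + 1 s)` of 512 samples,
  0-based; the baseline is the mean over `[onset − 0.1 s, onset)` (51
  samples).
* Downsampling to 16 Hz uses block averaging (the mean of each
  32-sample block), which acts as an anti-alias filter; the band edge
  (10 Hz) exceeds the 8 Hz Nyquist of the feature rate, so plain
  decimation would alias. Plain decimation is available as an option.
* The +40.0/−25.0 uV artifact screen operates per trial on the raw,
  pre-filter microvolt values.

## SWLDA classification

`swldaFit()` implements stepwise linear discriminant analysis as
stepwise least-squares regression of coded labels (target +1,
non-target −1): the forward step adds the unselected feature with the
smallest coefficient p-value if it is below 0.10; after every addition
the backward step repeatedly removes features whose p-value exceeds
0.15; iteration stops at a fixed point. Final weights are the
least-squares coefficients on the retained set; the intercept is always
present and never stepped. The discriminant score is the raw linear
value — no probability calibration is applied, because only the ranking
of the five grand-average scores matters for the decision.

Numerical choices: p-value ties resolve to the lower feature index;
candidates whose addition would make the design matrix numerically
rank-deficient (condition number above 1e10) are skipped, so duplicated
or collinear features cannot crash the fit; class imbalance (30 targets
vs 120 non-targets per trial) is left unweighted. Internally the
stepwise loop runs on Gram sufficient statistics (Cholesky subset OLS),
which makes each candidate evaluation independent of the number of
epochs and lets cross-validation loops add per-trial Gram blocks instead
of rebuilding design matrices; the test suite pins its p-values to an
independent normal-equations oracle at 1e−10.

`decideTarget()` applies the output rule: the highest-scoring label
wins; if that label is not an eligible command (sounds 2 and 4 are never
eligible online), the decision falls to the next-highest score. Ties
resolve to the lower label number.

## Evaluation machinery

* **LOTOCV** (`lotocv()`): each of the 15 trials is held out in turn;
  training uses the sub-trial features of the other 14 (2,100 epochs),
  testing the held-out trial's five grand averages. With a reduced
  candidate set the *candidates-only* scheme trains only on trials whose
  target is a candidate (11/8/5 trials → 1,650/1,200/750 epochs for
  4/3/2 commands), while the *train-on-all* scheme keeps all 14.
* **Reduced-command sweep** (`reducedCommandSweep()`): averages fold
  accuracies over all size-K candidate subsets that contain the fold's
  true target — a fold's accuracy is undefined under a subset that
  excludes its target, so such pairs are not enumerated.
* **ITR** (`itr()`): Wolpaw's formula at T = 45 s. The value is returned
  unclipped; note that the formula is log2 N minus the entropy of the
  induced outcome distribution and is therefore never negative.
* **Signed R²** (`signedR2()`): per time point, the squared
  point-biserial correlation between amplitude and class, signed by the
  direction of the class mean difference — the convention of the BCI
  literature; the quantity was never written out as a formula in the
  original report.
* **Peaks** (`findPeaks()`): argmin over 200–350 ms and argmax over
  350–1000 ms, ties to the earliest sample.
* **Learning curve** (`learningCurve()`): for each fold, training trials
  are drawn uniformly at random from the remaining 14 at each probed
  size; results are averaged over repeats.
* **Online evaluation** (`fitSubjectModel()` + `onlineSession()`): a
  model fitted on all offline sub-trial data is frozen and applied to
  new trials with candidates {duck, frog, dove}; the second online
  protocol first appends two calibration runs to the training data and
  refits.

Report tables round accuracies to one decimal (percent) and ITRs to two
decimals, matching the published layout.

## Problem sizes used in the shipped checks

The validation suite runs entirely on synthetic subjects: structural
checks use full-size subjects (30 sequences, 15 trials); ceiling checks
use noiseless subjects; the calibrated-noise recovery check averages
5-command LOTOCV over 10 seeded subjects; the learning-curve trend uses
one subject with 60 random draws per training-set size; scheme and
template-shift comparisons average 10 seeded subjects each. These sizes
were chosen to make Monte-Carlo error small relative to the asserted
margins.

## Known limitations

* The generator's Gaussian-bump morphology and stationary noise are a
  deliberate simplification; real prefrontal EEG has richer spectra,
  nonstationarity and ocular contamination.
* At the calibrated noise level the synthetic task saturates near 100%
  LOTOCV accuracy, so learning curves plateau after very few training
  trials; the upward-trend property is verified as non-decrease rather
  than strict growth.
* The artifact screen caps the admissible noise level (the lower bound
  sits 5.6 SDs from zero), which prevents emulating subjects whose
  single-epoch SNR is at chance while keeping the screen pass rate.
* Real-subject detection rates are not reproducible from simulation;
  printed-arithmetic checks (ITR cells, confusion-matrix TPRs) anchor
  those numbers instead via the bundled reference tables.
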