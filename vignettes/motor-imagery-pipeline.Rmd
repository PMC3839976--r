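---
title: "Detecting motor-imagery command-following in EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting motor-imagery command-following in EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micf)
```

## The problem

In disorders-of-consciousness research, a patient who cannot respond
behaviorally may still follow a command by *imagining* a movement. If a
classifier can tell imagery trials from rest trials in the patient's EEG
significantly above chance, that is evidence of command-following.
`micf` implements the full analysis chain used for this question:
preprocessing, a battery of 20 EEG features, leave-one-out
cross-validated (LOOCV) classification with four classifiers, and the
chance-level statistics needed to call a subject "above chance" without
fooling oneself — plus a synthetic cohort generator, because this kind
of human EEG is rarely shareable, and every stage of the pipeline needs
data whose ground truth is known.

## Chance-level statistics

With `n1` imagery and `n2` rest trials retained after artifact
rejection (`N = n1 + n2`), the proportional chance criterion is

    Cpro = (n1/N)^2 + (n2/N)^2,

the accuracy expected when assignments are made by class proportion
alone; it is 0.5 for balanced classes and grows with imbalance. An
observed number of correct trials `n_c` is converted to

    z = (n_c - N * Cpro) / sqrt(N * Cpro * (1 - Cpro)),

with a two-sided standard-normal p-value, and the effect size is the
improvement over chance criterion

    IOCC = (accuracy - Cpro) / (1 - Cpro),

zero at chance, one at perfection, negative below chance. Because the
two-sided p is small for *significantly below-chance* results as well
(a real phenomenon under LOOCV overfitting — with balanced classes and
exchangeable data the majority vote of the training fold is biased
against the held-out trial, in the worst case down to accuracy 0), a
subject counts as above chance only when the p-value is below threshold
*and* IOCC > 0. Families of such decisions are corrected with the
Benjamini–Hochberg step-up (`fdr_bh()`), and group-level comparisons of
features and classifiers use exact, tie-aware Wilcoxon signed-rank
tests.

A note on the p-value convention: some legacy analyses evaluated the
normal *density* at z rather than the tail probability. The default
here is the tail; `compat_pdf = TRUE` reproduces the density convention
for comparability and nothing else.

## Preprocessing

The chain mirrors standard clinical-EEG practice: mastoid-average
re-referencing (when mastoids are present), zero-phase Butterworth
band-pass 1–48 Hz, decimation of 1000 Hz (patient-mode) recordings to
250 Hz, segmentation into 4-s epochs starting at the end of each
instruction, automatic artifact rejection, and common average reference
(CAR) applied per epoch after segmentation.

The band-pass is implemented as an order-2 high-pass at 1 Hz plus an
order-8 low-pass at 48 Hz, each run forward–backward with
`signal::filtfilt`. A single 16-pole band-pass with a normalized lower
edge of 0.008 is numerically fragile under `filtfilt`; the cascade has
the same 48 dB/oct roll-off at the upper edge per pass and attenuates
both 0.2 Hz drift and 60 Hz mains by more than 40 dB (asserted in the
tests by probing the filter with sinusoids).

Artifact rejection removes an epoch when any channel shows (a) a
sample-to-sample step above 50 µV, (b) a peak-to-peak range above
200 µV within any 200-ms window, or (c) a range *below* 0.5 µV within
any 100-ms window (a flat-line detector). Windows slide one sample at a
time. The classical analyzer semantics also extend a contaminated
region by a surround (±100 ms for rule a, ±500 ms for b and c); since
the decision here is per 4-s epoch, a violation anywhere in the epoch
already rejects it, and the surrounds add nothing within an epoch —
they would only matter for continuous-data marking, which this package
does not do. Rejection operates on the signal as it arrives at the
inspection stage; note that zero-phase band-pass filtering smears
single-sample steps, so threshold-style artifacts are detected on the
segmented signal before any additional smoothing is applied to it.
Rejection reasons are logged per epoch (rule and first offending
channel), and the surviving per-condition counts feed `Cpro`.

## The feature battery

Twenty features are computed per trial; dimensions quoted for 21
channels and 12 frequency bins.

* **Hjorth activity / mobility / complexity** (21 each): variance,
  normalized first-derivative RMS, and the mobility ratio.
* **Brainrate** (21): spectrally weighted mean of the five classical
  band midpoints (2.5, 6, 10.5, 16.5, 25 Hz).
* **Wackermann Σ / Φ / Ω** (1 each): global field strength, global
  frequency, and spatial complexity (the exponentiated eigenvalue
  entropy of the channel covariance). These are inherently *global*
  quantities — Ω is undefined per channel, so all three are computed
  once per epoch even though per-channel wording appears in parts of
  the BCI literature.
* **Hurst exponent** (21): rescaled-range slope over the dyadic window
  ladder 16…n/4. R/S analysis is biased upward at these epoch lengths;
  white noise lands near 0.55 rather than 0.50, which the tests encode.
* **FFT** (252): magnitude spectrum of a zero-padded 1024-point
  transform, averaged into 12 bins of width 2.44 Hz centered at
  1 + 2.44·j Hz (j = 0…11; last center 27.84 Hz). The often-quoted
  "124 frequency steps between 1 and 30 Hz" does not correspond to any
  single transform length at 250 Hz / 4 s; 1024-point zero-padding
  (Δf ≈ 0.244 Hz) is used and the mismatch accepted.
* **Coherence** (2520): Welch magnitude-squared coherence per unordered
  pair, 8 Hamming segments at 50% overlap, 256-point transforms,
  bin-averaged. Estimator bias for independent signals is roughly one
  over the number of segments, which the tests assert against an
  independently coded oracle.
* **PDC / DTF** (5040 each): from a least-squares MVAR fit with order
  selected by the Schwarz criterion in 1…20. PDC column-normalizes the
  Fourier-transformed coefficient matrix (outflow normalization —
  Σ|PDC|² over targets is exactly 1 per source and frequency); DTF
  row-normalizes the transfer matrix.
* **Spectral Granger causality** (GW 5040, pp 252): Geweke's
  frequency-domain measure from *bivariate* fits per directed pair
  (pairwise convention), with `pp` the univariate autoregressive power
  spectrum per channel.
* **Entropies**: approximate entropy (m = 2, r = 0.2·SD — conventional
  defaults, configurable); Shannon and Rényi entropy by m-spacing
  estimators (m = ⌊√n⌋; the Shannon variant uses Ebrahimi boundary
  weights, and both are checked against Gaussian/uniform closed forms);
  Tsallis entropy by the Leonenko k-NN estimator (q = 1.5, k = 4);
  Bhattacharyya distance between the two halves of the epoch by a
  symmetrized k-NN plug-in with an analytic Gamma-moment bias
  correction; and correntropy, the mean Gaussian kernel on lag-1
  differences with adaptive width 0.2·SD. Where the field's wording
  leaves the pairing or order parameter open (Rényi α, Tsallis q,
  Bhattacharyya inputs, correntropy lag), the choice is documented here
  and exposed as an option.

Feature matrices carry a degeneracy flag (all rows identical, or any
non-finite value). Degenerate matrices are excluded from
classification with a failed result — this reproduces the known
pathology where a constant feature (e.g. a brainrate stuck at one
value) would otherwise be "classified" at a meaningless accuracy.

## Classification

LOOCV over trials: each trial is predicted from a model trained on all
others. Four classifiers: DADF (diagonal quadratic discriminant
analysis, i.e. Gaussian naive Bayes with class-specific diagonal
covariances), k-nearest-neighbour with k = 1 and k = 3 (Euclidean), and
a linear soft-margin SVM (C = 1). Standardization with training-fold
statistics is on for the SVM and off otherwise, mirroring the usual
toolbox defaults. Determinism matters for reproducibility, so knn
breaks distance ties toward the lower training index (documented — the
original toolboxes' tie behavior is unknowable) and vote ties fall back
to the nearest neighbour. DADF with a zero within-class variance raises
a recorded failure rather than a prediction; failures are never coerced
to chance-level accuracies, preserving the reduced-degrees-of-freedom
behavior such features produce in group comparisons.

## Coherence condition maps

For figures-level analysis the coherence is pooled: Welch cross-spectra
are accumulated over *all* trials of a condition before forming the
msc, then the imagery and rest maps are compared per pair and bin with
Fisher's r-to-z applied to the coherence magnitude `sqrt(msc)` (the
correlation analog; `fisher_on_msc = TRUE` transforms the msc itself),
using

    Z = (z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3)),

where the effective `n` is the pooled Welch segment count per condition
(trials × segments per trial) — the closest reading of "taking into
account the number of samples and trials" that yields a defined
standard error for pooled spectra. Within-subject significance is
BH-corrected over the full pair × bin family, and cohort maps count
subjects significant per pair and bin on a 13-electrode display subset.

## The synthetic cohort generator

Each subject is a continuous multichannel recording with interleaved
imagery/rest events (24 per condition; instructions of 9.5 s and 6 s
respectively, each followed by a 5-s response window; conditions
shuffled under the subject seed). The signal model:

* **Background**: per-channel 1/f^β noise (β = 1 by default, a typical
  broadband EEG slope over 1–48 Hz) mixed with a spatially shared
  component carrying 30% of the variance, so baseline coherence is
  neither 0 nor 1; total RMS 10 µV.
* **µ-rhythm**: band-passed (8–13 Hz) noise — not a sinusoid, so
  spectra and entropies stay realistic — added on C3, C4, CP1, CP2 with
  RMS `snr × 10 µV`. During imagery response windows its amplitude is
  scaled by `sqrt(1 - erd_depth)`, i.e. µ-power drops by `erd_depth`
  (event-related desynchronization).
* **Coherence coupling**: during imagery, the frontal channels F3, F4,
  Fz, F7, F8 have part of their signal *substituted* by a shared
  component with the same 1/f^β spectrum and RMS. The substitution
  weight is derived so the pooled msc on those pairs rises by
  `coh_gain` over baseline. Because the substitution preserves both
  power and spectral shape, the coupling is invisible to power-based
  features by construction — the coherence-versus-spectrum ordering in
  the results is a structural property of the effect, not a tuning
  artifact.
* **Null subjects**: `erd_depth = 0`, `coh_gain = 0`; nothing in the
  generative process then depends on the condition labels, so the two
  conditions are exchangeable by construction.
* **Cohorts**: responsive subjects get truncated-normal jitter on
  `erd_depth` (SD 0.1) to emulate inter-individual variability;
  per-subject seeds derive deterministically from the cohort seed, so a
  subject's data does not depend on cohort composition.

The default `snr = 0.4` was calibrated once so that the responsive
cohort's accuracies sit on the scale reported for healthy participants
in the motor-imagery literature this package models (power-spectrum
classification around .7, coherence higher, neither at ceiling for the
spectrum feature) rather than saturating at 1.0, and so that
single-subject detection at the default effect size is reliable.
Artifacts (voltage steps, flat stretches) are injectable on demand for
testing the rejection rules.

What the generator does *not* emulate: ocular/cardiac/muscle
components, non-stationary drowsiness effects, electrode pops beyond
the two injectable artifact kinds, volume-conduction geometry, or any
auditory stimulus waveform. Passing tests on synthetic cohorts
demonstrate that the pipeline recovers known structure and stays
calibrated under a known null — not that any particular real patient
dataset would behave the same way.

## Numerical choices and problem sizes

Epochs are 1000 samples at 250 Hz. MVAR order search never exceeds 20
and is also capped so the regression stays overdetermined. Singular
transfer matrices at isolated frequencies flag the affected bin rather
than aborting. Ties in entropy estimators are broken by a deterministic
relative jitter of 1e-10 and logged. The Wilcoxon implementation
enumerates the exact tie-aware null distribution up to n = 25 and uses
a continuity- and tie-corrected normal approximation above. EDF output
quantizes to 16 bits over each channel's observed range; events travel
in a JSON sidecar because plain EDF has no annotation channel. Tests
and the acceptance analysis run cohorts of 8–20 subjects with the full
24 + 24 trial protocol, and restrict classification to four cheap
features where the full battery's MVAR stages are not the object under
test; the expensive connectivity estimators are validated on small
channel subsets with known vector-autoregressive ground truth.

## Known limitations

ICA-based artifact removal is out of scope (its manual component
selection is not reproducible); only the automatic threshold rules are
implemented. The pairwise Granger convention cannot distinguish direct
from mediated influence in multichannel systems. The 180/120-family
feature comparisons implement "each feature versus all other features"
as one-sample signed-rank tests of the other features' metric values
against the target feature's value — the only reading that yields a
one-sample test with a defined n. Real-EEG validity of the synthetic
calibration is untested by construction.
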