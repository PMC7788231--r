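---
title: "Assessing consciousness from auditory-texture EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing consciousness from auditory-texture EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(auditoryPCI)
```

# The problem and the paradigm

Patients with prolonged disorders of consciousness (unresponsive wakefulness
syndrome, UWS, and the minimally conscious state, MCS) are routinely assessed
with behavioural scales such as the Coma Recovery Scale - Revised (CRS-R),
but behaviour can dissociate from awareness. This package implements an
EEG-based assessment built around responses to *naturalistic auditory
textures*: statistically defined sounds (rain, bubbling water) whose
statistics change once per trial at an unpredictable time (0.75, 1.6 or 3 s
after onset), with the sound continuing for 2 s after the change and sham
(no-change) trials interleaved. Two families of readouts are computed per
subject:

* **Event-related potentials (ERPs)** - the fronto-central P2 after sound
  onset and the slow centro-parietal positivity (CPP) that builds up after
  the statistics change, quantified as an area under the curve (AUC).
* **PCIa**, an auditory perturbational complexity index - the normalized
  Lempel-Ziv diversity of the binarized evoked EEG, computed around sound
  onset and around the change.

A linear discriminant classifier with leave-one-out cross-validation (LOOCV)
combines the P2 amplitude with both PCIa values to predict the clinical
category (MCS vs UWS).

# Preprocessing

`preprocessRecording()` applies a fixed stage order: bad-channel repair,
resampling, common-average re-referencing, band-pass filtering, epoching,
amplitude-based artifact rejection, and median baseline correction. The
defaults are the analysis defaults used throughout:

| stage | default | note |
|---|---|---|
| resample | 128 Hz | zero-phase anti-alias low-pass, integer decimation |
| reference | common average | per-sample channel mean becomes 0 |
| high-pass | Chebyshev II, order 15, 0.3 Hz, 40 dB stop-band | applied zero-phase |
| low-pass | Butterworth, order 4, 30 Hz | applied zero-phase |
| notch | 50 Hz biquad, off by default | line-noise option |
| epochs | [-0.5, +1.5) s around onset / change | half-open; time 0 = lock sample |
| rejection | any sample > ±200 µV | per trial, any channel |
| baseline | median in [-0.400, -0.150] s | robust to residual outliers |

Design notes:

* **Zero-phase filtering.** All IIR filters run forward-backward so that
  P2/CPP latencies are not shifted. Filters are designed in zero-pole-gain
  form and executed as second-order sections: an order-15 high-pass at
  0.3 Hz relative to 128 Hz is numerically meaningless in expanded
  polynomial (b, a) form, while the biquad cascade is exact (the designs are
  cross-checked against the `signal` package at moderate orders in the test
  suite). The stop-band attenuation (40 dB) is a package choice; only the
  filter families and orders are prescribed by the method.
* **Channel repair.** Bad channels are replaced by the inverse-distance
  weighted mean of their good montage neighbours. This is deliberately a
  simple, sane repair - spline interpolation on a head model is out of
  scope, and every analysis here is robust to the difference.
* **Ocular correction** is not implemented; the synthetic data carry no
  ocular artifacts. Sleep staging is represented by a per-trial `stage_ok`
  flag supplied by the generator rather than by a scoring algorithm.
* **Epoch conventions.** Windows are half-open `[-pre, +post)` with time 0
  at the lock sample; all times are in seconds. Trials whose window leaves
  the recording are kept as flagged metadata rows (reason `out_of_bounds`)
  so that trial accounting is always explicit.

# Electrode selection

Whether a subject shows an onset response, and where, is decided per subject
by a nonparametric cluster-based permutation test (`pairedPrePostStat()` +
`clusterPermutationTest()`): the 0.3 s silent pre-stimulus window is
compared sample-by-sample with the 0.3 s peri-stimulus window via a paired
t-statistic across trials; suprathreshold cells (two-sided t at α = 0.05,
a package default - the method defers to common practice without stating a
threshold) are clustered through channel adjacency and temporal contiguity;
the cluster statistic is the summed t; and the null distribution is built
from 1000 random per-trial exchanges of the pre and post windows (sign
flips of the paired difference), with p = (1 + #{null ≥ observed}) / (1 +
1000). The candidate set is the 15-electrode central grid (FC3-FC4 through
CP3-CP4).

Selection rules (`selectElectrodes()`): non-patients use the fixed
consistently-significant set {FCz, FC1, FC2}; patients use the three
candidate electrodes with the smallest positive-cluster p-values whether or
not they reach significance, with ties broken by the larger mean
peri-stimulus potential and then label order (determinism on quantized
data). Only positive clusters are considered, because the selection targets
the P2, a positivity.

The montage is a schematic 2-D grid of the 64-channel 10-20 layout; channel
adjacency is "within 0.3 grid units", giving interior channels 8
neighbours. The grid exists to define neighbourhoods, not geometry - no
source modelling is done.

# ERP features

* **P2**: the largest *interior local maximum* of the trial- and
  channel-averaged onset ERP within 0.10-0.35 s (a sample strictly greater
  than both neighbours; plateaus take their first sample; windows without a
  local maximum fall back to the window maximum and are flagged). Published
  descriptions of this component place its window variously at 0.1-0.3,
  0.10-0.35 or 0.15-0.30 s; the selection stage and the measurement stage
  therefore have independent window settings, with defaults 0.1-0.3 s and
  0.10-0.35 s.
* **CPP AUC**: the trapezoidal integral of the change-locked parietal ERP
  (fixed set Pz, POz, P1, P2) over 0.2-1.0 s, in µV·s. The literal
  integral is the default because the method's reported group values carry
  µV·s units; a normalized mode (integral divided by the window length) is
  selectable and recorded in the output. Only the longest change-time
  condition (3 s) enters the change-locked analysis.
* **Fixed-window peaks**: plain window maxima in 0.2-0.3 s (onset) and
  0.6-0.8 s (change), used for the CRS-R correlation analyses.

# PCIa - the auditory perturbational complexity index

For each kept trial and each channel of a 14-channel cluster, the epoch is
reduced to a binary sequence: the amplitude envelope (magnitude of the FFT
analytic signal, computed over the whole epoch to avoid window-edge
artifacts) is restricted to the analysis window (default [-0.5, 1.5] s
around the lock; the narrower [-0.25, 1.25] s variant is a named preset),
resampled to 64 Hz, and thresholded at its own mean - strictly greater
becomes 1. The rows are concatenated (channels in montage order within each
trial, trials in chronological order) into one sequence S of length L, and

$$\mathrm{PCIa} = c(S) \cdot \frac{\log_2 L}{L \cdot H(S)},\qquad
H(S) = -p_1 \log_2 p_1 - (1-p_1)\log_2(1-p_1),$$

where \(c(S)\) is the exhaustive-history (LZ76, Kaspar-Schuster) word count
and \(p_1\) the empirical proportion of ones. Because a random string of
length L needs about \(L/\log_2 L\) words per bit of entropy, PCIa
calibrates to 1 on i.i.d. random strings for *any* \(p_1\) - the package's
acceptance suite verifies this at L = 10^5 for \(p_1\) from 0.2 to 0.8.
Stereotyped signals (periodic strings, slow high-amplitude EEG) score far
below 1. When H(S) = 0 the score is undefined and flagged rather than
forced to a number.

Numerical decisions:

* **LZ76, not LZ78**: the exhaustive-history parsing is the variant whose
  word count matches the \(L/\log_2 L\) normalization; the compiled scanner
  is verified exactly against an independent brute-force \(O(L^2)\) parser
  on all 2^16 strings of length 16 and on 1000 random strings up to length
  512.
* **Threshold ties**: "strictly greater than the mean" with a 1e-9 relative
  tolerance, so a constant-envelope input (e.g. a pure sinusoid) binarizes
  deterministically to all zeros despite floating-point ripple.
* **Envelope before windowing**: the Hilbert transform sees the whole
  epoch; the window is cut afterwards and then decimated 128 → 64 Hz
  (zero-phase), so the binarized row for the default window holds exactly
  128 samples.
* **Cluster membership**: the method prescribes 14-channel clusters around
  onset and change without enumerating them. The package defaults are the
  central candidate set minus Cz (onset; keeps left-right symmetry) and a
  centro-parietal analogue (CP row, P row, PO3/POz/PO4, Oz) for the
  change. Both are configurable everywhere and recorded in every score's
  provenance.

# Group statistics and classification

Omnibus comparisons use Kruskal-Wallis; pairwise post-hoc comparisons are
rank-based. Rank-sum tests "with Tukey HSD correction" is an internally inconsistent
recipe (Tukey HSD is a parametric mean procedure), yet it is what common
statistics toolboxes produce when a multiple-comparison routine is applied
to Kruskal-Wallis output; the package implements that behaviour - a
studentized-range test on mean ranks (the default) - with pairwise
rank-sum tests under Holm adjustment available as a cleaner alternative. Effect sizes are Cohen's d
from the pooled SD (first group minus second). Correlations with CRS-R are
Pearson by default (matching the reported figures) with Spearman selectable
(matching the methods text).

The classifier (`fitLda()`) is a two-class pooled-covariance linear
discriminant on standardized features; the pooled covariance can be shrunk
toward its diagonal, with the intensity chosen by nested leave-one-out on
the training fold (`shrinkage = "auto"`). The score is the equal-prior
posterior probability of the second class, thresholded at 0.5.
`loocvClassify()` evaluates by leave-one-out; `shuffledLabelControl()`
repeats the full evaluation under random label permutations, which must
land at the 50% base rate (it does, within the small pessimistic bias LOOCV
is known to have under permuted labels). The default feature set is
{P2 amplitude, PCIa(onset), PCIa(change)}; which ERP measures entered the
original model is ambiguous between "P2 only" and "P2 + CPP", so the
feature list is a config key with the former as default.

# The synthetic cohort generator

All testing runs on synthetic data; the generator (`synthesizeSubject()`,
`generateCohort()`) emulates exactly the statistical structure the analysis
consumes:

* **Trial structure**: change at 0.75/1.6/3 s, 2 s post-change sound,
  1-2 s uniform ISI; 320 stimuli for patients (80 per change time + 80
  sham, sham fixed at the 3 s length), 240 for passive/asleep controls (40
  per condition), 480 for active controls. Study-scale group sizes are
  12/12/15/12/12 (63 subjects).
* **Evoked components**: a Gaussian P2 (σ = 40 ms) at 0.2 s on
  fronto-central channels with per-trial amplitude Normal(mean, sd), and a
  CPP modelled as a half-Gaussian ramp rising to its peak 0.65 s after the
  change (σ_rise = 0.30 s) with a faster half-Gaussian decay (σ_fall =
  0.15 s) on parietal channels. Components are injected as
  *average-reference topographies*: zero spatial mean, scaled to unit mean
  weight over the component's measurement electrodes. This makes the
  nominal amplitude the quantity the pipeline measures - a broad
  all-positive topography would otherwise be attenuated ~40% by the
  common-average reference, and "a 2 µV P2" is meaningful only as the
  amplitude seen at FCz/FC1/FC2 under that reference.
* **Group contrasts** (defaults): P2 ≈ 2 µV in all non-patient groups,
  attenuated in patients (MCS 0.6, UWS 0.4 µV); CPP 2 µV in the Responding
  group, 1 µV in Passive (about half, matching the reported AUC ratio),
  absent elsewhere; broadband desynchronized background (1/f noise, 10-12
  µV) for the conscious groups vs high-amplitude slow activity for
  Asleep-NREM and UWS.
* **The "unconscious" background** is a small set (3) of independent
  0.5-4 Hz delta sources with zero-spatial-mean random loadings, scaled to
  40 µV per channel, plus attenuated broadband noise (4-5 µV). The zero-mean
  loadings matter: a spatially uniform slow wave would be removed by the
  common-average reference and the stereotypy would never reach the
  complexity measure. This construction demonstrably halves PCIa relative
  to the broadband mode.
* **Artifacts** are square-pulse excursions of ±(250-500) µV, 0.1 s long,
  on 1-4 random channels, Poisson-distributed per trial. They exist to
  exercise the ±200 µV rejection rule, not to model EMG. Default rates
  (Responding/Passive 0.05, Asleep 0.08, MCS 0.2, UWS 0.35 per trial) were
  chosen to produce realistic rejection fractions (controls ~5-10%, UWS
  ~30%); the counted artifact rates reported for real recordings include
  many sub-threshold events, whereas every simulated artifact exceeds the
  rejection threshold, so the counted rates are not used verbatim.
* **Determinism**: one RNG stream per subject, derived from the master
  seed, so any subject regenerates independently and a cohort is
  bit-identical under its manifest.

What the generator does *not* emulate - and hence what passing tests do not
show about real data: no acoustic texture synthesis, no head-model forward
projection (the montage is a schematic grid), no ocular or myogenic
artifact structure, no non-stationary sleep architecture, no realistic
inter-subject spectral variability. The generator demonstrates that the
pipeline recovers what it injects and separates what it is told to
separate; it cannot certify clinical performance.

# Problem sizes and runtime choices

The test suite and the acceptance script keep simulations at sizes chosen
to exercise every code path at useful statistical power: random-string
calibration at L = 10^5 with 20 replicates per probability; 200 null
subjects (15 channels, 20 trials, 256 Hz) for the family-wise error check;
20 control subjects (14 + 3 trials per condition, 512 Hz) for P2 recovery;
50 subject pairs for the complexity separation; a 24-subject patient cohort
for the LOOCV checks. Full study-scale cohorts (63 subjects, 1024 Hz, full
trial counts) run through exactly the same code via
`defaultCohortConfig()`.

# Known limitations

* The EDF writer/reader covers the subset of EDF the package emits
  (uniform rate, 16-bit, 1 s records) - it is not a general EDF library.
* Channel repair is inverse-distance averaging, not spline interpolation.
* The cluster permutation test assumes trial exchangeability within a
  subject; it is not a between-subject test.
* PCIa values depend on the chosen channel clusters and window; both are
  recorded in every score's provenance and should be held fixed within a
  study.
* The LOOCV shuffled-label control sits ~1-3 percentage points below 50%
  by construction (training-fold imbalance anticorrelates with the held-out
  label); this is a property of LOOCV, not a defect of the classifier.
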