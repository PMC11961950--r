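---
title: "Methods: synthetic EEG cohorts, stress classification, and frontal alpha asymmetry"
author: "stressEEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic EEG cohorts, stress classification, and frontal alpha asymmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

`stressEEG` implements a complete, testable analysis chain for EEG-based
driver-stress research: it synthesizes stress-labelled multi-channel EEG,
preprocesses it, extracts the five classical time/frequency features per
scalp region, trains and compares six stress-state classifiers (headlined
by a genetic-algorithm-initialized backpropagation network), and analyses
the Fp1−Fp2 alpha-power asymmetry index, its rank correlation with ordinal
stress level, and the effect of music interventions.

Stress is a five-level ordinal label: calm (1), almost-no-stress (2),
slight (3), moderate (4) and severe (5), mirroring a five-point Likert
scale. Recordings are 31-channel 10-10 montages sampled at 500 Hz, 30 s
per recording, with a cohort composition of 60/12/16/16/16 recordings per
state (120 in total), plus one post-intervention recording per subject at
level 3 or above, with four music types (joyful, sorrowful, exhilarating,
gentle) cycled within each state.

## The synthetic-data generator

No public recordings exist for this design, so the generator is a
first-class, tested module. Each channel is a sum of four band-limited
oscillations — delta (1–4 Hz), theta (4–8 Hz), alpha (8–13 Hz), beta
(13–30 Hz) — realized as sinusoids whose instantaneous frequency is slowly
modulated inside the band, plus Gaussian broadband noise and optional
blink transients. Default baseline band powers are 20/10/5/4 µV² for
delta/theta/alpha/beta.

Three deliberate structural choices:

* **Calibrated frontal asymmetry.** The Fp1 and Fp2 alpha amplitudes are
  set so that the *expected* alpha-power difference P(Fp1) − P(Fp2) equals
  the per-state target: 0.1340, −0.2367, −1.9866, −2.9117, −5.0518 µV²
  for calm through severe. The two frontal-pole channels share one alpha
  waveform (and their other-band waveforms), differing only in amplitude;
  homologous frontal sites are strongly correlated in real EEG, and the
  shared waveform makes estimation errors common-mode, so the small calm
  target (0.134 µV²) is recoverable from ten replicates.
* **Correlated background noise.** Total noise SD is 2 µV, of which 95 %
  of the variance is one scalp-wide background process and the rest
  independent sensor noise. This emulates the strong inter-electrode
  correlation of scalp recordings (without modelling volume conduction
  proper) and is what makes the common-average reference meaningful.
* **A frontal-pole-weighted state effect.** Stress modulates band power:
  alpha is suppressed by up to 30 % and beta enhanced by up to 200 % at
  full stress on the frontal-pole channels (Fp1/Fp2/AF3/AF4); other
  channels receive the same modulation at a quarter strength
  (`regionalEffect = 0.25`). A pure Fp1-up/Fp2-down amplitude swap leaves every
  region-averaged feature invariant — the asymmetry is invisible to the
  classifiers by construction — so without this modulation no model could
  recover the planted frontal-pole structure the region comparison is
  supposed to find. The graded weighting keeps the comparison
  non-degenerate while making Fp the most informative region.

Inter-individual variability is a single log-normal power factor per
*subject* (`subjectSd = 0.05`), derived from the subject id so that a
subject's baseline and post-intervention recordings share it — paired
pre/post comparisons then cancel it, as they would for a stable
anatomical trait. The factor is deliberately modest — real
between-subject amplitude variability is several-fold larger — so that
desk-scale cohorts remain separable; passing tests therefore demonstrate
correct recovery of planted structure, not expected performance on real
EEG.

Music interventions pull the recording's *stress intensity* s (a
continuous value in [1, 5]) toward calm: s′ = s − pull·(s − 1), with
default pulls gentle 0.80 > joyful 0.65 > exhilarating 0.35 ≈ sorrowful
0.30. Both the asymmetry target (linearly interpolated between the state
targets) and the band modulation follow s′, so an intervention moves the
whole feature profile, not just the asymmetry. The pull fractions are
configuration, not claims about music.

Blink artifacts are 300 ms, 100 µV half-sine transients applied jointly
to the four frontal channels at a configurable rate. The default rate is
0: the baseline cohort is artifact-free, and blink injection is the knob
used to exercise the rejection stage. Every recording derives its own
seed from the cohort's master seed, so cohorts are bit-reproducible and
individual recordings can be regenerated in isolation.

The generator writes CSV (one column per channel) plus a TSV manifest;
an EDF writer is a possible extension point but is not provided.

## Preprocessing

The chain is filter → re-reference → segment → artifact screening.

* **Filtering** is zero-phase with a Butterworth *magnitude* response
  (default order 8, 1–40 Hz), applied by multiplying each channel's
  spectrum. A recursive forward–backward implementation leaves edge
  transients that decay on the time-scale of the low corner (~1 s for a
  1 Hz edge) and can dominate a 30 s epoch; the frequency-domain form is
  exactly zero-phase, transient-free, and testable against its analytic
  response. The band edges are configuration (the analysis only assumes
  delta–beta coverage), and an optional notch handles mains interference
  (off by default for synthetic data).
* **Re-referencing** defaults to the common average; a named reference
  channel or `as_recorded` are available. Note that a common average over
  a *partial* montage (e.g. frontal channels only) subtracts the very
  frontal modulation of interest — for reduced montages use
  `as_recorded`.
* **Segmentation** cuts non-overlapping epochs (default 30 s, i.e. one
  epoch per default recording); a trailing partial epoch is discarded.
* **Artifact rejection** removes epochs whose peak-to-peak amplitude on
  any channel exceeds 150 µV. Independent-component analysis is a common
  alternative, but on 30 s epochs of synthetic data it is unstable and
  needs a component-selection rule; the threshold rule is deterministic
  and fully testable, and ICA remains an extension point. Rejecting every
  epoch raises an error rather than returning a silent empty set.

## Features

Per channel and epoch, five features: mean, population variance, skewness
k₃/k₂^{3/2} and excess kurtosis m₄/m₂² − 3 (population central moments
throughout; constant signals yield an `NA` sentinel rather than NaN), and
the mean Welch PSD over 1–40 Hz. Features are averaged over the channels
of each region and the epochs of each recording, yielding exactly one
5-vector per recording × region — the input contract of the 5-input
classifiers. The alpha band (8–13 Hz) is deliberately *not* a classifier
feature; it is reserved for the asymmetry analysis.

The Welch estimator splits the signal into segments of M samples (default
2 s), tapers each with a Hamming window (50 % overlap), normalizes each
periodogram by M·U with U the mean squared window value, and averages.
The PSD is scaled as a one-sided density so that its integral over
frequency approximates the signal's power; band power is a trapezoidal
integral. The five 10-10 regions are Fp {Fp1, Fp2, AF3, AF4}, F
(frontal + fronto-central, 9 channels), C (central, 5), P (parietal +
centro-parietal, 9) and O (occipital + parieto-occipital, 4).

## Classifiers

Six models are compared per region: the 5-5-5 backpropagation network
(BPNN), its GA-initialized variant (GA-BPNN), k-nearest neighbours
(k = 5), an RBF support-vector machine, Gaussian naive Bayes (with
degenerate within-class variances floored at the pooled feature SD), and
L2-regularized multinomial logistic regression. Features are z-scored on
training statistics only; zero-variance columns are left unscaled with a
warning.

The BPNN is fully connected 5-5-5 with sigmoid hidden units and a
softmax/cross-entropy output, trained by full-batch gradient descent for
36 iterations (learning rate 1.0). Because plain full-batch descent is
not loss-monotone, the returned model carries the weights with the lowest
training loss observed — this also guarantees that GA-initialized
refinement never ends worse than the individual it started from.

The GA evolves real-valued flat weight vectors (60 genes for 5-5-5):
tournament selection of size 3 with one elite, per-gene blend crossover
(BLX-0.25, probability 0.8), Gaussian mutation (per-gene probability 0.1,
SD 0.3), population 40 for 30 generations. Fitness defaults to the
negative training MSE of the decoded network (cheap, deterministic); an
internal-validation-accuracy fitness is available. The GA replaces the
single random initialization, guarding against poor local optima; the
tested property is that GA-initialized training matches or beats the
median of ten random starts at the same iteration budget.

Evaluation: stratified 70/30 holdout (class proportions preserved within
one sample; every class present in both sets) is the headline protocol,
with leave-one-out cross-validation available — the study design
mentions both without reconciling them, so neither is labelled the
canonical one. Accuracy is the overall fraction correct;
precision, recall and F1 are one-vs-rest per class and macro-averaged
(the scalar metrics of a 5-class task require *some* aggregation rule;
macro one-vs-rest is the convention adopted, and macro-averaging an
"accuracy" would not reduce to the overall fraction correct). All four
are recomputable from the stored confusion matrix, which testing
enforces exactly.

## Asymmetry and intervention scoring

The asymmetry index is the power-subtraction form AI = P(Fp1) − P(Fp2)
over 8–13 Hz, with power the squared-amplitude scale quantity estimated
by Welch + band integration. The per-state target values span −5.05 to
+0.13 on an additive scale, which is consistent with a raw difference and
not with a log-ratio; a log-ratio variant is available as an option.

Spearman's rho uses mid-ranks; in the tie-free case it is computed by the
classical rank-difference formula (exact, so perfectly inverse rankings
give −1.000 without rounding). For n ≤ 8 the two-tailed p-value is exact
by enumeration of all n! permutations; for larger n a t-approximation is
used. For five states and rho = −1 the exact two-tailed p is 2/5! ≈
0.0167 — reports of p < 0.001 for this configuration are not attainable
by a permutation argument, and the package reports the exact value.

Intervention scoring feeds post-intervention feature vectors into a
pre-trained classifier. For network models the predicted level is the
probability-weighted expected level (continuous in [1, 5]); argmax class
labels quantize a 48-recording design into steps of 1 and bury the
between-music differences in discretization noise. Percent reduction per
(music × state) cell is 100 × (mean pre − mean post predicted
level)/mean pre, so scoring an unchanged cohort gives exactly 0. The
feature extraction used for scoring must match the preprocessing the
classifier was trained with (the default applies the standard chain).

## Numerical and design notes

* The printed definitions of the third central moment and of the
  kurtosis denominator in the source material repeat a squared (resp.
  fourth-power) deviation; both are treated as typographical slips and
  implemented as the standard third central moment and m₄/m₂² − 3 —
  the only readings under which the skewness normalization k₂^{3/2}
  and the "− 3" excess convention make sense.
* One master seed derives every stage's sub-seed through a fixed modular
  map, so a pipeline run is bit-reproducible while stages draw from
  independent streams. No stage mutates global RNG state.
* Epoch duration per sample is not fixed by the study design (30 s relax
  vs ~200 s induction); 30 s is the default, configurable.
* Whether the classifiers consumed per-channel or region-averaged
  features is likewise unstated; region averaging is chosen because it is
  the only reading compatible with a 5-neuron input layer.

## Problem sizes and limitations

The shipped tests run the full default cohort (120 baseline recordings,
31 channels, 30 s at 500 Hz) for the planted-structure recovery, 20
replicates per state on a two-channel montage for asymmetry recovery, and
a four-channel frontal montage for intervention scoring; smoke tests use
2 recordings per state. These sizes were chosen so the whole suite
completes in a few minutes on one core while keeping every statistical
margin comfortable.

Known limitations: the generator has no 1/f spectral background, no
EOG/EMG channels, no volume-conduction model and no non-stationarity
beyond slow frequency jitter; between-subject variability is modest by
design; music-intervention cells contain only four recordings each, so
per-state music rankings under the *default* pull fractions are noisy —
the tested recovery property uses a full gentle pull, and rankings from
default runs should be read qualitatively. Classification accuracies on
synthetic cohorts are in the 0.5–0.65 range and are not comparable to
accuracies reported on real recordings.
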