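---
title: "Methods: a combined EEG/AEP index of unconsciousness under anesthesia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a combined EEG/AEP index of unconsciousness under anesthesia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

During general anesthesia the clinical reference for (un)consciousness is
behavioral: the patient squeezes the investigator's hand on request, or fails
to. A monitor must reduce the spontaneous EEG and the mid-latency auditory
evoked potential (AEP) to a single graded index that orders conscious above
(or below) unconscious states. `doaindex` implements the full construction
pipeline for such an index: signal-parameter extraction, automatic artifact
rejection, information-gain feature ranking, a harness over standard
classifier families, and evaluation by the prediction probability
$P_K$ — together with a synthetic cohort generator that emulates the
transition protocol so every stage is testable without patient data.

## The data model the pipeline assumes

Each patient contributes four transition events (two losses and two returns
of consciousness). Around every event, one "conscious" and one "unconscious"
data point are taken; the uncertain interval between the last successful and
the first failed hand-squeeze request (or vice versa) contributes nothing.
A data point consists of a 10 s EEG epoch sampled at 1 kHz (acquisition
band-pass 0.5-400 Hz) and a set of stimulus-locked AEP sweeps. Forty
patients thus yield at most 320 data points, eight per patient, balanced
between states.

## Signal parameters

**EEG (23 columns).** Seven measures, each computed after zero-phase
band-pass filtering at `f_high` $\in$ {30, 49, 90} Hz, plus two
band-restricted variants:

* *WSMF* — spectral median frequency: the smallest frequency at which the
  cumulative (optionally weighted) Welch power reaches 50%, linearly
  interpolated between bins. Uniform weights by default; the weighting
  vector is exposed because the exact weighting used historically is not
  recoverable.
* *qWSMF* — quotient of two WSMFs, by default beta band (8-30 Hz) over the
  full analysis band.
* *SEn* — Shannon entropy of the bin-normalized power spectrum, normalized
  by $\log(\text{bins})$.
* *HEx* — Hurst exponent from rescaled-range analysis over a dyadic window
  ladder (16 … n/4) with the Anis-Lloyd-Peters finite-sample correction;
  without the correction raw R/S is biased to ≈0.55-0.6 for i.i.d. input at
  these lengths.
* *ApEn* — Pincus approximate entropy, $m = 2$, $r = 0.2\,\mathrm{SD}$,
  Chebyshev distance, self-matches included. Inside the catalog it is
  computed on the epoch decimated 4× to 250 Hz: the band-pass (≤90 Hz)
  makes this alias-free, it keeps $m=2$ templates physiologically
  meaningful at the oversampled rate, and it bounds the $O(n^2)$ cost.
* *LZc* — Lempel-Ziv complexity: median binarization, exhaustive-history
  LZ76 parse, normalized $c(n)\log_2 n/n$.
* *PeEn* — permutation entropy, order 3, lag 1, ties broken by position,
  normalized by $\log 3!$.

The catalog (7 × 3 variants + beta-band WSMF + delta/alpha-band SEn = 23) is
data, not code: rows can be added or re-parameterized without touching the
measures.

**AEP (80 columns).** Sweeps are high-passed at 25 Hz (applied to the sweep
mean — filtering and averaging commute), averaged, and decomposed by a
periodized orthogonal Daubechies-4 DWT to depth 5 over the 0-128 ms
post-stimulus window (128 samples at 1 kHz, so levels D1…D5 and A5). Per
level: maximum absolute coefficient, its latency, level energy, maximum
amplitude of the single-level reconstruction ("retransformed" AEP), and the
variance of the second difference of the coefficient sequence (30
parameters); plus 50 raw coefficients from the mid-latency-relevant levels
(all of D3, D4, D5, A5 and the 18 D2 coefficients centered in ~20-92 ms).
Coefficient latencies are mapped to the center of the coefficient's support,
$2^j k + (2^j - 1)(L - 1)/2$ samples modulo the window — ignoring the filter
extent here mislocates mid-latency energy by tens of ms, which is why the
mapping carries the $(L-1)$ term. Which 80 parameters enter an AEP catalog
is not uniquely determined; this one is an explicit, documented default.

## Artifact rejection

Three rules, any of which excludes the whole data point: a run of ≥100
identical samples (flat line; the run length is a choice — none is stated in
the source conventions), any sample beyond ±250 µV (peak, not peak-to-peak;
configurable), and a peak-to-peak excursion above 140 µV within any sliding
1 s window (the stated 140 µV/s rate criterion needs a window convention;
the sliding-window form is robust to sampling jitter). Note the windowed
rule flags a 100 µV-amplitude sine — a 200 µV swing within a second — which
is intended.

## Feature selection and classifiers

Features are ranked by information gain over a single threshold split,
candidates at midpoints between consecutive distinct sorted values (the C4.5
convention), entropy base 2, stable tie-breaking. Ranking is recomputed
inside every cross-validation training fold by default; the final holdout
evaluation ranks once on the working set.

The classifier harness standardizes features by training-fold statistics
(required for SVM comparability) and exposes ten families: SVMs with
linear/polynomial (degree 3)/RBF/sigmoid kernels via libSVM (`e1071`), cost
on the grid {0.01, 0.1, 1, 10, 100} with only the best-performing C
reported, kernel γ fixed at 1/n features; Gaussian naive Bayes; a
kernel-density naive Bayes (per-class, per-feature Gaussian-kernel
densities); logistic regression; a single-hidden-layer perceptron of size
(features+2)/2 with fixed seed; a CART decision tree standing in for the
C4.5 family with pinned settings (minsplit 10, cp 0.01); and a discrete
Bayes classifier with class-parent structure over supervised-threshold
binarized features and Laplace smoothing (a pinned, simple Bayes-net
structure — not claimed equivalent to any historical default). The graded
indicator fed to $P_K$ is the SVM decision value or the class probability,
oriented so higher = more unconscious; hard labels would collapse $P_K$
into ties.

## Evaluation

$P_K$ counts all cross-state pairs: concordant if the indicator orders the
pair as the states, discordant if opposite, tied if equal;
$P_K = (C + T/2)/(C + D + T)$. For binary states this equals the ROC area
with ties counted half, which the tests exploit as an independent oracle.
Polarity ("unconscious high") is a convention only — negating the indicator
maps $P_K \mapsto 1 - P_K$.

Cross-validation is leave-one-patient-out: all data of one patient form the
test fold, ranking and training see only the others, and per-patient $P_K$
values are summarized by unweighted mean and sample SD (n−1). For the final
evaluation a seeded patient-level split holds patients back; the pooled
holdout $P_K$ gets a percentile bootstrap CI from 2000 patient-level
resamples (patients, not points, are the exchangeable unit).

## The synthetic cohort generator

No generative model of anesthetic EEG is prescribed by the protocol, so the
generator makes the minimal choices that give every feature its clinically
documented direction:

* **EEG**: a state-weighted mixture of two unit-RMS filtered-noise regimes —
  slow (delta/theta-dominant, $1/(1+(f/4)^2)$ above 0.3 Hz) and fast (a
  broad 15-90 Hz bump centered at 40 Hz). The fast weight is
  $w = \mathrm{logit}^{-1}(\text{offset} \pm \text{eeg\_effect}/2)$
  (+ when conscious), total amplitude ~10-14 µV RMS with unconscious slow
  waves slightly larger. An optional `gamma_band_effect` adds a purely
  30-90 Hz component (full when conscious, 30% when unconscious) for
  experiments about the low-pass setting, where the discriminative
  information must genuinely sit above 30 Hz.
* **AEP**: two Gabor-like mid-latency deflections (positive near 30 ms,
  negative near 45 ms; Pa/Nb analogues) of ~1 µV against 20 µV RMS
  background per sweep — the classic regime where the response only emerges
  from averaging hundreds of sweeps. Unconscious: amplitude ×(1−0.4),
  latency +10 ms.
* **Variability**: per-patient Gaussian offsets (SD 0.5) on the mixture
  logit and log AEP amplitude plus a per-patient latency jitter; per-epoch
  jitter (SD 0.6 on the logit, scaled down for AEP amplitude and latency)
  representing within-state fluctuation of arousal — without it repeated
  epochs of one state would be statistically identical and any classifier
  would be trivially perfect.
* **Reproducibility**: the master seed expands to per-patient substreams,
  so any patient subset regenerates identically.
* **Artifacts**: an `artifact_rate` fraction of epochs receives exactly one
  of the three detector-triggering corruption classes, with a hidden truth
  flag for detector-completeness tests.

Defaults (40 patients, 4 events, 10 s/1 kHz epochs, 512 sweeps, eeg_effect
1.5, attenuation 0.4, delay 10 ms) were fixed once as the emulated study
conditions; with them the pipeline reproduces the qualitative ordering of
the original setting — combined index above either single modality,
EEG-only and AEP-only in the high-0.8s/low-0.9s, single best parameters
around 0.9.

**What the generator does not emulate**: nonstationarity and burst
suppression, drug-specific spectral signatures, realistic artifact
morphology beyond the three rule-triggering classes, electrode/montage
physics, or variable-length AEP segments (the window is fixed at 0-128 ms
for deterministic testability). Passing tests therefore demonstrate the
pipeline's correctness and directional behavior, not clinical performance.

## Numerical and design choices

* Zero-phase filtering (2nd-order Butterworth high-pass at 0.5 Hz cascaded
  with a 4th-order low-pass at `f_high`, each forward-backward) so entropy
  and latency features see no phase distortion; stop-band behavior is
  test-asserted, not assumed.
* Welch PSD: Hann window, 1024-sample segments, 50% overlap, one-sided
  density scaled so `sum(power)·df` matches the variance (Parseval
  checked in tests).
* WSMF interpolation treats each bin's mass as accruing linearly over the
  preceding inter-bin interval; with a discrete two-line spectrum the
  median therefore falls at the 50% crossing, not necessarily on a line.
* The wavelet transform is periodized, so all level energies sum exactly to
  the waveform energy; "depth too large" and non-dyadic lengths are errors.
* Degenerate inputs error loudly (zero-power spectra, zero-variance Hurst,
  single-class $P_K$) rather than returning sentinel values; all-zero
  wavelet levels report latency as `NA`, never 0.
* Ties: ranking tie-breaks are stable (original column order);
  `best_over_C` resolves ties toward the lowest C; ordinal-pattern ties
  break by position.
* Per-patient $P_K$ uses within-patient cross-state pairs; pooled $P_K$
  (holdout) uses all cross-state pairs of the test set. Whether the
  historical patient-wise SD used n or n−1 is unknown; n−1 is used.
* Sizes used in the shipped analyses and tests (12 patients in
  `analysis/`, 5-10 patients and 16-512 sweeps in the test suite) are the
  package's own choices balancing Monte-Carlo stability against runtime;
  effect sizes and noise levels always stay at the study-condition
  defaults, only cohort dimensions shrink.

## Known limitations

Coefficient latencies are quantized to the level stride (8 ms at D3, 16 ms
at D4), so a 10 ms delay is at the edge of per-patient resolvability; the
latency-recovery test uses a one-stride (16 ms) configured delay and a
cohort-level sign test. The 23- and 80-parameter catalogs are documented
reconstructions, not a recovered historical parameter list. The discrete
Bayes classifier is a deliberately simple structure. Real-data mode expects
the documented delimited text layout; EDF input is out of scope here.
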