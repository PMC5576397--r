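---
title: "Methods: EMD-domain features for EEG emotion recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EMD-domain features for EEG emotion recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, conventions and numerical choices behind
`emdeeg`, in the spirit of the methods sections of the mature Bioconductor
analysis packages: what is computed, under which assumptions, which knobs
matter, and what the synthetic validation does and does not demonstrate.

## The pipeline

Affective state (binary high/low valence and arousal, from 1-9
self-assessment ratings split at 5) is predicted from short EEG epochs.
Each 5-second, 128 Hz epoch of each channel is decomposed by empirical mode
decomposition (EMD) into intrinsic mode functions (IMFs), ordered fastest
oscillation first. Three scalar features summarise each IMF:

* `Dt` — the mean absolute first difference of the IMF's samples, the
  intensity of change in the time domain (a signed mean would telescope to
  nearly zero, so magnitudes are summed);
* `Dp` — the mean absolute first difference of the IMF's *unwrapped*
  analytic (Hilbert) phase, in radians per sample; for a band-limited mode
  this is an instantaneous-frequency summary;
* `logEnorm` — the natural log of the IMF's energy divided by the raw
  epoch's energy, the relative weight of that oscillation component.

The feature vectors across channels and IMF levels feed a C-classification
SVM with RBF kernel at the classical LIBSVM defaults (cost 1, kernel width
`1/n_features`), evaluated subject-by-subject with leave-one-trial-out
cross-validation: all segments of one trial are held out per fold, so
within-trial correlation can never leak between training and test sets.
Electrode importance is scored by the two-class Fisher distance
\((\mu_1-\mu_2)^2/(\sigma_1^2+\sigma_2^2)\) per channel and feature.

## Sifting: conventions where the procedure is under-determined

The sifting loop subtracts the mean of the cubic-spline envelopes through
the maxima and minima until the candidate satisfies the two IMF
admissibility conditions (extrema and zero-crossing counts differing by at
most one; envelope mean everywhere zero). Several details are conventions
that any implementation must fix:

* **Stop rule.** The strict two-condition test can cycle indefinitely in
  floating point. Sifting of one mode therefore stops at the first of:
  the two-condition test passing with envelope-mean tolerance
  `zero_mean_tol = 0.05` (relative to the candidate's peak amplitude); the
  Cauchy-type ratio `SD = sum(m^2)/sum(h^2)` dropping to `0.2` (Huang's
  classical value); or 100 sifting iterations.
* **Boundary handling.** Spline envelopes over-swing at the epoch ends.
  The two extrema nearest each end are mirrored across the first/last
  sample before fitting (the `mirror_extrema` mode) — the standard remedy.
  End distortion is reduced, not removed; quantitative tests therefore use
  the interior 80% of samples.
* **Plateaus.** A run of tied samples that is locally extremal contributes
  exactly one extremum at the floor of its midpoint index. Deterministic,
  and consistent with common implementations.
* **Zero crossings.** Counted as sign changes with exact zeros skipped,
  so ties cannot produce platform-dependent counts.
* **Termination.** Decomposition stops when the remainder has fewer than
  three extrema (it can no longer oscillate — this also covers monotone
  remainders) or when `max_imfs` (default 5) modes have been extracted;
  downstream feature extraction never uses deeper levels, and more would be
  wasted work.

Reconstruction `sum(imfs) + residual == input` holds to floating-point
rounding by construction, because every mode is subtracted from the running
remainder.

## Phase: why unwrapping is not optional

The analytic signal is built with the FFT method over the whole epoch at
once (no windowing; edge distortion accepted as above). The raw
four-quadrant angle lives on \((-\pi, \pi]\); first differences across the
branch cut would be spurious \(\approx 2\pi\) jumps, destroying the
instantaneous-frequency interpretation of `Dp`. The phase is therefore
unwrapped cumulatively before differencing. For a pure 8 Hz tone at 128 Hz
the interior phase increment is \(\pi/8\) radians per sample, which the
test suite recovers to well under 5%.

An identically-zero mode has undefined phase and raises a degenerate-signal
error; levels that a decomposition did not reach are filled with the
sentinel triple `(0, 0, log(1e-12))`, deterministic and conspicuous in any
downstream table.

## Classifier protocol

Features are z-scored inside each cross-validation fold using training-fold
statistics only (constant features keep unit scale); the held-out trial
contributes nothing to the scaler or the fit, and `loto_evaluate(...,
keep_fold_fits = TRUE)` exposes the per-fold scaler and SVM parameters so
this is directly assertable. Per-subject accuracy is the mean over folds;
multi-subject summaries average per-subject accuracies and additionally
pool confusion matrices for an F1 of the high class,
`2TP/(2TP + FP + FN)`. Whether to z-score and which SVM constants to use
are not dictated by the protocol being reproduced; the choices here (fold-wise
z-scoring; LIBSVM defaults) are pinned in code and in `ClassifierConfig`-style
arguments so alternatives are explicit. Paired two-sided t-tests compare
configurations across subjects — paired, because the same subjects underlie
both conditions; identical inputs report `p = 1`, and a constant nonzero
difference (zero variance) is an error rather than a fabricated p-value.

Subjects whose ratings produce a single class in a dimension cannot be
cross-validated in that dimension and are excluded from its averages, with
a message.

## Fisher-distance channel ranking

Scores use unbiased sample variances; a summed within-class variance below
`1e-12` (e.g. a constant feature) is capped at `1e-12` with a warning, so
rankings stay total instead of producing infinities. With several subjects,
channels are ranked within subject and ordered by mean rank across subjects
(the paper-workflow shape of "important electrodes across all subjects");
the 8-electrode preset Fp1, Fp2, F7, F8, T7, T8, P7, P8 ships as
`channels_preset8()`. How the three features' scores should combine into
one electrode ranking is genuinely open; `feature = "all"` sums them, and
single-feature rankings are available alongside.

## Comparison baselines

* **Box-counting fractal dimension** of the epoch's graph, normalised to
  the unit square, dyadic box sizes `2^-1 … 2^-6` (no scales are dictated;
  one decade of dyadic scales is the usual desk choice), least-squares slope
  of `log N(s)` vs `log(1/s)`. A constant epoch is a flat line, dimension 1.
* **Sample entropy** with `m = 2`, `r = 0.2 sd`, Chebyshev distance,
  Richman–Moorman counting (templates `1..N-m` for both lengths,
  self-matches excluded). A 640-sample segment is split into five
  non-overlapping 128-sample windows whose finite values are averaged —
  the window length is part of the protocol, the averaging rule is this
  package's recorded choice.
* **db4 wavelet differential entropy.** No wavelet package ships with the
  environments this package targets, so the single-level db4 analysis bank
  (periodised convolution, dyadic downsampling; verified energy-preserving)
  is implemented here. At 128 Hz, detail level 1 spans 32–64 Hz (Gamma) and
  level 2 spans 16–32 Hz (Beta); bands are addressed by level, so input
  low-passed at 45 Hz simply yields a band-limited Gamma detail. The
  differential-entropy estimator is the Gaussian closed form
  \(\tfrac12\log(2\pi e \sigma^2)\) on the band's detail coefficients — the
  standard choice in the EEG differential-entropy literature, recorded here
  as an interpretation since no estimator is dictated.

## The synthetic generator: what it emulates, and what it does not

`synthetic_spec()` defaults encode the geometry of the preprocessed DEAP
recordings: 40 trials × 60 s × 32 channels at 128 Hz, band 4–45 Hz, ratings
in [1, 9]. Background activity is 1/f-shaped band-limited noise synthesised
in the frequency domain. Class structure follows the premise that affective
information concentrates in the higher EEG bands: on the informative
channels, high-class trials receive an additional flat-spectrum 16–45 Hz
component whose variance is `separation` times the background's 16–45 Hz
band power, making the programmed high/low band-power ratio exactly
`1 + separation`. Ratings are generated class-first (high: uniform [5, 9);
low: uniform [1, 5)) so binarised labels recover the generating class
unambiguously — the reverse of how ratings arise in a real experiment, but
necessary for ground truth. The default `separation = 3` is far above the
classifier's transition region and yields essentially error-free
classification on informative channels — a positive control, not a
realistic effect size.

What the generator does **not** emulate: non-stationarity, artifacts,
volume conduction and inter-channel correlation, 1/f exponents varying by
band, oscillatory bursts, or any physiologically realistic forward model.
Passing the synthetic recovery suite therefore demonstrates that the
pipeline's machinery is correct and leakage-free — not that the headline
accuracies on real recordings are reproduced. The real-data accuracies
require the licensed DEAP download and are out of scope here.

A property worth knowing when designing synthetic experiments with this
generator: because the class signal is *added* power, the raw-segment
energy differs between classes, and `logEnorm` (whose denominator is the
raw segment) carries some class information at *every* IMF level. The
first level still dominates by a wide margin, which is what the IMF1-vs-IMF3
comparison below exploits.

## Problem sizes and thresholds used in the validation suite

Sizes were chosen once, as the smallest designs whose statistics are stable:

* **Chance behaviour** is asserted at the full 40-trial × 60 s geometry
  (480 segments), where the mean accuracy over 5 seeded zero-separation
  subjects must lie in [40, 60]%. Leave-one-trial-out has a known
  small-sample pathology at chance: holding out a trial makes its class the
  training minority, biasing the classifier against it, so accuracy sits
  *below* 50% (we observe ≈ 45% at 480 segments, and far lower at 64
  segments). The band is asserted on the mean across seeds; single runs
  fluctuate by several points.
* **Separation sweep**: 6 levels at 0, 0.025, 0.05, 0.1, 0.2, 0.4 × 5
  seeds × 40 trials × 20 s. The levels sample the generator's transition
  region — above ≈ 0.4 accuracy saturates at 100% and a monotonicity
  statistic over tied values is uninformative. Spearman ρ of per-level mean
  accuracy against separation must exceed 0.9.
* **IMF1 vs IMF3**: separation 0.5, 10 seeds; moderate separation keeps
  IMF1 near but not at its ceiling while IMF3 (fed only by the energy-ratio
  leak described above) stays well below, so the sign test over seeds is
  strict. One-sided binomial p < 0.05.
* **Channel-selection recovery**: 8 channels with classes planted on
  channels 2 and 7, 16 trials × 20 s; Fisher ranking must place the planted
  pair in the top 2, and the maximum score under 100 trial-level label
  permutations must fall below the observed maximum in ≥ 95% of
  permutations.

## Known limitations

* EMD end effects are mitigated, not eliminated; features computed on very
  short epochs (a few oscillation cycles) inherit boundary bias.
* The sifting stop tolerances are conventions; published EMD variants
  (ensemble EMD, multivariate EMD) are out of scope.
* `Dp` assumes the mode is narrow-band enough for its analytic phase to be
  meaningful; for broadband residual-like components the value is a summary
  statistic without a frequency interpretation.
* The DEAP reader operates on the documented in-memory array layout and on
  this package's delimited container; parsing the binary MATLAB/pickle
  distribution files is intentionally left to the caller's tooling.
* Sample entropy returns a flagged `Inf` when no extended template matches
  exist; windowed averaging drops such windows, which slightly biases the
  estimate low on extremely regular signals.
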