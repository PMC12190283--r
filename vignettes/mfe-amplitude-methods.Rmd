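---
title: "Amplitude transformations and multiscale fuzzy entropy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amplitude transformations and multiscale fuzzy entropy: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfeeg)
```

This vignette documents the science implemented by `mfeeg`: the entropy
model and its assumptions, the parameters that matter, what the synthetic
cohort generator does and does not emulate, and the numerical and design
decisions taken where conventions in the literature are ambiguous.

## 1. The measurement model

### Fuzzy entropy

For a series $x_1,\dots,x_N$ and embedding dimension $m$, form the $N-m$
template vectors of length $m$ and of length $m+1$ starting at each
$i = 1,\dots,N-m$, each centred on its own mean. With the Chebyshev
distance $d_{ij}$ between two centred templates, the pairwise similarity is
the exponential fuzzy membership

$$\mu(d) = \exp\!\left(-\,d^{\,n}/r\right),$$

and $\varphi^m$ is the mean over $i$ of the mean over $j \ne i$ of
$\mu(d_{ij})$. Fuzzy entropy is
$\mathrm{FuzzEn}(m, n, r) = \ln\varphi^m - \ln\varphi^{m+1}$, in nats. It
estimates the conditional surprise of extending a matched pattern by one
sample: high values mean irregular, unpredictable dynamics.

### Multiscale extension

The series is coarse-grained at scale $\tau$ by replacing non-overlapping
blocks of $\tau$ samples with their mean, and the entropy is recomputed at
each $\tau = 1,\dots,20$. At 200 Hz with 3 s epochs, scale 20 probes a
10 Hz effective sampling of the slow dynamics. The classification feature
is the mean MFE over scales 17–20, per channel — long scales are where the
clinical contrast is expressed, and the averaging reduces 380 entropy
values to 19 features per observation, limiting overfitting.

### Why amplitude matters at all

Two membership conventions circulate. With
$\mu = \exp(-(d/r)^n)$, $d$ and $r$ scale together under $x \mapsto cx$
when $r \propto \mathrm{SD}(x)$, and univariate entropy is exactly
amplitude-invariant — every amplitude condition would give identical
features, and the pipeline's question would be vacuous. With
$\mu = \exp(-d^{\,n}/r)$ and $n = 2$, the exponent scales by $c$, so gain
differences move the entropy. Only the second form is consistent with the
premise that instrumentation gain biases the biomarker; `mfeeg` uses it as
the default and keeps the invariant form available
(`mfe_params(membership = "exp_d_over_r_n")`), whose invariance is asserted
in the test suite. Shift invariance holds exactly under both forms because
templates are mean-centred and the SD ignores location.

### Tolerance convention

The tolerance is $r = 0.2 \times \mathrm{SD}$ of "the time series". Two
readings exist: SD of the original (scale-1) epoch, reused at all scales
(the classic multiscale-entropy convention), or SD recomputed per
coarse-grained series. The package defaults to the former
(`r_convention = "fixed_from_scale1"`, per epoch and channel): with a fixed
yardstick, the loss of variance under coarse-graining is part of the signal
being measured, which is what makes long-scale MFE sensitive to slow
dynamics. The per-scale convention is available and both are pinned by
regression fixtures on seeded white noise (where entropy decays
monotonically with scale under the per-scale convention).

## 2. Pipeline parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| band | 0.5–45 | Hz | clinically informative EEG band |
| FIR order | 3 × fs | samples | causal; first 3 s dropped as transient |
| epoch length | 3 | s | non-overlapping; 16 epochs from 51 s |
| resampler fc, df | 0.9, 0.2 | fraction of output Nyquist | Kaiser anti-aliasing design |
| m, n | 2, 2 | — | embedding dimension, fuzziness exponent |
| r | 0.2 × SD | amplitude | per epoch, per channel, scale-1 SD |
| scales | 1–20 | — | feature band 17–20 |
| A_min, A_max | −5, +5 | amplitude | min-max output range; symmetric, SD of order 1 |
| coverage factor k | 2 | — | expanded uncertainty of mean accuracy |

Filtering is causal (with the transient discarded) rather than zero-phase:
the entropy statistics are invariant to the pure delay, and dropping the
transient matches the epoch bookkeeping (51 s → 48 s → 16 epochs). The FIR
band-pass is a Hamming windowed-sinc built as the difference of two
unit-DC-gain lowpasses, so DC is rejected exactly; the design window is a
package choice, as only the order and band edges are fixed by convention.

The resampler reduces the rate ratio to an integer fraction $p/q$ by
continued fractions (denominator ≤ 1000 for non-rational ratios),
zero-stuffs by $p$, applies a Kaiser-window lowpass with cutoff
$0.9\,f_{\mathrm{Nyq}}$ and transition width $0.2\,f_{\mathrm{Nyq}}$ of the
lower of the two rates (ripple 0.002), compensates the group delay, and
decimates by $q$.

Amplitude transforms are fitted per subject on the whole post-filter,
pre-epoching recording. The "sliding" 3 s windows for the min-max extremes
are non-overlapping (stride = window length, configurable): no stride is
prescribed by convention, and this matches the epoching convention.
Normalized values are **not** clipped to $[-5, 5]$ — the map must stay
affine for inter-channel correlations to be preserved exactly, which the
statistics module verifies. Standardization uses the sample ($n-1$) SD
(configurable); the difference from the population SD is a factor
$\sqrt{(n-1)/n}$, irrelevant at $n \approx 10^4$ samples.

## 3. Classification and evaluation

Each subject's 16 epochs are treated as independent observations (the
subject-level dependence is respected by the splits, never by the
classifier). Subjects are split into train/test sets stratified by group
and acquisition dataset with equal group counts; at study scale the test
set is 9+9 subjects from site A and 6+6 from site B. Model selection is
leave-one-subject-out: for each hyperparameter combination, all of one
subject's observations form the validation fold, and per-feature z-scoring
is refitted on the remaining subjects only, so no moments leak from the
held-out subject. Selection maximizes observation-level validation accuracy
(subject-level averaging is available); ties break to the earliest
combination in declared grid order, making the search deterministic.

The final model is retrained on the full training set and evaluated once on
the held-out subjects: per-subject accuracy, mean accuracy with expanded
uncertainty $k\,\sigma/\sqrt{K}$ ($k = 2$, $K$ test subjects — the standard
error scaling required for a 95 % interpretation), and MCC pooled over all
test observations. MCC of an empty marginal is defined as 0.

Backends: SVM via `e1071` (RBF kernel, cost/γ), random forest via `ranger`
(`n_estimators → num.trees`, `max_depth → max.depth`,
`min_samples_split → min.node.size`, `min_samples_leaf → min.bucket`,
seeded), and a small built-in weighted-KNN (uniform/distance weights;
Euclidean, Manhattan, or Minkowski with the conventional power 2), verified
against a naive re-evaluation loop in the tests. `grid_default()` carries
the full published search space; `grid_reduced()` is the sub-grid used for
simulation studies, where the search itself is not the object of interest.

## 4. Statistical layer

* **t-test grids.** Welch (unequal-variance) two-tailed tests per
  (scale, channel) cell on per-subject MFE values (each subject's epochs
  averaged first, to avoid pseudo-replication), with Benjamini–Hochberg
  adjustment across the full 20 × 19 grid and the mask taken at adjusted
  p < 0.05. Cells with zero variance in both groups are flagged, not
  tested. The Welch variant is a robustness choice; grids at the
  exchangeable null are calibrated at the nominal level in the tests.
* **Effect sizes.** Cohen's d with the pooled ($n-1$-weighted) SD.
* **Mixed ANOVA.** Channel-averaged per-subject values, within factor
  scale (20 levels), between factors group and dataset; type-III sums of
  squares with sum-to-zero contrasts and Greenhouse–Geisser correction of
  within-factor p-values. With fewer subjects than within levels the
  sphericity estimate does not exist; the table then reports uncorrected
  within p-values and says so (`gg_applied`).
* **Condition comparisons.** Paired one-tailed t-tests of per-subject
  accuracies (condition > reference) on the shared split. Zero-variance
  difference vectors are reported as degenerate with p ∈ {0, 0.5, 1} by
  the sign of the mean.

## 5. The synthetic cohort generator

`synth_config()` encodes the structure the analysis assumes, not EEG
physics:

* **Group dynamics.** HS channels are a fast AR(1) (φ = 0.88) plus white
  sensor noise. AD channels add a slow AR(1) component (φ = 0.95, SD twice
  the fast process) — the synthetic analogue of AD "EEG slowing" (excess
  low-frequency power). The mixture is rescaled to the same marginal SD as
  the HS process, so the groups differ in *temporal structure only*; this
  matters, because a slow component that also inflated amplitude would
  couple the group label to the very confound the transforms remove. The
  slow component's correlation time (~20 samples) is comparable to the
  long-scale coarse-graining window, so it survives averaging as
  *irregular* low-frequency variance and raises long-scale entropy; a
  near-random-walk component (φ → 1) would instead make the coarse series
  smooth and predictable and *lower* it.
* **Gains.** Each signal is multiplied by
  site gain (defaults 1.0 and 3.0) × subject gain
  (log-normal, σ = 0.5) × channel gain (default flat), all assigned
  independently of the group label: amplitude is a pure confound. Site
  membership follows the 35:17 per-group split of a two-source cohort.
* **Cross-channel structure.** A shared component (mixing weight 0.4)
  gives non-trivial inter-channel correlations for the
  correlation-preservation analysis.
* **Determinism.** Every subject draws from an RNG stream derived from
  (seed, subject index), so cohorts are reproducible and extensible.

With these defaults, a 40-per-group cohort shows the intended regime:
reference-condition LOSO accuracy near chance (the classifier latches onto
gain), global-norm accuracy near 74 %, Cohen's d > 0.5 for long-scale MFE,
and a significant paired improvement. The calibration targets the
generator's stated contract — direction and effect size of the long-scale
separation — and was frozen before the acceptance checks were written.

What the generator does **not** emulate: spectral peaks (alpha rhythm),
non-stationarity, artifacts (ocular, muscular), electrode-distance-
dependent correlation structure, volume conduction, or any physiological
gradient across channels. Consequently, green tests demonstrate the
*method's* behaviour under controlled assumptions — confound removal,
calibration, bookkeeping — not clinical performance on real EEG. Absolute
accuracies on real cohorts depend on effect sizes this generator only
imitates.

## 6. Numerical notes, degenerate inputs, problem sizes

* The C++ entropy kernel accumulates in extended precision and skips
  membership terms with exponent beyond 45 (each < 3·10⁻²⁰); it matches an
  independent plain-R double-loop oracle to 10⁻¹⁰ across 50 seeded series,
  and is non-negative up to −10⁻¹² on all tested inputs.
* Constant series (zero SD) raise a degenerate-tolerance error at scale 1;
  a zero-SD coarse series under the per-scale convention yields `NaN` for
  that scale with a warning. Similarity-sum underflow yields `NaN` with a
  warning rather than −∞.
* Constant recordings raise degenerate-amplitude errors in both transform
  fits; features containing `NaN` are flagged and dropped (with a message)
  before classification.
* EDF output is 16-bit with per-channel physical ranges written back from
  their 8-character header representation, so a write/read round trip is
  exact to one quantization step of the channel range.
* Test problem sizes are chosen so the full suite runs in about two
  minutes on one core: bookkeeping at the full 104-subject scale (features
  only at the 17–20 band), the confound-removal study at 40 subjects per
  group with the reduced random-forest grid, null calibration at 20 per
  group, oracle comparisons at series lengths ≤ 200.

## 7. Known limitations

* ICA-based artifact rejection is intentionally out of scope (it requires
  a trained component classifier); the pipeline exposes an
  `artifact_hook` so such a stage can be plugged in.
* The mixed ANOVA reports the standard univariate repeated-measures table;
  multivariate alternatives are not provided.
* The KNN backend is exact but O(n²) in observations — adequate at
  cohort scales here, not for very large epoch counts.
* Classification operates on epoch-level observations, as the protocol
  prescribes; subject-level aggregation (e.g. majority vote) would change
  the reported accuracy definition and is deliberately not applied.
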