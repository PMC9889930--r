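---
title: "EEG-based depression recognition: features, pipeline, and clinical scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG-based depression recognition: features, pipeline, and clinical scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegdr)
```

`eegdr` implements a complete desk-scale workflow for recognizing depression
from resting-state EEG, together with the clinical instruments that usually
accompany such studies: HAMD-24 and TAS-20 scoring with severity banding, an
anxious-depression subtype gate, and classification of cortisol/ACTH
circadian-rhythm disturbance from three-timepoint hormone profiles. Because
clinical EEG cohorts of depressed patients are essentially never public, the
package ships seeded synthetic-data generators that emulate each input type,
and every claim the test suite makes is a property of the methods evaluated
on those generators.

## Per-epoch EEG features

Recordings are cut into fixed-length epochs (default 4 s, no overlap; at
250 Hz that is 1000 samples, enough for stable scaling-exponent estimates)
and each epoch yields seven features per channel.

**Linear moments.** `feat_max`, `feat_variance` (unbiased, denominator
$n-1$), excess kurtosis and skewness. Kurtosis is computed as

$$\mathrm{kurt}(x) = \frac{1}{n-1}\sum_{i=1}^n \frac{(x_i-\bar x)^4}{SD^4} - 3,$$

with $SD^2$ the $1/(n-1)$ sample variance. This hybrid estimator (a
$1/(n-1)$ fourth moment over the squared sample variance) is neither the
population-moment form nor the unbiased $G_2$ statistic; it is kept
deliberately because it is the form the feature set is defined with, and for
Gaussian series it still converges to 0. Skewness uses population moment
denominators, $m_3/m_2^{3/2}$, with the standard sign convention (positive =
heavier right tail). A sometimes-seen verbal gloss that negative skew means
"less data left of the mean" conflicts with this convention; we implement the
standard convention and note the conflict rather than resolve it.

**Detrended fluctuation analysis.** The mean-centered series is integrated,
split at each box size $n$ into $\lfloor N/n \rfloor$ non-overlapping boxes,
each box linearly detrended (DFA-1), and

$$F(n) = \sqrt{\tfrac{1}{\#\text{covered}}\sum (\text{residual})^2}$$

is regressed on $n$ in natural log–log coordinates; the slope is $\alpha$.
Verbal descriptions of this procedure sometimes omit the squaring inside the
residual sum; the root-mean-square form is required for $F(n)$ to be a
fluctuation magnitude and is what we implement. Box sizes default to ~12
log-spaced integers from 4 to $N/4$, so the largest size still leaves four
boxes; sizes leaving fewer than two boxes are dropped with a warning.
Theory anchors the estimator: $\alpha \approx 0.5$ for white noise,
$\approx 1.0$ for $1/f$ (pink) noise, $\approx 1.5$ for Brownian motion,
and the test suite checks all three orderings plus exact (1e-10) agreement
with an independent literal-equation reference implementation.

**Higuchi fractal dimension.** For lag $k \le k_{max}$ (default 10) and
offset $m \in 1..k$,

$$L_m(k) = \Big[\sum_i |S(m+ik)-S(m+(i-1)k)|\Big]\cdot
  \frac{N-1}{\lfloor (N-m)/k\rfloor\, k}\cdot \frac{1}{k},$$

$L(k)$ averages over $m$, and the dimension is $-$slope of $\ln L(k)$ on
$\ln k$. Printed versions of this normalization are frequently garbled; the
form above is the standard Higuchi construction. For a 1-D series the true
dimension lies in $[1, 2]$; the estimator can stray slightly outside on
finite noise samples, so `higuchi_fd` reports both the raw slope
(`dimension_raw`, used for oracle-equivalence testing) and a clipped
`dimension` with a flag.

**Spectral entropy.** Entropy-rate derivations motivate using the power
spectrum as an entropy carrier; operationally we compute the Shannon entropy
of the normalized Welch PSD estimate: Hann taper, segments of
$\min(N, 256)$ samples, 50% overlap, per-segment mean removal, DC bin
dropped, normalized by $\ln(\#\text{bins})$ into $[0,1]$. The per-segment
mean removal makes the estimate invariant under constant offsets (otherwise
taper leakage smears a DC shift into low-frequency bins), and the
normalization makes it invariant under amplitude scaling. A flat spectrum
scores near 1 (white noise > 0.95 in practice), a pure tone near 0.

Whether features should be aggregated per subject or fed per epoch is a
genuinely open design point; we default to the per-subject mean over epochs
(`aggregate_features`) because it matches one-row-per-subject clinical
labels, and keep the per-epoch long table (`features_table`) available.

## The recognition pipeline

`cross_validate` runs repeated stratified k-fold cross-validation (defaults
5 folds, 10 repeats). Inside each training fold, and only there, the
pipeline applies, in this fixed order:

1. **SMOTE** minority oversampling to class balance (k = 5 neighbors,
   uniform interpolation coefficient). Oversampling precedes normalization
   so synthetic rows are formed in the original feature space, and precedes
   selection so selection sees balanced classes.
2. **z-score normalization**, parameters estimated on the (balanced)
   training rows only; constant features are dropped with a warning.
3. **Feature selection**, one of four routes: `all` (no selection), `l1`
   (lasso-penalized logistic regression, non-zero coefficients kept), `tree`
   (random-forest impurity importances normalized to sum to 1, kept above
   the mean/median/absolute threshold, ties broken by canonical column
   order), `fdr` (per-feature Welch t-tests, Benjamini–Hochberg adjustment
   at level 0.05).
4. **Classifier fit.** The classifier family is configurable; the default is
   an L2-regularized (ridge) logistic model with probability output, which
   keeps the selection-route comparison interpretable; a probability random
   forest is available as `type = "tree"`.

The held-out fold is scored untouched, and accuracy, recall and precision
(positive class = depressed/A-MDD) are reported both pooled over all folds
and per repeat — both, because either convention is defensible and they can
differ at small n. The no-leakage contract is tested mechanically: mutating
the rows of a test fold leaves that fold's fitted normalizer and selected
feature set bit-identical. Fold assignment depends only on the labels and
the seed, so the whole report is reproducible from (matrix, config, seed).

Degenerate corners are defined rather than left to chance: an empty
selection falls back to a training-prior classifier; a single selected
feature uses an unregularized logistic fit (ridge paths need two columns);
SMOTE on balanced classes is the identity.

## Clinical instruments

**HAMD-24.** Totals band as: > 35 severe, 20–35 definite, 8–19 possible,
< 8 normal. Published band descriptions overlap at 20 and at 8; we resolve
both boundaries upward (20 is "definite", 8 is "possible"), consistent with
the ≥ 21 inclusion convention for definite depression, and the cut-points
are configuration, not code. The item→factor map of the 24-item version is
not part of the instrument's printed definition; we ship the standard
Chinese 7-factor structure (anxiety/somatization = items 10, 11, 12, 13, 15,
17, etc.) as an editable, externally sourced default, including per-item
ranges (0–4 for most items, 0–2 for the insomnia/somatic/weight/insight/
diurnal/obsessional items). The subtype gate classifies
anxiety/somatization ≥ 7 as A-MDD and ≤ 2 as NA-MDD, with 3–6 indeterminate
(excluded by design in subtype studies).

**TAS-20.** Items score 1–5; items 4, 5, 10, 18, 19 reverse
($v \mapsto 6-v$); the DIF/DDF/EOT factors partition the 20 items exactly
(asserted at configuration load). Bands: ≤ 51 non-alexithymia, 52–60
moderate, ≥ 61 severe; the moderate band is sometimes misprinted
("52 ≤ 51") and is resolved to 52–60, the unique reading that makes the
bands exhaustive and mutually exclusive.

**Circadian rhythm disturbance.** A profile (c8, c16, c24) is disturbed
when a later draw fails to fall below 50% of an earlier one:
c16 ≥ 0.5·c8, c24 ≥ 0.5·c16, or c24 ≥ 0.5·c8, inclusive at the boundary.
The published wording of this rule is typographically corrupted; this
reading is the one consistent with normal cortisol roughly halving over the
day, and both the threshold and the rule subset are arguments, not
constants. Note the pooled rule "c24 vs c8" can never be the sole violation
(two healthy declines of < 50% each imply c24 < 0.25·c8), which is why the
synthetic generator plants disturbances through the two adjacent-interval
rules. Whether such rules should be applied per analyte or pooled across
ACTH and cortisol is not decidable from published descriptions; we evaluate
per analyte and report each. The diurnal cortisol slope defaults to the
two-point definition (c8 − c24)/16 h (the denominator is our choice of the
08:00→24:00 span), with a three-point regression alternative that agrees
exactly for time-collinear profiles.

## Synthetic data: what it emulates, what it does not

All generators are pure functions of their arguments including the seed.

- `gen_white_noise` / `gen_colored_noise`: i.i.d. Gaussian and
  FFT-spectrally-shaped $1/f^\beta$ noise (Hermitian-symmetric shaping, DC
  removed, exact target slope in $O(n\log n)$); $\beta = 0$ returns the
  white noise bit-for-bit. These are the oracle signals for the scaling
  features.
- `gen_eeg_cohort`: two groups on a unit-SD pink-noise background; the
  depressed group receives an additive band-limited (default 8–13 Hz
  alpha-band) component on the first half of the channels. Defaults — 30
  subjects per group, 16 channels, 250 Hz, 60 s, effect amplitude 1.0 SD
  with per-subject gain jitter (N(1, 0.2), truncated at 0.2) — are the
  package's stated "strong effect" study conditions; recording geometry
  defaults stand in for acquisition parameters that EEG depression studies
  frequently leave unstated. The acceptance suite requires pooled CV
  accuracy ≥ 0.75 under exactly these conditions, the qualitative regime of
  the ~80% accuracies reported for real cohorts of comparable size — not a
  reproduction of any particular cohort's number.
- `gen_scale_cohort`: subject totals drawn from a truncated normal (defaults
  31.81 ± 5.39 vs 25.25 ± 5.02, n = 21/21, the canonical A-MDD vs NA-MDD
  HAMD contrast), then item vectors constructed to sum to the drawn total
  exactly by uniformly distributing points over items with headroom.
- `gen_hormone_cohort`: profiles built by direct construction — c8
  log-normal around a physiological baseline (cortisol ~450 nmol/L, ACTH
  ~40 pg/mL), later draws as fractions of earlier ones on the appropriate
  side of the 50% thresholds — so exactly `round(n · fraction)` profiles are
  disturbed, re-verified against the classifier at generation time. The
  incidence round-trip (72%/51% at n = 100/group) is therefore exact.

None of this is physiologically realistic EEG or endocrinology: there are no
artifacts, eye blinks, montage geometry, non-stationarity, medication
effects, or pulsatile hormone secretion. Passing tests demonstrate that the
feature estimators, the pipeline's statistical hygiene, and the scoring
rules behave as specified — they say nothing about classification accuracy
on real patients.

## Numerical choices and problem sizes

Natural logarithms are used in all log–log fits. Feature extraction is
vectorized (per-box detrending as one residual-operator matrix product;
Higuchi via strided `diff`s) and is verified to 1e-10 against literal-loop
references. The test and acceptance suites use: 50 × n = 4096 white-noise
series for the DFA constant; 100 × n = 10⁴ series for the kurtosis
constant; 20 random series (n ≤ 2048) for oracle equivalence; 200 label
permutations × 100 noise features for FDR type-I control; and the full
default EEG cohort (60 subjects × 16 channels × 60 s) for effect recovery —
sizes chosen to make each stochastic check stable at two digits while
keeping a full run in the minutes range on one core.

## Known limitations

- The EDF writer/reader covers the plain-EDF single-record case the package
  itself produces; EDF+ annotations, discontinuous records and multi-rate
  signals are out of scope.
- SMOTE interpolates in the raw assembled feature space with Euclidean
  distances; features on wildly different scales will bias neighbor choice
  (the pipeline always normalizes *after* oversampling by design, so this
  matters only for extreme scale ratios).
- The FDR route tests marginal mean differences only; interactions or
  variance differences between groups are invisible to it.
- Scale-response generation targets the *total*-score distribution; item
  covariance structure (and hence factor-score distributions) is not
  calibrated to real psychometric data.
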