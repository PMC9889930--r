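# eegdr

Depression recognition from resting-state EEG, with the clinical scoring
that accompanies it. `eegdr` is an R toolkit for studies that combine
machine-learning classification of multichannel EEG with psychometric
scales (HAMD-24, TAS-20) and circadian hormone profiling (cortisol/ACTH).
Because clinical EEG cohorts of depressed patients are rarely public, the
package also ships seeded synthetic-data generators for every input type,
so the entire workflow is testable end to end without patient data.

## What it computes

**Seven per-epoch EEG features**, per channel:

- maximum and sample variance;
- excess kurtosis, $\frac{1}{n-1}\sum_i (x_i-\bar x)^4 / SD^4 - 3$, and
  skewness $m_3/m_2^{3/2}$;
- the **DFA** scaling exponent $\alpha$: integrate the mean-centered
  series, detrend linearly in non-overlapping boxes of size $n$, and fit
  $\log F(n)$ on $\log n$, where $F(n)$ is the RMS residual
  ($\alpha \approx 0.5$ white noise, $1.0$ pink, $1.5$ Brownian);
- the **Higuchi fractal dimension** ($-$slope of $\ln L(k)$ vs $\ln k$ for
  the normalized curve lengths $L(k)$; 1 = smooth, 2 = noise-like);
- normalized **spectral entropy** of the Welch PSD (Hann taper, 50%
  overlap, DC dropped), in $[0, 1]$.

**A leakage-safe recognition pipeline**: subject-level feature matrices,
SMOTE minority oversampling, z-score normalization, four feature-selection
routes (all features / L1-penalized logistic / tree-ensemble importance /
FDR-corrected Welch tests), a ridge-logistic or random-forest classifier,
and repeated stratified cross-validation reporting accuracy, recall and
precision — with oversampling, normalization and selection re-fitted inside
every training fold.

**Clinical scoring**: HAMD-24 totals, 7-factor scores and severity bands
(> 35 severe, 20–35 definite, 8–19 possible, < 8 normal); the
anxious-depression gate on the anxiety/somatization factor (≥ 7 A-MDD,
≤ 2 NA-MDD); TAS-20 with reverse-scored items 4, 5, 10, 18, 19, DIF/DDF/EOT
factors and alexithymia bands; and circadian-rhythm-disturbance
classification of (08:00, 16:00, 24:00) hormone profiles by 50%-decline
rules, with diurnal slope and cohort incidence/chi-square summaries.

## Worked example

```r
library(eegdr)

# a small synthetic two-group cohort: 10 + 10 subjects, 4 channels,
# 20 s at 250 Hz, alpha-band (8-13 Hz) power effect in the depressed group
spec <- cohort_spec(n_per_group = 10, n_channels = 4, duration = 20, seed = 42)
coh  <- gen_eeg_cohort(spec)
epochs <- unlist(lapply(coh$recordings, epoch_signal), recursive = FALSE)
fm <- assemble_matrix(aggregate_features(features_table(epochs)), coh$labels)
fm
#> Feature matrix: 20 subjects x 28 features (control: 10, depressed: 10; positive = depressed)

cross_validate(fm, selection_method = "tree", folds = 5, repeats = 10, seed = 1)
#> 10 x 5-fold stratified CV (selection: tree, positive class: depressed)
#>   pooled:  accuracy 1.000, recall 1.000, precision 1.000
#>   repeats: accuracy 1.000, recall 1.000, precision 1.000 (means)

dfa(gen_white_noise(4096, seed = 1))
#> DFA: alpha = 0.4957 over 12 box sizes [4..1024], R^2 = 0.9947

score_tas(rep(3, 20))
#> TAS-20: total 60 (moderate_alexithymia); factors: DIF=21, DDF=15, EOT=24

h <- rbind(gen_hormone_cohort(100, 0.72, seed = 1, group = "A-MDD"),
           gen_hormone_cohort(100, 0.51, seed = 2, group = "NA-MDD"))
cohort_incidence(h)$incidence
#>   analyte  group   n n_disturbed incidence
#> 1     COR  A-MDD 100          72        72
#> 2     COR NA-MDD 100          51        51
```

The injected band-power effect shifts variance and spectral entropy on the
affected channels, so the tree-selection route separates the groups
perfectly at this effect size; the DFA exponent of simulated white noise
sits at its theoretical 0.5; an all-"partially agree" TAS-20 response
scores 60 (the reverse-scored items also map to 3); and the hormone
generator round-trips its requested 72% / 51% disturbance incidences
exactly, by construction.

A command-line front end over the same functions is installed at
`inst/cli/dr.R` (`simulate`, `extract`, `crossval`, `compare-selection`,
`train`, `predict`); run it with `Rscript` and `--help`-style header
documentation in the file.

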