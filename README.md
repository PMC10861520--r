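# actiRA

Digital biomarkers of rheumatoid arthritis (RA) from wrist-worn sensor data
and patient-reported outcomes (PROs).

## The problem

RA symptoms — morning stiffness, disturbed sleep, reduced mobility and
dexterity — fluctuate day to day and are poorly captured by sporadic clinic
visits. Remote monitoring studies instead collect two streams between
visits: *passive* data (continuous wrist actigraphy from a smartwatch) and
*active* data (short guided smartphone tests: wrist range of motion, a 30-s
walk, a digital 9-hole peg test, sit-to-stand and lie-to-stand transitions),
alongside validated PRO questionnaires (HAQ-DI, RASIQ, FACIT, PROMIS) and
the in-clinic RAPID-3 composite severity score.

`actiRA` is a complete, tested pipeline for this setting, aimed at
biostatisticians and digital-health methodologists. Because raw study data
of this kind is rarely deposited, the package ships a first-class synthetic
study generator whose group effects default to the baseline summary table
of a 14-day RA remote-monitoring study (30 healthy controls, 13 moderate
and 15 severe RA participants), so every downstream stage is reproducible
and testable from nothing but a seed.

## What it implements

* **Synthetic cohort** — `effect_config()`, `generate_cohort()`,
  `simulate_activity_days()`, `synthesize_raw_stream()`,
  `simulate_guided_tests()`: per-group PRO distributions (truncated
  normals clipped to instrument ranges), semi-Markov activity sequences
  over {sleep, sedentary, light, MVPA}, a sample-level tri-axial
  accelerometer model, and guided-test recordings with group-dependent
  wrist ROM, cadence, peg pace and transition duration.
* **Activity recognition with HMM smoothing** — `window_stream()`,
  `extract_window_features()`, `fit_window_classifier()` (a transparent
  multinomial-logistic stand-in for a deep network), `estimate_hmm()` and
  `viterbi_decode()`. Per-epoch class posteriors are decoded as scaled
  likelihoods `p_t(c)/pi(c)` under a smoothed bigram transition model; the
  Viterbi path is exactly optimal (verified against exhaustive search).
* **Passive features** — `detect_sleep_periods()` (noon-to-noon nights,
  30-min gap merging), total volume of daytime activity (TVDA), morning
  movement attenuation (MORN), night-time restlessness (NTR), activity
  fragmentation (AF).
* **Active features** — `extract_wrt_features()`, `extract_wlk_features()`,
  `extract_peg_features()`, `extract_transition_features()`.
* **Statistics** — Mann-Whitney U (exact for small untied samples),
  Kruskal-Wallis, Brown-Forsythe, Benjamini-Hochberg FDR,
  Pearson/Spearman correlation with clinical strength categories, and
  ICC(3,k) test-retest reliability with `icc_vs_days()` curves.
* **Penalised modelling** — `penfit()`, a single fitting function for
  lasso / ridge / elastic-net / sparse-group-lasso logistic and linear
  models solved by monotone FISTA, minimising

  ```
  (1/n) loss(b0, b) + lambda [ alpha ||b||_1 + (1-alpha) sum_g sqrt(p_g) ||b_g||_2 ]
  ```

  (elastic net replaces the group term with `(1-alpha)/2 ||b||_2^2`), with
  `print`, `summary`, `coef` and `predict` methods, the exact composed prox
  (`prox_sparse_group()`), and `kkt_residual()` for optimality audits.
  Feature domains (TVDA, MORN, ..., PRO, DEM) are the sparse-group lasso's
  groups.
* **Evaluation protocol** — `run_cv()`: stratified subject-wise k-fold
  cross-validation, train-fold-only imputation and standardisation,
  inner-CV penalty selection, majority-vote subject aggregation, AUROC /
  Cohen's kappa / macro-F1 and r² / MAE / RMSE.
* **Experiments** — `run_ra_identification()`,
  `run_severity_stratification()`, `run_rapid3_regression()`,
  `run_days_subsampling()` (performance vs number of monitoring days).

## Worked example

```r
library(actiRA)

cfg   <- effect_config(seed = 7)
study <- simulate_study(cfg, n_hc = 30, n_ra_mod = 13, n_ra_sev = 15,
                        n_days = 14)

run_ra_identification(study, seed = 7)
#> Experiment: ra_identification (config 00a727be )
#>   active               F1 = 0.983 kappa = 0.965 AUROC = 1.000
#>   passive              F1 = 1.000 kappa = 1.000 AUROC = 1.000
#>   combined             F1 = 1.000 kappa = 1.000 AUROC = 1.000

run_rapid3_regression(study, seed = 7)
#> Experiment: rapid3_regression (config 00a727be )
#>   r2 = 0.857 MAE = 0.698 RMSE = 0.923 rho = 0.874 (HC median |pred| = 0.37)
```

Reading: with the default group effects, subject-wise cross-validated
classification separates RA from healthy controls essentially perfectly
(the synthetic effect sizes follow a study population whose PRO and
activity differences are large), the combined sensor sources are at least
as good as either alone, and the regression recovers the 0-10 RAPID-3
severity score to within ~0.7 points MAE with healthy-control predictions
concentrated near their assigned zero.

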