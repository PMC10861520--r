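---
title: "Models and methods behind actiRA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind actiRA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(actiRA)
```

`actiRA` estimates rheumatoid arthritis (RA) status and severity from
wrist-worn sensor data and patient-reported outcomes (PROs). This vignette
is the package's account of its models, the assumptions behind them, the
parameters that matter, and the places where the design was genuinely open.

## 1. The synthetic study generator

Raw data from remote-monitoring RA studies is rarely deposited, so the
generator is a first-class, tested component, not a fixture. Its defaults
encode the study conditions the analysis assumes: a cohort of 30 healthy
controls (HC), 13 moderate-RA and 15 severe-RA participants monitored for
14 days.

**PROs.** Each instrument is drawn from a per-group truncated normal
clipped to the instrument's range (HAQ-DI 0-3, RASIQ scales 0-100, FACIT
0-52, PROMIS T-scores 20-80, RAPID-3 0-10). Published baseline tables
report only mean ± sd per group, and a truncated normal is the simplest
distribution consistent with that information. HC degenerate values
(HAQ-DI and RAPID-3 exactly 0 ± 0) are reproduced literally: healthy
controls are *assigned* a RAPID-3 of zero rather than measured. A note on
scales: source tables of this kind sometimes footnote RAPID-3 severity
cut-offs on the 0-30 raw scale while reporting group means on the 0-10
scale; the generator treats 0-10 as canonical throughout, and severity
group labels are generated directly rather than re-thresholded from the
score, sidestepping the inconsistency.

**Activity.** Each participant-day is a semi-Markov chain over the broad
taxonomy {sleep, sedentary, light, MVPA} at 30-s epochs. One main sleep
block per night starts near 23:00 (sd 0.5 h) and is allowed to span
midnight; daytime epochs are filled with geometric dwell times (means 10,
3 and 2 minutes for sedentary, light and MVPA — memoryless, matching the
downstream first-order HMM). Whole-day class fractions default to
HC 0.33/0.45/0.17/0.05, RA-mod 0.34/0.50/0.13/0.03 and RA-sev
0.35/0.53/0.10/0.02, encoding the lower MVPA observed in RA. Each
participant carries latent multipliers (lognormal, ~15% cv) on the
light/MVPA weights so that repeated days from one person are correlated —
without this between-subject layer, test-retest reliability (ICC) would be
meaningless.

**Symptom effects.** Three RA signatures are injected: (i) movement in the
first 30 min after wake is multiplied by a *morning factor* (HC 1.0,
RA-mod 0.7, RA-sev 0.5); (ii) *night-time movement episodes* arrive as a
Poisson process during sleep (0.5, 1.2, 2.0 per hour) with geometric
length (mean 1 min) and a 0.1 g magnitude bump; (iii) guided tests carry
group means for wrist ROM (140/110/90°), step cadence (1.9/1.7/1.5 Hz),
peg inter-event time (1.5/2.2/3.0 s) and postural transition duration
(1.5/2.2/3.0 s), each with between-subject and day-to-day noise.

**Two magnitude routes.** `synthesize_raw_stream()` builds the tri-axial
signal sample by sample: a slowly rotating gravity unit vector plus a
zero-mean dynamic component whose sd orders sleep < sedentary < light <
MVPA (0.005/0.01/0.05/0.15 g). `epoch_magnitudes()` draws the per-epoch
mean movement directly from the same class levels with a multiplicative
~10% between-epoch variation — because an epoch mean over ~900 samples
concentrates tightly around its class level, per-epoch dispersion is
dominated by behavioural variation, not sample noise. Full-cohort
experiments use the epoch route (58 participants x 14 days of 30 Hz raw
signal would be ~2 x 10^9 samples for no statistical benefit); the raw
route is exercised end-to-end at small scale in the tests, where a
classifier trained on windowed features decodes a day of signal back to
its true labels.

**What the generator does not emulate.** Real actigraphy has non-wear,
device artefacts, heteroscedastic noise, circadian drift and label noise;
classes are far less separable than Gaussian class-conditional features
make them. Passing pipeline tests therefore demonstrate correctness of the
machinery and the direction/order of group effects, not real-world effect
sizes — cross-validated F1 near 1.0 on synthetic data says nothing about
F1 on a real cohort.

## 2. Activity recognition and HMM smoothing

Per-epoch classification treats epochs independently, so the decoded
activity sequence is temporally incoherent. `actiRA` restores coherence
with a hidden Markov model decoded by Viterbi.

The window classifier is deliberately transparent — summary features
(magnitude moments and percentiles, per-axis means, zero-crossing rate,
band power 0.5-3 and 3-8 Hz) into a multinomial logistic model — and the
HMM layer is agnostic to the posterior source, so a deep network could be
plugged in unchanged.

Emission handling was an open decision: the decoder defaults to *scaled
likelihoods* `p_t(c) / pi(c)`, the correct generative emission term when
the classifier's posteriors absorb non-uniform class priors; raw-posterior
mode is available (`emission = "raw"`) for comparability. Transitions are
smoothed bigram counts, `A[i,j] = (n_ij + c)/(n_i. + Kc)`; the prior `pi`
uses marginal class frequencies rather than sequence-initial states (a
study contributes few sequences but hundreds of thousands of epochs).
Numerics: log space, probabilities floored at 1e-12, back-pointer ties
broken toward the lower class index so decoding is deterministic.

Two properties anchor this module: the decoded path exactly attains the
exhaustive-search maximum on small instances, and on day-length sticky
sequences (self-transition 0.95, correct-class posterior 0.6) Viterbi
beats independent argmax in essentially every replicate, raising per-epoch
accuracy by roughly 0.28.

## 3. Feature extraction

**Sleep.** Nights run noon-to-noon so the main sleep block is never split
at midnight. Sleep runs separated by gaps ≤ 30 min merge (brief
awakenings should not split main sleep; configurable), and the longest
merged run is the night's main sleep; its offset is the wake-up time.

**Passive features.** TVDA: class fractions (a partition summing to 1),
MVPA minutes, mean and 95th-percentile daytime movement. MORN: mean
movement in [wake, wake+30 min) over mean movement in [wake+30, wake+90),
null when fewer than 90 min of data follow the wake. NTR: movement
episodes are maximal runs above a threshold; no published threshold
exists, so the default is the night mean plus three standard deviations of
the *quiet reference* (the below-median half of the night's epochs),
configurable. AF: epochs dichotomised to active (light+MVPA) vs rest;
the active-to-rest transition probability is transitions divided by active
epochs. Missing days yield null features that are excluded from
aggregation denominators — never imputed as zero at this stage.

**Active features.** Wrist ROM integrates angular velocity (trapezoidal)
and removes a linear trend anchored at the first and last samples; an
ordinary least-squares line would absorb part of the oscillation itself
(regressing a sinusoid on time leaves a sloped residual) and inflate the
peak-to-peak range by ~10%, whereas the endpoint line removes a constant
gyro bias exactly and reproduces the closed-form 90° example within 2°.
Walking: band-pass 0.5-3 Hz, peaks above 0.3 x sd with ≥ 0.25 s
separation (scale-invariant by construction), cadence in steps/min,
regularity as the autocorrelation at the dominant period. Peg test: last
minus first event and inter-event moments. Postural transitions: the
vertical axis is the axis with the largest low-passed plateau change; the
duration is the 10-90% crossing interval of the low-passed vertical
component divided by 0.8, so a linear ramp of duration d reads back as d —
without the rescaling the 10-90% rule systematically reports 80% of the
true ramp time. An instantaneous step reads as the low-pass response time
(~0.3 s at 2 Hz cutoff), the method's resolution floor.

## 4. Univariate statistics and reliability

Group comparisons are two-sided throughout (the underlying claims are
directionless differences in medians). Mann-Whitney U uses midranks, exact
enumeration for combined n ≤ 12 without ties and the tie-corrected normal
approximation otherwise. Kruskal-Wallis mirrors that split: exact
permutation p for combined n ≤ 8 untied (the assignment space is
enumerable), chi-squared (df = g-1) otherwise. Brown-Forsythe is the
one-way F on absolute deviations from group medians, with the degenerate
zero-within-variance case resolved by its limit (F = 0/0 -> no evidence;
F -> infinity -> p = 0). Benjamini-Hochberg adjusted p-values come from
`p.adjust`; rejection at level alpha is `adjusted <= alpha`, equivalent to
the linear step-up rule. Correlation strength categories on |r|:
good-to-excellent > 0.75, moderate-to-good 0.50-0.75, fair 0.25-0.49,
otherwise none.

ICC(3,k) is the two-way consistency average-measures coefficient,
`(MS_subjects - MS_error)/MS_subjects`, with study days as raters;
negative estimates are reported as computed but categorised poor
(< 0.5; moderate to 0.75, good to 0.9, excellent above). It satisfies the
Spearman-Brown identity with the single-measure ICC(3,1) to 1e-10, which
the tests assert algebraically. `icc_vs_days()` uses the first d
*contiguous* days (the alternative — random day subsets — belongs to the
day-subsampling experiment, which is explicitly about non-contiguous
days), complete-case per feature on the day grid.

## 5. Penalised models and evaluation

`penfit()` minimises `(1/n) loss + penalty` with the unpenalised
intercept, where loss is half squared error or the mean logistic negative
log-likelihood (the factor-2 alternative of using the full deviance only
rescales lambda, and the mean-NLL convention makes unregularised fits
match `glm` exactly). Penalties: elastic net
`lambda(alpha ||b||_1 + (1-alpha)/2 ||b||_2^2)` and sparse-group lasso
`lambda(alpha ||b||_1 + (1-alpha) sum_g sqrt(p_g) ||b_g||_2)` with feature
domains as groups and the standard sqrt-group-size weights; demographics
form their own group. The solver is proximal gradient with FISTA
acceleration, restarted whenever momentum would increase the objective
(so the reported objective path is non-increasing); the step is
1/L with L from a power iteration on X'X/n (quartered for logistic). The
sparse-group prox is the exact composition: elementwise soft-threshold,
then per-group Euclidean shrinkage. Convergence: relative objective
change below 1e-8 (default) or 10^4 iterations, with non-convergence a
warning rather than an error; `kkt_residual()` verifies stationarity and
the dual-norm conditions for zero groups to 1e-6 at tight tolerances.
`lambda_max` for the sparse-group penalty has no closed form and is found
by per-group bisection on the deactivation condition.

**Evaluation protocol.** Cross-validation is *subject-wise*: participants,
never observations, are partitioned (stratified round-robin, per-fold
class counts within one of proportional), so no participant contributes to
both sides of a fold. Median imputation and standardisation are computed
on training folds only — a property the tests assert by poisoning held-out
rows and checking the training statistics are bit-identical. Lambda is
chosen by an inner 3-fold subject-wise CV over 20 log-spaced points from
lambda_max down three decades; the minimum-error rule is the default, with
the one-standard-error rule available where support recovery matters more
than raw prediction error. Observation-level predictions are aggregated
per participant by majority vote, ties broken toward the class with the
higher mean positive score (deterministic and score-consistent); both the
subject-wise metrics (after voting) and pooled observation-wise metrics
are emitted, since either convention is defensible. Classification
reports AUROC (rank form, ties half-counted), Cohen's kappa and macro-F1;
regression reports r², MAE, RMSE.

**A known limitation: CV penalties over-select.** On the designed
support-recovery problem (10 groups x 5 features, 2 active groups with 3
of 5 nonzero coefficients — within-group sparsity being precisely the
structure the penalty assumes — n = 200, signal-to-noise variance ratio
5), the sparse-group lasso at the inner-CV penalty *always* retains the
true groups but keeps a tail of spurious ones: with the 1-SE rule the
median false-group count is ~1, yet 15-25% of replicates keep three or
more. This is the well-known behaviour of prediction-optimal penalties,
which are systematically smaller than support-recovery-optimal ones;
achieving near-perfect group screening would require a different selector
(stability selection, BIC-type criteria) that the package deliberately
does not bolt on. `sg_recovery_experiment()` measures and reports the
rate honestly.

## 6. Experiments and problem sizes

The four experiments mirror the analysis questions: RA vs HC
identification per sensor source and combined; moderate vs severe
stratification with PRO-only vs PRO+sensor designs; RAPID-3 regression
(HC fixed at zero, so healthy predictions should concentrate near 0); and
data-volume sufficiency, where for each d a uniform random subset of d
distinct days per participant ("non-contiguous" meaning gaps are allowed,
not that adjacency is forbidden) is averaged and the CV repeated, folds
re-drawn per permutation from derived seeds. The days experiment uses a
fixed penalty (lambda = 0.05) so its hundreds of refits measure data
volume, not selector noise.

Default problem sizes are chosen to be desk-scale while keeping every
statistical claim testable: the full cohort (58 participants, 14 days)
for the pipeline experiments, 100 permutations per d for the
day-subsampling curve, 200 replicates for the HMM-benefit and
episode-rate simulations, 50 for support recovery. Every report embeds
the configuration hash and seed, and identical seeds give bit-identical
outputs end to end — per-participant and per-operation random streams are
derived from the master seed by integer mixing, so regeneration is
order-independent.

## 7. Interfaces

Functions are the interface. `simulate_study()` returns the cohort, the
long PRO table and the tidy daily feature table
(`participant_id, day_index, feature, domain, value`); `write_study()`
exports them as CSV plus a JSON manifest (seed, config hash).
`build_design()` assembles feature matrices per source set
(PRO / active / passive; demographics always included since age and BMI
are legitimately informative covariates), and the `run_*` experiment
functions orchestrate the rest. The acceptance script
(`scripts/acceptance.R`) regenerates everything from a single seed and
writes the headline numbers as JSON.
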