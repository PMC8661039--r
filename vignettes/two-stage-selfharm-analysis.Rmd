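---
title: "Two-stage subgroup discovery and risk-factor selection for adolescent self-harm cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage subgroup discovery and risk-factor selection for adolescent self-harm cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twopath)
```

## The analysis this package implements

`twopath` packages a two-stage analysis of self-harm in a longitudinal birth
cohort with sweeps at ages 5, 7, 11 and 14:

1. **Subgroup discovery.** Among adolescents who report past-year self-harm
   at age 14, z-scored profile measures — the five caregiver-rated SDQ
   subdomain scores (emotional symptoms, conduct problems,
   hyperactivity/inattention, peer problems, prosocial behaviour; each
   0–10) and the self-report MFQ depression total (0–26) — are fed to a
   self-organizing map (SOM). k-means is then run on the learned node
   weights, each participant inherits the cluster of their best matching
   unit (BMU), and the partition is validated with the mean silhouette
   coefficient.

2. **Risk-factor discovery.** For each subgroup versus a non-self-harm
   comparison sample, and for each sweep's 75–97 candidate predictors
   (grouped into six domains: child health, child mental health, caregiver
   mental health, home environment, peer relations, adversity), the
   procedure is: exclude participants missing more than 30% of the sweep's
   predictors; impute the rest by k-nearest-neighbour imputation (k = 25);
   split 70/30 stratified by outcome; run 1,000 bootstrap iterations of
   L1-penalised (LASSO) logistic regression with 5-fold cross-validated
   penalty selection on the train sample; keep variables with a nonzero
   coefficient in at least 95% of iterations; and finally validate the
   kept variables by ordinary logistic regression on the held-out test
   sample. A variable "survives" when its holdout coefficient keeps the
   sign of its mean bootstrap coefficient and its Wald p-value is at most
   a configurable alpha (default 0.05).

Developmental trajectories of the SDQ subdomains are compared across
groups with a two-factor mixed ANOVA (group × age) with
Greenhouse–Geisser (GG) correction.

Because the motivating cohort is access-restricted, the package ships a
first-class synthetic cohort generator that emulates the statistical
structure the analysis assumes; every stage is exercised end-to-end on
generated data.

## Statistical model and estimators

### Stability selection

For predictor matrix $X$ (standardized columns) and binary outcome $y$,
each bootstrap iteration $b$ resamples participants with replacement
**stratified by outcome**, re-standardizes the columns on the resample,
and solves

$$\hat\beta^{(b)} = \arg\min_\beta \; -\tfrac1n \ell(\beta; X^{(b)}, y^{(b)})
  + \lambda_b \lVert\beta\rVert_1,$$

with $\lambda_b$ chosen per iteration by minimum mean 5-fold
cross-validated binomial deviance (folds stratified by outcome). The
inclusion frequency of variable $j$ is
$\pi_j = \frac1B \sum_b \mathbf 1\{\hat\beta^{(b)}_j \neq 0\}$, and
$j$ is *stable* when $\pi_j \ge 0.95$. The reported effect size is the
mean standardized coefficient over the iterations where the variable was
selected; for domain-wheel style summaries the mean of
$|\hat\beta^{(b)}_j|$ is used, with the sign reported separately.

Design choices a user should know about (all config-exposed through
`selection_config()`):

* **Penalty rule** — minimum CV deviance rather than the 1-SE rule. The
  procedure's conservatism comes from the 95% stability threshold, so the
  penalty choice is deliberately the least conservative of the two.
* **Per-resample standardization** — "standardized coefficient" is then
  well defined within each iteration, and coefficients are comparable
  across iterations and variables (binary predictors are scaled to unit
  SD like continuous ones, for penalty fairness).
* **Stratified resampling** — the subgroup-versus-comparison designs are
  imbalanced (about 1:2.4); stratification prevents single-class
  resamples.
* **Survival alpha** — holdout survival uses Wald $p \le 0.05$ by
  default. Published analyses of this design have treated a factor with
  $p = .052$ as validated, so the exact criterion is ambiguous in the
  field; it is a knob (`validation_alpha`), not a constant.
* **One split per contrast** — the 70/30 split is drawn once per
  subgroup-versus-comparison pair and reused across sweeps, mimicking a
  longitudinal design where the same held-out participants validate every
  sweep.

### SOM + k-means

The SOM is a batch self-organizing map on a rectangular grid (default
8×8 for a cohort of ~1,300; roughly 4–8 observations per node is
conventional and leaves k-means enough nodes to work with). The
neighborhood is Gaussian in grid space; the radius decays linearly from
`max(grid)/2` to 0.2 over 200 epochs. The small final radius matters:
at radius 1 the Gaussian weight between adjacent nodes is still 0.61, so
every node would remain a blend of neighbouring catchments; decaying to
~0 makes the last epochs pure vector quantization, which is the
conventional fine-tuning phase. Node weights are initialised linearly
along the first two principal components, so training is deterministic
and invariant to participant order; random-sample initialisation is
available (`init = "sample"`).

k-means on node weights uses `stats::kmeans` with 50 random restarts and
keeps the best within-cluster sum of squares. Cluster labels are
canonicalised by descending centroid SDQ total, so cluster 1 is always
the high-psychopathology profile. All distances everywhere (BMU
assignment, k-means, silhouette) are Euclidean in z-score space.
`select_k()` scans candidate k by mean silhouette with ties broken
toward smaller k.

The silhouette uses the standard $(b-a)/\max(a,b)$ definition with two
conventions: singleton clusters score 0, and $a=b=0$ (coincident points)
scores 0.

### KNN imputation

Distances between participants are Euclidean over pairwise-observed,
column-standardized coordinates, scaled by the number of shared observed
columns (so rows with different missingness patterns are comparable).
Donors tied with the k-th nearest distance are all included — this makes
the imputation deterministic and independent of row order. Continuous
cells take the donor mean; binary/ordinal cells take the donor mode with
ties broken toward the smaller category, which keeps binary columns in
{0, 1} for the logistic stage. The imputer sees predictors only — the
outcome is never an imputation feature, a deliberately conservative
choice since outcome-aware imputation could leak label information into
the selection stage. The exclusion rule is strict: *more than* 30%
missing is excluded, exactly 30% is retained.

### Mixed ANOVA with GG correction

The split-plot sums of squares come from the standard univariate
partition (`stats::aov` with an `Error(participant)` stratum; the
synthetic designs are balanced within participant, where the sequential
and Type II decompositions coincide for the interaction). The GG epsilon
is estimated from the pooled within-group covariance $S$ of the $m = 4$
repeated measures:

$$\hat\varepsilon = \frac{\operatorname{tr}(CSC)^2}{(m-1)\,\sum_{ij}(CSC)_{ij}^2},
  \qquad C = I - \tfrac1m \mathbf{1}\mathbf{1}^\top,$$

clipped to $[1/(m-1), 1]$; the interaction test uses
$F_{\hat\varepsilon\,df_1,\;\hat\varepsilon\,df_2}$. Two numerical facts
worth recording: for $m = 2$ the epsilon is identically 1, and the
common claim that the corrected p-value can never be smaller than the
uncorrected one holds only for $F \ge 1$ — when $F < 1$ shrinking both
degrees of freedom can shrink the upper-tail probability. Participants
missing any sweep's score are dropped from this analysis only
(listwise), matching the repeated-measures design; the rest of the
pipeline keeps them.

## What the synthetic generator emulates — and what it does not

`cohort_config()` defaults are the study conditions: group sizes
379/905/900; age-14 SDQ total means (SDs) 17.67 (5.10), 6.41 (3.56),
6.92 (5.22); MFQ 15.14 (6.72), 12.03 (6.87), 4.41 (4.43); about 71/76/70%
female; 80 candidate predictors per sweep in six domains; ~1.5% missing
predictor cells (published sweeps imputed 0.95–1.96%) plus 5% of
participants pushed over the 30% exclusion threshold. Earlier-sweep SDQ
totals (10 → 12 → 14.5 → 17.67 for the high-psychopathology group
against essentially flat profiles near 7 for the others) encode the
escalating-divergence trajectory; only the age-14 values are published
numbers, the earlier ones are this package's reading of the published
trajectory figure.

Distributional choices, made once:

* Scores are truncated-and-rounded normals. No distributional form is
  published for these measures; this is a modelling choice, not a data
  claim. Each SDQ subdomain is drawn independently with SD
  `total SD / sqrt(5)` so the five subdomains sum to the configured total
  mean and SD; subdomain-level parameters are not published. All five
  subdomains are treated as difficulty-scored.
* Subgroup membership is assigned first with fixed group sizes, then
  predictors are drawn conditional on group. A planted log-odds effect
  $\beta$ per SD is implemented as a mean shift of $\beta$ in the
  affected group's unit-SD predictor — exactly the coefficient an
  infinite-sample logistic regression of subgroup-versus-comparison on
  that predictor recovers.
* Missingness is MCAR by default (`mar_missingness = TRUE` doubles the
  cell rate in group 1 for a simple MAR mechanism); the real cohort's
  missingness mechanism is uncharacterised.
* Default planted effects (five per sweep, 0.8–1.0 log-odds per SD)
  mirror the qualitative structure of the published findings: the
  high-psychopathology subgroup carries child-mental-health, adversity
  and caregiver-mental-health effects; the second subgroup weaker
  peer-relations and child-health effects.

The generator does **not** emulate: survey sampling weights, attrition
across sweeps, item-level questionnaire responses, skew or bimodality of
real questionnaire scores, or correlated predictors. Consequences for
interpreting green tests: recovery and calibration results show the
*procedures* behave as designed under the assumed data-generating
process, not that real cohort data are this easy (or this hard).
The most consequential gap runs the other way: two truncated normals at
the published means/SDs overlap more than the real age-14 profiles
evidently do (the real two-cluster solution reports silhouette 0.52).
Under the generator's conditions a supervised classifier given the true
labels cannot exceed an adjusted Rand index of about 0.75 against the
planted labels, so unsupervised recovery plateaus near 0.65–0.70 — a
ceiling imposed by the generating distributions, not by the clustering
implementation.

## Problem sizes and numerical conventions

Simulation-backed checks in the test-suite use deliberately scaled
problem sizes — 200 bootstrap iterations instead of 1,000, 10 replicates
or seeds per experiment, null calibration at n = 900 with p = 80,
recovery at n_train ≈ 600 — chosen as the smallest designs at which the
monitored quantities (inclusion-frequency calibration, selection power,
ARI, KS uniformity of null p-values) are stable across seeds.
Tie-breaks are deterministic everywhere: first-encountered BMU on
distance ties, smaller k on silhouette ties, smaller category on donor-
mode ties, variable id on |beta| ties. All randomness flows from one
integer master seed through named substreams (`substream_seed(seed,
label)`), so adding draws to one stage never perturbs another, and
`run_pipeline()` outputs are byte-identical for a fixed seed and
configuration.

## A short worked run

```{r example, eval = FALSE}
cfg <- cohort_config(seed = 11)          # the full study conditions
cohort <- simulate_cohort(cfg)

fit <- fit_profile_clusters(cohort, k = "auto", seed = 11)
fit$k_profile                            # silhouette per candidate k

pr <- twopath:::predictors_at(cohort, 11, "group1")
sel <- stability_selection(pr$x, pr$y,
                           selection_config(n_bootstrap = 200, seed = 11))
sel                                      # selected + survived variables

trajectory_anova(cohort)$table
```

## Known limitations

* The SOM stage is one reading of a loosely specified "simple artificial
  neural network"; the original toolbox settings are unrecoverable, so
  grid size, epochs, schedule and initialisation are documented,
  config-exposed defaults rather than a reproduction.
* `mixed_anova_gg()` requires complete repeated measures and at least two
  participants per group; no mixed-effects growth-model alternative is
  provided (deliberately out of scope, as is the Huynh–Feldt correction).
* The imputer is single imputation; no between-imputation variance is
  propagated into the holdout standard errors.
* Sex-stratified analysis and survey design weights are out of scope.
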