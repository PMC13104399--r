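---
title: "Methods: panel discovery from label-free proteomes of small three-group cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: panel discovery from label-free proteomes of small three-group cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfqpanel)
```

## The problem and the model

`lfqpanel` targets a common design in clinical tissue proteomics: a few
dozen samples in three ordered disease groups (here N = non-diabetic,
P = pre-diabetic, D = type 2 diabetic; 11/6/9 by default), several
thousand proteins quantified by label-free iBAQ intensities, and the goal
of a *minimal protein panel* that separates the groups — not merely a
differential list. The pipeline chains five statistical stages, each of
which makes assumptions worth stating explicitly.

### Left-censored missingness and downshifted imputation

iBAQ values are missing mostly because a protein falls below the
instrument's detection limit, i.e. missing-not-at-random in the left tail
of the intensity distribution. The preprocessing stage therefore:

* scales each sample column to a common linear-scale total
  (`scale_total`, default 10^11), which equalizes sample loading under
  the assumption that most proteins do not change — a compositional
  assumption that fails if a loading-dominant protein changes several
  fold;
* log2-transforms, and keeps a protein only if some group has at least
  `ceiling(min_valid_fraction * n_g)` observed values
  (`min_valid_fraction = 0.90`; for groups of 11/6/9 this demands
  10/6/9). The ceiling convention reads "at least 90 %" as a lower
  bound;
* imputes each sample's remaining missing cells from
  N(m_s − `impute_downshift`·σ_s, (`impute_width`·σ_s)²) with the
  conventional Perseus defaults 1.8 and 0.3 (both in units of the
  sample's observed log2 sd). This *assumes* missing values sit below
  the detection limit; for values missing for other reasons it biases
  abundances downward.

Filtering precedes imputation, so imputed values can never rescue a
protein past the validity filter. Imputation draws are seeded and touch
only missing cells.

### Distribution-aware testing

For each protein the omnibus test over the three groups is chosen by a
decision tree: Shapiro–Wilk within each group and Levene across groups
(both gated at 0.05). All-normal + homoscedastic → Fisher one-way ANOVA
with pooled-t pairwise contrasts; all-normal + heteroscedastic → Welch
ANOVA with Games–Howell; any non-normal group → Kruskal–Wallis with Dunn.
Design choices a user should know:

* The normality gate requires Shapiro–Wilk p > 0.05 in *all three*
  groups; a group with fewer than 3 values cannot be tested and passes
  by default; a zero-variance group counts as non-normal (rank branch).
* Levene is mean-centered (the classic test matching its name);
  median-centering (Brown–Forsythe) is slightly more robust but is not
  what the decision tree announces.
* Games–Howell refers the Welch t statistic to the studentized-range
  distribution with k = 3; Dunn uses the pooled Kruskal–Wallis ranking
  with the standard ties correction.
* Holm step-down adjustment is applied across the three contrasts
  *within* a protein (m = 3), and no protein-level FDR is applied. The
  selection rule — omnibus p < α and at least one Holm-adjusted pairwise
  p < α — therefore controls per-protein error, not the expected number
  of false selections across thousands of proteins. On a global null the
  selected fraction stays below α, and on small candidate sets a few
  borderline null proteins are expected to ride along with real markers.
* Degenerate (zero-variance) proteins are excluded and reported, not
  assigned NaN p-values. With α = 1 the gates are disabled explicitly,
  because Holm-adjusted p-values cap at exactly 1.

### Exhaustive LDA subset ranking

The panel search scores *every* subset of the candidate proteins at sizes
2–5 (configurable) by linear-discriminant resubstitution accuracy —
train-on-all, predict-on-all, trace of the confusion matrix over n. This
is deliberately the optimistic accuracy notion: with 26 samples the
search is a ranking device, not a validity claim; validity is delegated
to the cross-validation stage. Numerical choices:

* The LDA fit solves the between/within scatter generalized eigenproblem
  via Cholesky reduction. A singular within-class scatter (collinear
  proteins, tiny n) gets a ridge of 1e-8 × trace(W) on the diagonal and
  is flagged, so an exhaustive enumeration never aborts mid-run.
* Classification uses the pooled-covariance Gaussian rule with
  class-proportion priors, and "% separation by LD1" is the first
  eigenvalue over the eigenvalue sum ("proportion of trace" in standard
  LDA output). Discriminant scores are scaled to unit pooled
  within-class variance, so they agree with standard implementations up
  to per-axis sign.
* Proteins are ranked by occurrence frequency among the perfect subsets
  at the minimal perfect size; ties break by ascending omnibus p (the
  biologically natural secondary key, configurable) and then name order,
  so the ranking is fully deterministic.
* At 23 candidates the search space is C(23,5) = 33,649 subsets of size
  5 and 44,528 across sizes 2–5; the lean fit evaluates these in well
  under a minute on one CPU.

### Screening: correlation and ROC

Pearson correlations among candidates are computed on the pooled,
imputed 26-sample matrix (all groups together), with pairs above a
*signed* threshold of 0.6 reported; strong negative correlations never
qualify. Per-protein ROC uses a fixed orientation — positive class is the
disease group, score is abundance — so markers that fall in disease have
AUC below 0.5, which is information, not an error; the rank-statistic AUC
counts ties as one half. The per-protein "accuracy" column is the best
confusion-matrix accuracy over all midpoint thresholds in both
orientations (a single-feature LDA reading is available behind the
`accuracy_rule` switch, since the field uses both conventions).

### Repeated cross-validated pair classification

Each candidate pair (and single) is evaluated per partitioning seed: a
stratified 70/30 split (per class, round(0.7·n_g) to training, clamped so
both sides keep every class; 11/6/9 → 8/4/6 vs 3/2/3), a repeated (3×)
stratified 4-fold CV of a three-class multinomial logistic model on the
training side — reported, tuning nothing — then a refit on the full
training side and confusion-matrix accuracy on the untouched 30 %. A pair
is *perfect* when its held-out accuracy is 1 for **every** seed (ten
seeds by default); a mean-based reading is available via `perfect_rule`.
Two numerical notes:

* The multinomial fit carries a fixed mild L2 penalty (`decay = 0.01`)
  because unpenalized multinomial fits on 18 training samples fail to
  converge exactly when a pair separates the classes — the interesting
  case. Features are standardized with training-side statistics first;
  log2 abundances sit far from zero, and penalizing the large intercepts
  that un-centered features require visibly biases the decision
  boundary.
* Partitioning, fold assignment and their sub-seeds derive
  deterministically from the seed list, so the full outcome table is
  reproducible byte for byte.

### qPCR follow-up

2^−ΔΔCt with technical replicates averaged before ΔCt, and the
calibrator taken as the *arithmetic mean ΔCt of the control group* (the
standard group-design convention; a single calibrator sample is the main
alternative). Consequences: the control group's fold changes have
geometric mean exactly 1, and a global Ct shift cancels. Group
comparisons reuse the two-group branch of the testing decision tree
(pooled t / Welch t / Wilcoxon). Amplification-efficiency correction
(Pfaffl) is out of scope.

## The synthetic cohort: what it emulates, and what it does not

`synthetic_spec()` defaults define the study conditions used throughout
the tests: 26 samples (11 N / 6 P / 9 D), 3963 proteins, 23 planted
differential proteins.

* Protein-level log2 means are N(`base_mu` = 23, `base_sigma`² = 3²) —
  iBAQ-like intensities spanning several orders of magnitude; sample
  measurements add N(0, `noise_sigma`² = 0.5²) residuals, a typical LFQ
  within-protein spread.
* A cell with latent log2 intensity x is detected with probability
  plogis(`missing_slope`·(x − `missing_mid`)); the defaults (slope 1,
  midpoint 21.5) were calibrated once, by Monte Carlo over the midpoint,
  so that the 90 % validity filter retains roughly half the proteins
  (≈ 2000 of 3963) — the attrition regime this pipeline is built for.
  Missingness is therefore strictly intensity-driven (MNAR), the model
  the downshifted imputation assumes.
* Planted markers get a log2 shift (default magnitude 2.5) in one
  affected group — upward in P, downward in D by default, mirroring the
  dominant directions in duodenal T2D proteomes. They are planted in a
  mid-to-high abundance band: reliably detected at the unshifted level
  (so the filter keeps them through their unaffected groups) but below
  the top abundance decile, because shifting a loading-dominant protein
  several fold perturbs the column-sum normalization of the affected
  samples and induces apparent changes in every other protein — an
  instructive artifact, but not the default condition to test under.
* The qPCR generator writes duplicate technical Ct replicates around a
  reference-gene Ct of 20 and a control ΔCt of 5, with planted group
  fold changes recoverable exactly at zero noise.

Passing tests on this cohort show the pipeline recovers planted
intensity shifts under intensity-driven missingness with independent
residuals. They do **not** show robustness to what real FFPE data adds:
correlated proteins (co-regulation, shared peptides), batch and
crosslinking-recovery effects, group-correlated missingness, heavy-tailed
residuals, or compositional shifts from dominant proteins. The
within-protein correlation structure in particular means real candidate
sets behave less independently than simulated ones — visible in the
correlation screen, where planted same-group markers correlate through
their shared group structure alone.

## Problem sizes and tolerances

The test suite runs the full generator defaults only where the check
needs them (parameter recovery uses 2076 proteins with 23 planted
markers at |Δlog2| = 2.5; the acceptance script runs the complete 3963 ×
26 pipeline with ten CV seeds); unit and property tests use matrices of
tens to hundreds of proteins, chosen as the smallest sizes at which the
properties are non-trivial. Monte Carlo assertions use frozen seeds and
tolerances derived from the statistic's own sampling error (binomial SDs
for proportions, 1 % relative error on 10^5 imputation draws);
normalization and trace-proportion identities are asserted at 1e-9
relative tolerance. The decision-tree simulation asserts the closed-form
gate probability 0.95^4 ≈ 0.81 for the Fisher branch under an exact
null, since each of the four gates passes independently with probability
0.95 there.

## Known limitations

* No protein-level FDR: selection mirrors the per-protein gate of the
  target analysis; at thousands of null proteins and α = 0.05 the
  selected list contains ~5 % of nulls by construction.
* Resubstitution LDA accuracy is optimistic by design; only the CV stage
  speaks to generalization, and with 8 held-out samples per seed even
  ten seeds give a coarse resolution (multiples of 1/8 per seed).
* Games–Howell and Dunn p-values use their standard asymptotic
  approximations, which are rough at n_g = 6.
* The multinomial CV model is mildly penalized; an unpenalized fit, as a
  textbook description would have it, is not attainable on separable
  18-sample training sets.
* 2^−ΔΔCt assumes perfect doubling efficiency for target and reference.
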