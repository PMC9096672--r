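---
title: "Deriving community-weighted point scores for prehospital ROSC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving community-weighted point scores for prehospital ROSC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(proscore)
```

## The problem

Return of spontaneous circulation (ROSC) before arrival at the emergency
department is the earliest marker of successful resuscitation in
out-of-hospital cardiac arrest (OHCA). A *point-based* ROSC score assigns
each patient an integer by summing per-variable category points — no logit
tables or calculators at the roadside — and large multi-community arrest
registries are the natural substrate for deriving one. Two things make that
derivation statistically interesting:

1. **Interpretability constraints.** The model must end up as small integer
   points over a handful of variables, maximum total 100, with the
   lowest-risk category of every variable pinned at 0.
2. **Community heterogeneity.** Arrest registries pool communities whose
   event rates, case mix and EMS practice differ substantially (in our
   simulated default, the largest community has roughly twice the ROSC rate
   of the smallest). A single pooled fit hides this; the divide-and-combine
   strategy implemented here fits one score per community and aggregates
   them with explicit weights.

`proscore` implements the full derivation pipeline, packages the published
five-variable P-ROSC table as `prosc_table()`, and ships a synthetic
registry generator so that every stage is testable although the real
registry is access-restricted.

## The derivation procedure

Given an eligible cohort split into training / validation / test sets:

1. **Ranking** (`rank_variables()`): a random forest of the outcome on all
   candidate variables (13 clinical candidates plus the community index)
   ranks importance. Defaults: 100 trees, impurity importance, fixed seed,
   one thread. The forest is only a *ranker*; it never produces the score.
2. **Parsimony** (`build_parsimony()`): for each top-k variable set a point
   model is derived on training data and scored on validation data; the
   AUC-versus-k curve guides the (human) choice of model size. We derive a
   point model at each k rather than a raw logistic model, so the curve
   measures exactly the object being selected.
3. **Categorisation** (`bin_continuous()`): continuous variables are cut at
   sample quantiles (default quartiles, type-7 linear interpolation —
   the convention had to be fixed somewhere and this is R's default).
   Intervals are lower-closed and upper-open (`q1 <= x < q2`), so a value
   equal to a cut takes the interval the cut opens. Cut-offs are exposed as
   a user-editable override in every downstream function because, in
   practice, final cut-offs are fine-tuned by clinical judgement — a step
   that cannot be automated honestly.
4. **Points** (`derive_points()`): a multivariable logistic regression on
   the indicator-coded categories; within each variable the
   lowest-coefficient category is rebased to 0; every coefficient
   difference is divided by the smallest positive difference in the model
   and rounded half-away-from-zero. The weakest retained effect therefore
   maps to 1 point and all points are non-negative integers.
5. **Per-community fitting and weighting** (`derive_weighted_score()`):
   with variables, levels and cuts frozen (fitted on pooled training
   data), steps 4 is repeated per community; community *i* with training
   size \(N_i\) and validation AUC \(AUC_i\) receives weight
   \[ w_i = \frac{AUC_i \, N_i^{3}}{\sum_j AUC_j \, N_j^{3}}, \]
   and each category's point is the \(w\)-weighted average across
   communities, rounded half-away-from-zero. The cube is taken literally
   from the published formula; because it makes the largest community
   dominate almost completely (weights of 0.997 vs 0.003 are typical at
   realistic size ratios), the exponent is a parameter (`exponent = 3`)
   so its consequences can be examined.
6. **Normalisation** (`normalize_table()`): points are rescaled so the
   maximum attainable total is exactly 100; the post-rounding residual is
   pushed onto the single largest point value. The operation is idempotent
   and zero references stay zero.
7. **Probability conversion** (`fit_probability_conversion()`,
   `build_conversion_table()`): a single-predictor logistic model of
   outcome on score, fitted on validation data, maps any cut-off to a
   predicted ROSC probability; the conversion table adds the percentage of
   patients at or above each cut-off and sensitivity/specificity with
   Wilson 95% intervals (Wilson rather than Wald because the extreme
   cut-offs put the proportions near 0 or 1). The observation weights of
   the "weighted" logistic regression are not pinned down in the source
   description; we default to community weights \(w_i\), with unweighted
   fitting available.

A sensitivity check, `fit_uncategorized_lr()`, refits the same variables
without any recoding or categorisation; comparing its test AUC with the
point score's measures what the categorisation costs (or gains).

## Cohort policy

`prepare_cohort()` chains the study's data rules: structurally missing
arrest location and bystander-AED status become an explicit `"unknown"`
category (whole source registries did not record them — the missingness is
informative structure, not noise); then records are excluded in a fixed
documented order — resuscitation not attempted, not conveyed by EMS, DNR
order, missing outcome, missing age, age under 18, incomplete remaining
fields, and finally communities with fewer than 1000 cases (too small to
support a community-specific model). Each excluded record is tallied under
the *first* rule it fails, so the tally always reconciles exactly with the
input size. `temporal_stratified_split()` then reserves the most recent 20%
of each community as the test set (seed-free by construction; timestamp
ties broken by record id) and splits the remainder 7:1 into training and
validation, stratified by outcome.

## What the synthetic registry emulates

`generate_cohort()` draws, per community, candidate variables from
configurable marginals and the binary ROSC outcome from a
logistic-additive model with a community intercept calibrated (by root
finding) to a target marginal prevalence. The defaults describe a
four-community registry shaped like the published derivation cohort
scaled down by ten — sizes 13,037 / 1,439 / 1,207 / 1,385 (total 17,068) —
with community ROSC rates 8.8%, 7.0%, 4.6% and 8.0% (overall near 8.26%,
and the largest community roughly double the rate of the third), drug
administration common in the Singapore-like community and rare in the
Korean-like one, 70% missing arrest location in the Japan-like community
and 99% missing AED status in the Taiwan-like one.

The default outcome effects are an *additive point model*: 0.075 logit per
point of the published table (age and response time as step functions,
shockable rhythm 30 points, witness status, drug administration). Two
reasons: it gives a known ground truth against which the entire pipeline's
recovery can be measured, and 0.075 logit/point places the true score's
discrimination near AUC 0.8, the regime reported for prehospital ROSC
scores. Marginals follow the published descriptive table where printed
(shockable 9.3%, professional witness 7.1%, lay witness 35.7%, drug 12.3%,
age centred at 72 with SD 17, response time log-normal with median
6.3 min); the remaining marginals are plausible values, not calibrated
ones, because no reference distributions are printed for them.

What the generator deliberately does **not** emulate: joint dependence
between predictors beyond what the outcome model induces, secular trends
in event times (uniform over 2009–2018), informative missingness, pediatric
or trauma-specific physiology, and registry bookkeeping quirks. Passing
recovery tests therefore show the *pipeline* is correct and stable at
realistic sizes — they are not evidence about real registry data.

## Numerical choices and degenerate inputs

* Rounding is half-away-from-zero everywhere points are rounded; R's
  banker's rounding would make point values depend on floating parity.
* Weights are computed on size *ratios* (`(N_i / max N)^p`), so they are
  invariant under common rescaling of sizes or AUCs and immune to overflow
  at any exponent.
* `derive_points()` treats a singular fit or a coefficient beyond ±15 as a
  failed (separated) fit and names the variable; empty category levels are
  dropped with a warning; a constant continuous variable cannot be binned.
  Quantile cuts are deduplicated and cuts at the sample minimum are
  discarded so no empty lowest interval arises.
* DeLong comparison of two identical (or rank-identical) score vectors has
  zero variance; the comparison returns a difference of 0 with p = 1
  rather than NaN.
* The normality check in `describe_cohort()` is a Kolmogorov–Smirnov test
  against a normal with the sample moments; with registry-sized n it
  rejects normality for any clinically interesting variable, which is why
  group comparisons default to rank tests. Chi-square tests are computed
  without continuity correction.

## Scale of the shipped checks, and a known limitation

The test suite exercises generator calibration at n = 50,000 (within three
Monte-Carlo standard errors), effect recovery by logistic regression at
n = 50,000 (within three model standard errors), and the full
rank–bin–derive–weight–aggregate–normalise pipeline at the default
17,068-record, four-community registry. At that scale the pipeline
recovers the generative table's category orderings exactly, with Spearman
rank correlation above 0.99 and a test AUC within 0.02 of the generative
score's.

Individual category *points*, however, carry an irreducible sampling
noise of about ±2–3 points: one normalised point equals the generative
slope (0.075 logit), while the low-risk reference cells (age ≥ 90,
response ≥ 12 min) of the dominant community hold only ~50 outcome
events, so entire variable blocks shift together with a standard error
near 0.15 logit ≈ 2 points. The cubic size weighting is decisive here —
it concentrates ~99.7% of the weight in the largest community, so the
smaller communities contribute essentially no variance reduction. A
ten-fold larger simulation (the size of the real registry) still shows
deviations up to 2 points, partly from the rounding chain itself:
dividing by the smallest coefficient (≈3 raw points) before normalising
can alone move a category by one point (e.g. 30 → 31). Exact point
reproduction is therefore not a realistic expectation of this derivation
procedure at any feasible cohort size; orderings and discrimination are.

## Worked example

```{r example}
cfg <- cohort_config(seed = 42)
cohort <- generate_cohort(cfg)
prep <- prepare_cohort(cohort)
prep$tally

rec <- prep$records
split <- temporal_stratified_split(rec, seed = 7)
vars <- c("age", "response_time", "first_rhythm", "witnessed",
          "prehospital_drug")
fit <- derive_weighted_score(rec, split, vars,
                             binning = list(age = c(60, 85, 90),
                                            response_time = c(5, 9, 12)))
round(fit$weights, 4)
fit$table

test <- rec[split == "test", ]
scores <- apply_score_table(test[vars], fit$table)
auc_with_ci(scores, test$rosc)
mean_score_by_outcome(scores, test$rosc)

val <- rec[split == "validation", ]
pmap <- fit_probability_conversion(
  apply_score_table(val[vars], fit$table), val$rosc)
build_conversion_table(scores, test$rosc, pmap, cutoffs = seq(20, 80, 20))
```

Comparator scores of the logit family are evaluated on the same test set
with `logit_score()` after `recode_for_ub_rosc()`-style recoding, and
compared with `evaluate_scorers()`, which reports each AUC with its
DeLong 95% CI and all pairwise DeLong tests.
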