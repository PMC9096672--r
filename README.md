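# proscore

Derivation and evaluation of point-based prehospital ROSC scores for
out-of-hospital cardiac arrest (OHCA).

Return of spontaneous circulation (ROSC) before hospital arrival is the
earliest marker of resuscitation success. A point-based ROSC score maps
each patient's category in a handful of prehospital variables (age,
response time, first rhythm, witness status, drug administration, ...) to
small integer points that simply add up — usable at the roadside, no
calculator. `proscore` is aimed at biostatisticians and resuscitation
researchers who derive, audit or compare such scores on multi-community
arrest registries.

## What it implements

* **The derivation engine**: random-forest variable ranking, a parsimony
  (AUC-versus-model-size) curve, quantile categorisation of continuous
  variables with half-open intervals (`q1 <= x < q2`), and conversion of
  logistic-regression coefficients to integer points — each variable's
  lowest-risk category is the 0-point reference and coefficient
  differences are divided by the smallest positive difference and rounded
  half-away-from-zero.
* **Divide-and-combine aggregation** for heterogeneous registries: one
  score per community, then a weighted average of category points with

      w_i = AUC_i * N_i^3 / sum_j (AUC_j * N_j^3)

  (validation AUC times cubed training size, normalised), followed by
  rescaling so the maximum attainable total is exactly 100.
* **The published P-ROSC table** as a packaged constant (`prosc_table()`),
  plus a score-to-probability conversion table builder with Wilson 95%
  intervals for sensitivity/specificity at each cut-off.
* **Comparator machinery**: logit-formula scorers (RACA-style linear
  predictor through the logistic function, coefficients supplied by the
  user) and the documented registry recoding rules for UB-ROSC-style
  scores (location remapping, rhythm collapse, witness-by-CPR fusion).
* **Evaluation**: AUC with DeLong confidence intervals, pairwise DeLong
  tests, and study-table-style descriptive summaries (rank tests for
  continuous variables, chi-square without continuity correction for
  categorical ones).
* **A synthetic multi-community registry generator** with configurable
  sizes, prevalences, effects (including step-function "point model"
  truths), marginals and missingness, plus the study's eligibility
  filters and a most-recent-cases temporal split — so the whole pipeline
  is testable although real arrest registries are access-restricted.

## Worked example

Scoring three patients with the packaged table:

```r
library(proscore)
patients <- data.frame(
  age              = c(55, 72, 92),
  response_time    = c(4, 7, 13),
  first_rhythm     = regroup_rhythm(c("vf", "pea", "asystole")),
  witnessed        = c("professional", "layperson", "none"),
  prehospital_drug = c("yes", "yes", "no"))
apply_score_table(patients, prosc_table())
#> [1] 100  57   0
```

Patient 1 (55 y, 4 min response, shockable, professionally witnessed,
drug given) collects 13+9+30+27+21 = 100 points, the maximum; patient 3
sits in the reference category of every variable and scores 0.

Deriving a community-weighted score on a simulated registry whose outcome
truth *is* an additive point model (0.075 logit per point of the packaged
table):

```r
cohort <- generate_cohort(cohort_config(seed = 42))   # 4 communities, 17,068 records
prep   <- prepare_cohort(cohort)                      # eligibility + unknown-recoding
rec    <- prep$records
split  <- temporal_stratified_split(rec, seed = 7)    # latest 20% per community = test
vars   <- c("age", "response_time", "first_rhythm", "witnessed", "prehospital_drug")
fit    <- derive_weighted_score(rec, split, vars,
                                binning = list(age = c(60, 85, 90),
                                               response_time = c(5, 9, 12)))
fit$table
#> Point-based score table (max 100 points)
#>   age
#>     <60                       15
#>     60-85                     14
#>     85-90                     11
#>     >=90                       0
#>   ...
#>   first_rhythm
#>     shockable                 30
#>     unshockable                0
#>   ...

test   <- rec[split == "test", ]
scores <- apply_score_table(test[vars], fit$table)
auc_with_ci(scores, test$rosc)
#> AUC 0.778 (95% CI 0.744-0.813; 209 positive / 2203 negative)
round(mean_score_by_outcome(scores, test$rosc), 1)
#>    rosc no_rosc
#>    50.7    32.3
```

The derived table reproduces the generative table's category orderings
exactly and its test-set AUC is within 0.003 of the generative score's;
individual points wobble by a few points because the cubic size weighting
concentrates ~99.7% of the weight in the largest community (see the
methods vignette, `vignettes/score-derivation.Rmd`, for why that noise
floor is irreducible).

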