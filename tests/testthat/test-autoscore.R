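# Score-derivation engine: regrouping, ranking, binning, point derivation,
# parsimony curve, uncategorised sensitivity model.

test_that("rhythm regrouping follows the shockable/unshockable mapping", {
  expect_equal(regroup_rhythm(c("vf", "vt", "unknown_shockable")),
               rep("shockable", 3))
  expect_equal(regroup_rhythm(c("pea", "asystole", "unknown_unshockable")),
               rep("unshockable", 3))
  expect_equal(regroup_rhythm("shockable"), "shockable")  # pass-through
  expect_error(regroup_rhythm(c("vf", NA)), "missing")
  expect_error(regroup_rhythm("sinus"), "unknown rhythm")
})

test_that("quantile binning uses type-7 quantiles and half-open intervals", {
  cuts <- bin_continuous(1:100, c(0.25, 0.5, 0.75))
  expect_equal(cuts, unname(quantile(1:100, c(0.25, 0.5, 0.75), type = 7)))
  # heavy ties collapse duplicated quantiles; cuts stay strictly increasing
  # and never open an empty lowest interval
  x <- c(rep(2, 75), 101:125)
  cuts2 <- bin_continuous(x, c(0.25, 0.5, 0.75))
  expect_lt(length(cuts2), 3)
  expect_true(all(diff(cuts2) > 0))
  expect_true(all(cuts2 > min(x)))
  expect_error(bin_continuous(rep(3, 10)), "constant")
  # a value equal to a cut scores in the interval the cut opens
  tab <- score_table(list(v = list(levels = c("<2", "2-4", ">=4"),
                                   points = c(0, 1, 2), cuts = c(2, 4))))
  expect_equal(apply_score_table(data.frame(v = c(2, 4)), tab), c(1, 2))
})

test_that("random-forest ranking finds the only informative variable", {
  eff <- list(first_rhythm = c(vf = 2, vt = 2, unknown_shockable = 2,
                               pea = 0, asystole = 0, unknown_unshockable = 0))
  coh <- generate_cohort(clean_config(20000, base_rate = 0.15,
                                      effects = eff, seed = 31))
  cand <- c("age", "response_time", "first_rhythm", "witnessed",
            "prehospital_drug", "gender", "bystander_cpr")
  rk <- rank_variables(coh, cand, seed = 2)
  expect_equal(nrow(rk), length(cand))
  expect_setequal(rk$variable, cand)
  expect_true(all(rk$importance >= 0))
  expect_equal(rk$variable[1], "first_rhythm")
  # permuting the top variable's column demotes it from first place
  coh2 <- coh
  coh2$first_rhythm <- sample(coh2$first_rhythm)
  rk2 <- rank_variables(coh2, cand, seed = 2)
  expect_false(rk2$variable[1] == "first_rhythm")
  # single-class outcome is rejected
  coh3 <- coh[coh$rosc == "no", ]
  expect_error(rank_variables(coh3, cand, seed = 2), "both classes")
})

test_that("point derivation self-scales, reflects effect ratios and monotonicity", {
  # single binary predictor -> reference 0, other category 1
  set.seed(41)
  n <- 20000
  x1 <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-2 + 0.8 * x1))
  rec <- data.frame(v1 = ifelse(x1 == 1, "b", "a"), rosc = y)
  tab <- derive_points(rec, "v1")
  expect_equal(tab$variables$v1$points, c(0, 1))
  expect_equal(tab$variables$v1$levels, c("a", "b"))

  # two binary predictors with log-odds 0.5 and 1.0 -> points 1 and 2
  set.seed(42)
  n <- 50000
  x1 <- rbinom(n, 1, 0.5); x2 <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-2.5 + 0.5 * x1 + 1.0 * x2))
  rec <- data.frame(v1 = ifelse(x1 == 1, "b", "a"),
                    v2 = ifelse(x2 == 1, "b", "a"), rosc = y)
  tab <- derive_points(rec, c("v1", "v2"))
  expect_equal(tab$variables$v1$points, c(0, 1))
  expect_equal(tab$variables$v2$points, c(0, 2))

  # monotone generative risk across age bins -> monotone points
  eff <- list(age = list(cuts = c(50, 65, 80), values = c(1.5, 1.0, 0.5, 0)))
  coh <- generate_cohort(clean_config(50000, base_rate = 0.10,
                                      effects = eff, seed = 43))
  tab <- derive_points(coh, "age", binning = list(age = c(50, 65, 80)))
  expect_equal(tab$variables$age$levels, c("<50", "50-65", "65-80", ">=80"))
  expect_true(all(diff(tab$variables$age$points) < 0))
})

test_that("empty category levels are dropped with a warning", {
  rec <- data.frame(v = rep(c("a", "b"), each = 50),
                    rosc = rep(c(0, 1), 50))
  expect_warning(
    tab <- derive_points(rec, "v", level_sets = list(v = c("a", "b", "ghost"))),
    "empty category"
  )
  expect_equal(tab$variables$v$levels, c("a", "b"))
})

test_that("the parsimony curve shows diminishing returns after the true model", {
  # five informative variables; the rest carry no effect
  coh <- generate_cohort(cohort_config(
    communities = data.frame(id = "A", n = 20000L, base_rate = 0.0826),
    marginal_overrides = list(),
    missingness = list(rates = numeric(0), by_community = list()),
    not_conveyed_rate = 0, dnr_rate = 0, no_resuscitation_rate = 0,
    seed = 44))
  coh$first_rhythm <- regroup_rhythm(coh$first_rhythm)
  split <- temporal_stratified_split(coh, seed = 1)
  train <- coh[split == "train", ]
  val <- coh[split == "validation", ]
  # order the five informative variables so the fifth carries a strong
  # effect: the gain from adding it dwarfs the null gain from the sixth
  ranking <- data.frame(
    variable = c("first_rhythm", "prehospital_drug", "age",
                 "response_time", "witnessed", "gender", "bystander_cpr"),
    stringsAsFactors = FALSE)
  curve <- build_parsimony(train, val, ranking)
  expect_equal(curve$k, 1:7)
  expect_true(all(curve$auc >= 0 & curve$auc <= 1))
  gain_5 <- curve$auc[5] - curve$auc[4]
  gain_6 <- curve$auc[6] - curve$auc[5]
  expect_lt(gain_6, gain_5)
})

test_that("the uncategorised sensitivity model behaves at the extremes", {
  # perfectly separable toy data
  tr <- data.frame(x = c(1, 2, 3, 10, 11, 12), rosc = c(0, 0, 0, 1, 1, 1))
  res <- fit_uncategorized_lr(tr, tr, "x")
  expect_equal(res$auc, 1.0)
  # label-independent features sit at chance level
  set.seed(55)
  n <- 10000
  te <- data.frame(x = rnorm(n), z = sample(c("a", "b"), n, TRUE),
                   rosc = rbinom(n, 1, 0.3))
  res2 <- fit_uncategorized_lr(te, te, c("x", "z"))
  n1 <- sum(te$rosc); n0 <- n - n1
  se_null <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(res2$auc - 0.5), 3 * se_null)
  # under a purely linear-logit truth the raw model beats the binned score
  eff <- list(age = -0.05, response_time = -0.08)
  coh <- generate_cohort(clean_config(30000, base_rate = 0.15,
                                      effects = eff, seed = 56))
  split <- temporal_stratified_split(coh, seed = 2)
  train <- coh[split == "train", ]
  test <- coh[split == "test", ]
  raw_auc <- fit_uncategorized_lr(train, test, c("age", "response_time"))$auc
  tab <- derive_points(train, c("age", "response_time"),
                       binning = list(age = bin_continuous(train$age),
                                      response_time = bin_continuous(train$response_time)))
  binned_auc <- auc_with_ci(apply_score_table(test, tab), test$rosc)$auc
  expect_gte(raw_auc, binned_auc)
})
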