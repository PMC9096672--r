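# Packaged P-ROSC table, probability conversion, conversion table, logit
# comparator machinery and UB-ROSC recoding.

test_that("the packaged P-ROSC table matches every published cell", {
  tab <- prosc_table()
  expected <- data.frame(
    variable = c(rep("age", 4), rep("response_time", 4), rep("first_rhythm", 2),
                 rep("witnessed", 3), rep("prehospital_drug", 2)),
    category = c("<60", "60-85", "85-90", ">=90",
                 "<5", "5-9", "9-12", ">=12",
                 "unshockable", "shockable",
                 "none", "professional", "layperson",
                 "yes", "no"),
    points = c(13L, 10L, 7L, 0L, 9L, 7L, 3L, 0L, 0L, 30L, 0L, 27L, 19L,
               21L, 0L),
    stringsAsFactors = FALSE)
  expect_equal(as.data.frame(tab), expected)
  expect_equal(max_score(tab), 100)
  # every variable has a zero-point reference category
  expect_true(all(vapply(tab$variables, function(v) any(v$points == 0),
                         logical(1))))
  # the shockable rhythm alone contributes 30 points
  shock <- tab$variables$first_rhythm
  expect_equal(shock$points[shock$levels == "shockable"] -
                 shock$points[shock$levels == "unshockable"], 30)
})

test_that("worked patient examples score as published", {
  best <- data.frame(age = 55, response_time = 4, first_rhythm = "shockable",
                     witnessed = "professional", prehospital_drug = "yes")
  expect_equal(apply_score_table(best, prosc_table()), 100)
  worst <- data.frame(age = 92, response_time = 13,
                      first_rhythm = "unshockable", witnessed = "none",
                      prehospital_drug = "no")
  expect_equal(apply_score_table(worst, prosc_table()), 0)
  mid <- data.frame(age = 72, response_time = 7, first_rhythm = "shockable",
                    witnessed = "layperson", prehospital_drug = "yes")
  expect_equal(apply_score_table(mid, prosc_table()), 10 + 7 + 30 + 19 + 21)
})

test_that("probability conversion recovers a logistic score-outcome law", {
  set.seed(61)
  n <- 20000
  s <- sample(0:100, n, replace = TRUE)
  a <- -4; b <- 0.045
  y <- rbinom(n, 1, plogis(a + b * s))
  map <- fit_probability_conversion(s, y)
  fit <- glm(y ~ s, family = binomial())
  se <- summary(fit)$coefficients[, "Std. Error"]
  expect_lt(abs(map$intercept - a), 3 * se[1])
  expect_lt(abs(map$slope - b), 3 * se[2])
  # equal weights match the unweighted fit; the map is strictly monotone
  map_w <- fit_probability_conversion(s, y, weights = rep(2, n))
  expect_equal(map_w$intercept, map$intercept, tolerance = 1e-8)
  expect_equal(map_w$slope, map$slope, tolerance = 1e-8)
  expect_true(all(diff(predict(map, 0:100)) > 0))
  expect_error(fit_probability_conversion(s, rep(0, n)),
               class = "proscore_fit_error")
})

test_that("conversion tables report correct operating characteristics", {
  map <- fit_probability_conversion(c(0, 20, 40, 60), c(0, 0, 1, 1))
  toy_s <- c(10, 20, 30, 40)
  toy_y <- c(0, 0, 1, 1)
  ct <- build_conversion_table(toy_s, toy_y, map, cutoffs = c(5, 20, 30))
  # a cut-off below the minimum score captures everyone
  expect_equal(ct$sensitivity[1], 1)
  expect_equal(ct$specificity[1], 0)
  expect_equal(ct$pct_patients[1], 100)
  # c = 20: both positives kept, one of two negatives excluded
  expect_equal(ct$sensitivity[2], 1)
  expect_equal(ct$specificity[2], 0.5)
  # c = 30 separates the classes perfectly
  expect_equal(ct$sensitivity[3], 1)
  expect_equal(ct$specificity[3], 1)
  expect_true(all(ct$sens_lo <= ct$sensitivity & ct$sensitivity <= ct$sens_hi))
  expect_error(build_conversion_table(numeric(0), integer(0), map), "empty")

  # monotone operating characteristics on arbitrary score data
  set.seed(62)
  s <- sample(0:100, 500, TRUE)
  y <- rbinom(500, 1, plogis(-2 + 0.03 * s))
  ct2 <- build_conversion_table(s, y, fit_probability_conversion(s, y))
  expect_true(all(diff(ct2$sensitivity) <= 0))
  expect_true(all(diff(ct2$specificity) >= 0))
  expect_true(all(diff(ct2$predicted_probability) > 0))
  expect_true(all(ct2$predicted_probability >= 0 &
                    ct2$predicted_probability <= 1))
})

test_that("logit scoring evaluates the linear predictor through plogis", {
  rec <- data.frame(witnessed = c("none", "layperson"),
                    age = c(70, 50))
  zero <- logit_coefficients(0, list(witnessed = c(none = 0, layperson = 0)))
  expect_equal(logit_score(rec, zero), c(0.5, 0.5))
  # X = 1.5 -> 0.8176 (evaluated logistic function)
  one5 <- logit_coefficients(1.5)
  expect_equal(logit_score(rec, one5), rep(0.81757, 2), tolerance = 1e-4)
  # a strongly negative intercept drives the probability to zero
  expect_lt(logit_score(rec[1, ], logit_coefficients(-30))[1], 1e-12)
  # mixed categorical and linear terms
  lc <- logit_coefficients(-1, list(witnessed = c(none = 0, layperson = 0.5),
                                    age = -0.01))
  expect_equal(logit_score(rec, lc),
               plogis(c(-1 - 0.7, -1 + 0.5 - 0.5)), tolerance = 1e-12)
  # unmapped category is a coefficient error
  bad <- logit_coefficients(0, list(witnessed = c(none = 0)))
  expect_error(logit_score(rec, bad), class = "proscore_coef_error")
})

test_that("UB-ROSC recoding maps location, rhythm and witness-CPR fusion", {
  rec <- data.frame(
    arrest_location = c("industrial_area", "unknown", "transportation_center",
                        "home", "street"),
    witnessed = c("professional", "none", "none", "layperson", "layperson"),
    bystander_cpr = c("yes", "no", "yes", "no", "yes"),
    first_rhythm = c("vf", "asystole", "pea", "vt", "unknown_unshockable"),
    etiology = rep("cardiac", 5),
    stringsAsFactors = FALSE)
  out <- recode_for_ub_rosc(rec)
  expect_equal(out$arrest_location,
               c("workplace", "home", "public_building", "home", "street"))
  expect_equal(out$first_rhythm,
               c("shockable", "unshockable", "unshockable", "shockable",
                 "unshockable"))
  # professional witness maps to EMS-witnessed regardless of CPR status
  expect_equal(out$witness_cpr,
               c("ems_witnessed", "not_witnessed_no_cpr", "not_witnessed_cpr",
                 "witnessed_no_cpr", "witnessed_cpr"))
  rec2 <- rec
  rec2$bystander_cpr[1] <- NA
  expect_error(recode_for_ub_rosc(rec2), class = "proscore_recode_error")
  expect_error(recode_for_ub_rosc(rec[, -1]), class = "proscore_recode_error")
})
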