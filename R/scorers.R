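# Applying score definitions to records: the packaged P-ROSC table,
# score-to-probability conversion, and the logit-formula / recoding
# machinery used by comparator scores.

#' The published P-ROSC score table
#'
#' The packaged five-variable point table for prehospital ROSC: age
#' (<60: 13, 60-85: 10, 85-90: 7, >=90: 0), time to EMS arrival in minutes
#' (<5: 9, 5-9: 7, 9-12: 3, >=12: 0), first rhythm (shockable: 30,
#' unshockable: 0), arrest witnessed (professional: 27, layperson: 19,
#' none: 0) and prehospital drug administration (yes: 21, no: 0). Age and
#' response-time intervals are lower-closed and upper-open; the maximum
#' attainable total is 100. Rhythm must be regrouped with
#' [regroup_rhythm()] before scoring.
#'
#' @return a [score_table()].
#' @export
#' @examples
#' prosc_table()
prosc_table <- function() {
  score_table(list(
    age = list(levels = c("<60", "60-85", "85-90", ">=90"),
               points = c(13, 10, 7, 0), cuts = c(60, 85, 90)),
    response_time = list(levels = c("<5", "5-9", "9-12", ">=12"),
                         points = c(9, 7, 3, 0), cuts = c(5, 9, 12)),
    first_rhythm = list(levels = c("unshockable", "shockable"),
                        points = c(0, 30)),
    witnessed = list(levels = c("none", "professional", "layperson"),
                     points = c(0, 27, 19)),
    prehospital_drug = list(levels = c("yes", "no"), points = c(21, 0))
  ))
}

#' Convert scores to outcome probabilities
#'
#' Fits a single-predictor logistic regression of the binary outcome on the
#' score, optionally with observation weights (by default each validation
#' record can be weighted by its community's aggregation weight), and
#' returns a monotone score-to-probability map.
#'
#' @param scores numeric vector of scores (validation set).
#' @param outcomes binary outcome vector aligned with `scores`.
#' @param weights optional non-negative observation weights; `NULL` fits
#'   unweighted.
#' @return object of class `score_prob_map` with fields `intercept` and
#'   `slope`; use `predict(map, scores)` to evaluate.
#' @export
fit_probability_conversion <- function(scores, outcomes, weights = NULL) {
  y <- as_binary_outcome(outcomes)
  stop_if_not(length(unique(y)) == 2,
              "fit error: outcome must have both classes present",
              class = "proscore_fit_error")
  stop_if_not(is.null(weights) || all(weights >= 0),
              "weights must be non-negative")
  dat <- data.frame(.y = y, .s = as.numeric(scores))
  dat$.w <- if (is.null(weights)) rep(1, length(y)) else weights
  fit <- suppressWarnings(stats::glm(.y ~ .s, data = dat, weights = .w,
                                     family = stats::binomial()))
  cf <- stats::coef(fit)
  structure(list(intercept = unname(cf[1]), slope = unname(cf[2])),
            class = "score_prob_map")
}

#' @export
predict.score_prob_map <- function(object, newdata, ...) {
  stats::plogis(object$intercept + object$slope * as.numeric(newdata))
}

# Wilson score interval for a binomial proportion
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  as.numeric(suppressWarnings(
    stats::prop.test(x, n, correct = FALSE, conf.level = conf)$conf.int))
}

#' Conversion table: score cut-offs to probability and operating metrics
#'
#' For each cut-off c the table reports the model-predicted outcome
#' probability at a score of c, the percentage of patients scoring at or
#' above c, and the sensitivity and specificity (with Wilson 95% CIs) of
#' the classification rule "score >= c predicts the outcome".
#'
#' @param scores numeric test-set scores.
#' @param outcomes binary outcome vector aligned with `scores`.
#' @param prob_map a `score_prob_map` from [fit_probability_conversion()].
#' @param cutoffs strictly increasing numeric cut-offs (study convention:
#'   10, 20, ..., 90).
#' @return data frame of class `conversion_table` with columns `cutoff`,
#'   `predicted_probability`, `pct_patients`, `sensitivity`, `sens_lo`,
#'   `sens_hi`, `specificity`, `spec_lo`, `spec_hi`.
#' @export
build_conversion_table <- function(scores, outcomes, prob_map,
                                   cutoffs = seq(10, 90, by = 10)) {
  stop_if_not(length(scores) > 0, "empty test set")
  stop_if_not(all(diff(cutoffs) > 0), "cutoffs must be strictly increasing")
  y <- as_binary_outcome(outcomes)
  rows <- lapply(cutoffs, function(cc) {
    pos <- scores >= cc
    tp <- sum(pos & y == 1); fn <- sum(!pos & y == 1)
    tn <- sum(!pos & y == 0); fp <- sum(pos & y == 0)
    sens_ci <- wilson_ci(tp, tp + fn)
    spec_ci <- wilson_ci(tn, tn + fp)
    data.frame(cutoff = cc,
               predicted_probability = predict(prob_map, cc),
               pct_patients = 100 * mean(pos),
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               sens_lo = sens_ci[1], sens_hi = sens_ci[2],
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               spec_lo = spec_ci[1], spec_hi = spec_ci[2])
  })
  structure(do.call(rbind, rows),
            class = c("conversion_table", "data.frame"))
}

#' Logit-formula coefficient sets
#'
#' Container for scores of the RACA family, where a linear predictor X is
#' the intercept plus per-category coefficients (and optional linear terms
#' for numeric fields) and the ROSC probability is `plogis(X)`.
#'
#' @param intercept numeric intercept of the linear predictor.
#' @param terms named list; each element is either a named numeric vector
#'   mapping a field's categories to coefficients, or a single unnamed
#'   numeric giving a linear coefficient for a numeric field.
#' @return object of class `logit_coefficients`.
#' @export
#' @examples
#' lc <- logit_coefficients(0.2, list(witnessed = c(none = 0, layperson = 0.5)))
logit_coefficients <- function(intercept, terms = list()) {
  stop_if_not(is.numeric(intercept) && length(intercept) == 1,
              "intercept must be a single number")
  structure(list(intercept = intercept, terms = terms),
            class = "logit_coefficients")
}

#' Score records with a logit formula
#'
#' @param records data frame of recoded records.
#' @param coefficients a [logit_coefficients()] set covering every category
#'   the records take.
#' @return numeric vector of predicted probabilities `plogis(X)`.
#' @export
logit_score <- function(records, coefficients) {
  stop_if_not(inherits(coefficients, "logit_coefficients"),
              "'coefficients' must be a logit_coefficients set")
  X <- rep(coefficients$intercept, nrow(records))
  for (f in names(coefficients$terms)) {
    term <- coefficients$terms[[f]]
    x <- records[[f]]
    stop_if_not(!is.null(x), "coefficient error: field '", f,
                "' absent from records", class = "proscore_coef_error")
    stop_if_not(!anyNA(x), "coefficient error: missing values in field '", f,
                "'", class = "proscore_coef_error")
    if (is.null(names(term))) {
      X <- X + term * as.numeric(x)
    } else {
      b <- term[as.character(x)]
      if (anyNA(b)) {
        bad <- unique(as.character(x)[is.na(b)])
        stop_if_not(FALSE, "coefficient error: unmapped categor",
                    if (length(bad) > 1) "ies " else "y ",
                    paste(bad, collapse = ", "), " in field '", f, "'",
                    class = "proscore_coef_error")
      }
      X <- X + unname(b)
    }
  }
  stats::plogis(X)
}

#' Recode registry records for the UB-ROSC comparator
#'
#' Applies the documented recoding rules: arrest location `unknown` is
#' considered home, `industrial_area` is treated as workplace and
#' `transportation_center` as a public building; first rhythm collapses to
#' shockable/unshockable; and witness status with bystander CPR are fused
#' into a five-category feature (`ems_witnessed`, `not_witnessed_no_cpr`,
#' `not_witnessed_cpr`, `witnessed_no_cpr`, `witnessed_cpr`). A
#' professional (EMS) witness maps to `ems_witnessed` regardless of CPR
#' status.
#'
#' @param records data frame with `arrest_location`, `witnessed`,
#'   `bystander_cpr`, `first_rhythm` and `etiology` columns, non-missing.
#' @return the records with `arrest_location` and `first_rhythm` recoded and
#'   a new `witness_cpr` column.
#' @export
recode_for_ub_rosc <- function(records) {
  need <- c("arrest_location", "witnessed", "bystander_cpr", "first_rhythm",
            "etiology")
  for (f in need) {
    stop_if_not(f %in% names(records), "recode error: field '", f,
                "' absent", class = "proscore_recode_error")
    stop_if_not(!anyNA(records[[f]]), "recode error: missing values in '",
                f, "'", class = "proscore_recode_error")
  }
  loc <- records$arrest_location
  loc[loc == "unknown"] <- "home"
  loc[loc == "industrial_area"] <- "workplace"
  loc[loc == "transportation_center"] <- "public_building"
  records$arrest_location <- loc
  records$first_rhythm <- regroup_rhythm(records$first_rhythm)
  w <- records$witnessed
  cpr <- records$bystander_cpr
  records$witness_cpr <- ifelse(
    w == "professional", "ems_witnessed",
    ifelse(w == "none",
           ifelse(cpr == "yes", "not_witnessed_cpr", "not_witnessed_no_cpr"),
           ifelse(cpr == "yes", "witnessed_cpr", "witnessed_no_cpr")))
  records
}
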