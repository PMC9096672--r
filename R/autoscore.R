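# Score-derivation engine: variable ranking, parsimony curve, quantile
# binning, coefficient-to-points conversion.

#' Regroup the raw first arrest rhythm
#'
#' VF, VT and "unknown shockable" collapse to `shockable`; PEA, asystole and
#' "unknown unshockable" to `unshockable`. Already-regrouped values pass
#' through unchanged.
#'
#' @param first_rhythm_raw character vector of raw rhythm codes.
#' @return character vector over \{shockable, unshockable\}.
#' @export
regroup_rhythm <- function(first_rhythm_raw) {
  stop_if_not(!anyNA(first_rhythm_raw),
              "missing first rhythm must be excluded before regrouping")
  map <- c(vf = "shockable", vt = "shockable", unknown_shockable = "shockable",
           pea = "unshockable", asystole = "unshockable",
           unknown_unshockable = "unshockable",
           shockable = "shockable", unshockable = "unshockable")
  out <- map[as.character(first_rhythm_raw)]
  if (anyNA(out)) {
    bad <- unique(first_rhythm_raw[is.na(out)])
    stop_if_not(FALSE, "unknown rhythm value(s): ", paste(bad, collapse = ", "))
  }
  unname(out)
}

#' The candidate predictor set
#'
#' The thirteen pre-selected clinical candidate variables plus the community
#' index (included as a location identifier).
#'
#' @return character vector of column names.
#' @export
candidate_variables <- function() {
  c("age", "gender", "etiology", "witnessed", "arrest_location",
    "first_rhythm", "bystander_cpr", "bystander_aed", "response_time",
    "daytime_call", "prehospital_drug", "prehospital_defib",
    "advanced_airway", "community_id")
}

#' Rank candidate variables by random-forest importance
#'
#' Fits a random forest (100 trees by default, impurity importance, single
#' thread for reproducibility) of the binary outcome on the candidate
#' variables and returns them ordered by decreasing importance.
#'
#' @param records training data frame; candidate columns must be
#'   non-missing.
#' @param variables character vector of candidate column names.
#' @param num_trees number of trees.
#' @param seed integer RNG seed.
#' @param outcome name of the binary outcome column.
#' @return data frame of class `variable_ranking` with columns `variable`
#'   and `importance`, sorted by decreasing importance.
#' @export
rank_variables <- function(records, variables = candidate_variables(),
                           num_trees = 100, seed = 1L, outcome = "rosc") {
  stop_if_not(nrow(records) > 0, "empty training data")
  y <- as_binary_outcome(records[[outcome]])
  stop_if_not(length(unique(y)) == 2,
              "outcome must have both classes present")
  dat <- records[variables]
  for (v in variables) {
    stop_if_not(!anyNA(dat[[v]]), "candidate variable '", v,
                "' has missing values; filter the cohort first")
    if (!is.numeric(dat[[v]])) dat[[v]] <- factor(dat[[v]])
  }
  dat$.outcome <- factor(y, levels = c(0, 1))
  fit <- ranger::ranger(dependent.variable.name = ".outcome", data = dat,
                        num.trees = num_trees, importance = "impurity",
                        respect.unordered.factors = "order",
                        num.threads = 1, seed = seed)
  imp <- sort(fit$variable.importance, decreasing = TRUE)
  structure(data.frame(variable = names(imp), importance = unname(imp),
                       stringsAsFactors = FALSE),
            class = c("variable_ranking", "data.frame"))
}

#' Quantile cut points for a continuous variable
#'
#' Computes the requested sample quantiles (linear interpolation of order
#' statistics, `stats::quantile()` type 7), deduplicates them and returns a
#' strictly increasing cut vector. Downstream, intervals are lower-closed
#' and upper-open: a value equal to a cut belongs to the interval the cut
#' opens.
#'
#' @param values numeric vector with at least two distinct finite values.
#' @param probs quantile probabilities in (0,1); default quartiles.
#' @return numeric vector of strictly increasing cut points.
#' @export
bin_continuous <- function(values, probs = c(0.25, 0.5, 0.75)) {
  values <- values[is.finite(values)]
  stop_if_not(length(unique(values)) >= 2,
              "cannot bin a constant (or empty) variable")
  stop_if_not(all(probs > 0 & probs < 1), "probs must lie in (0,1)")
  cuts <- unique(unname(stats::quantile(values, sort(probs), type = 7)))
  cuts <- cuts[cuts > min(values)]  # keep the lowest interval non-empty
  stop_if_not(length(cuts) >= 1, "quantiles degenerate; cannot bin")
  cuts
}

# "<c1", "c1-c2", ..., ">=ck" interval labels (lower-closed, upper-open)
bin_labels <- function(cuts) {
  f <- format(cuts, trim = TRUE, digits = 7)
  if (length(cuts) == 1) return(c(paste0("<", f), paste0(">=", f)))
  c(paste0("<", f[1]),
    paste0(f[-length(f)], "-", f[-1]),
    paste0(">=", f[length(f)]))
}

# map numeric values to interval labels under q1 <= x < q2
categorize <- function(x, cuts) {
  labs <- bin_labels(cuts)
  factor(labs[findInterval(x, cuts) + 1L], levels = labs)
}

#' Convert logistic-regression coefficients to integer points
#'
#' Fits a multivariable logistic regression of the outcome on the selected
#' variables (continuous variables first categorised by `binning`,
#' categorical variables at their observed or supplied levels) and converts
#' the fitted log-odds to a point table: within each variable the
#' lowest-coefficient category becomes the 0-point reference, and every
#' other category receives `round(coefficient difference / s)` points, where
#' the scaling constant `s` is the smallest positive coefficient difference
#' across all variables (so the weakest effect in the model maps to 1
#' point). Rounding is half-away-from-zero.
#'
#' @param records training data frame.
#' @param variables character vector of predictor columns.
#' @param binning named list of cut vectors for the continuous predictors
#'   (see [bin_continuous()]); numeric variables not listed raise an error.
#' @param level_sets optional named list giving the category levels (and
#'   their order) to use for categorical predictors; defaults to sorted
#'   observed values.
#' @param outcome name of the binary outcome column.
#' @return a [score_table()] over the selected variables.
#' @export
derive_points <- function(records, variables, binning = NULL,
                          level_sets = NULL, outcome = "rosc") {
  y <- as_binary_outcome(records[[outcome]])
  stop_if_not(length(unique(y)) == 2, "outcome must have both classes present")
  dat <- data.frame(row.names = seq_along(y))
  cuts_of <- list()
  for (v in variables) {
    x <- records[[v]]
    stop_if_not(!is.null(x), "variable '", v, "' absent from records")
    stop_if_not(!anyNA(x), "variable '", v, "' has missing values")
    if (is.numeric(x) && !is.null(binning[[v]])) {
      dat[[v]] <- categorize(x, binning[[v]])
      cuts_of[[v]] <- binning[[v]]
    } else if (is.numeric(x)) {
      stop_if_not(FALSE, "no binning supplied for continuous variable '", v, "'")
    } else {
      lev <- level_sets[[v]] %||% sort(unique(as.character(x)))
      dat[[v]] <- factor(as.character(x), levels = lev)
    }
    if (any(table(dat[[v]]) == 0)) {
      empty <- names(which(table(dat[[v]]) == 0))
      warning("variable '", v, "': empty category level(s) dropped: ",
              paste(empty, collapse = ", "))
      dat[[v]] <- droplevels(dat[[v]])
    }
    stop_if_not(nlevels(dat[[v]]) >= 2,
                "variable '", v, "' has a single observed category")
  }
  dat$.y <- y
  fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial())
  cf <- stats::coef(fit)

  var_coefs <- list()
  for (v in variables) {
    lev <- levels(dat[[v]])
    beta <- c(0, cf[paste0(v, lev[-1])])
    names(beta) <- lev
    stop_if_not(all(is.finite(beta)),
                "fit error (singular fit) for variable '", v, "'",
                class = "proscore_fit_error")
    stop_if_not(all(abs(beta) < 15),
                "fit error (possible separation) for variable '", v, "'",
                class = "proscore_fit_error")
    var_coefs[[v]] <- beta - min(beta)  # lowest-risk category -> 0 reference
  }
  pos <- unlist(var_coefs, use.names = FALSE)
  pos <- pos[pos > 0]
  stop_if_not(length(pos) > 0, "all coefficients are zero; no score derivable",
              class = "proscore_fit_error")
  s <- min(pos)
  vars <- lapply(variables, function(v) {
    out <- list(levels = names(var_coefs[[v]]),
                points = round_half_away(var_coefs[[v]] / s))
    if (!is.null(cuts_of[[v]])) out$cuts <- cuts_of[[v]]
    out
  })
  names(vars) <- variables
  score_table(vars)
}

#' Parsimony curve over nested top-k variable sets
#'
#' For each k from 1 to the full ranking length, derives a point-based model
#' on the training set using the top-k ranked variables and records its AUC
#' on the validation set. The resulting curve is used to choose the model
#' size at which added variables stop paying for their complexity.
#'
#' @param train,validation data frames (complete cases for the candidates).
#' @param ranking a `variable_ranking` from [rank_variables()] (or a data
#'   frame with a `variable` column in rank order).
#' @param binning_probs quantile probabilities used to bin continuous
#'   variables on the training set.
#' @param outcome name of the binary outcome column.
#' @return data frame of class `parsimony_curve` with columns `k`,
#'   `variable` (the variable added at that k) and `auc`.
#' @export
build_parsimony <- function(train, validation, ranking,
                            binning_probs = c(0.25, 0.5, 0.75),
                            outcome = "rosc") {
  stop_if_not(nrow(train) > 0 && nrow(validation) > 0,
              "train and validation must be non-empty")
  vars_all <- ranking$variable
  aucs <- numeric(length(vars_all))
  for (k in seq_along(vars_all)) {
    vars <- vars_all[seq_len(k)]
    binning <- list()
    for (v in vars) {
      if (is.numeric(train[[v]])) binning[[v]] <- bin_continuous(train[[v]],
                                                                 binning_probs)
    }
    res <- tryCatch({
      tab <- derive_points(train, vars, binning = binning, outcome = outcome)
      sc <- apply_score_table(validation[vars], tab)
      auc_with_ci(sc, validation[[outcome]])$auc
    }, error = function(e) {
      stop_if_not(FALSE, "parsimony model at k=", k, " failed: ",
                  conditionMessage(e))
    })
    aucs[k] <- res
  }
  structure(data.frame(k = seq_along(vars_all), variable = vars_all,
                       auc = aucs, stringsAsFactors = FALSE),
            class = c("parsimony_curve", "data.frame"))
}

#' Sensitivity-analysis model: logistic regression without categorisation
#'
#' Fits a multivariable logistic regression on the same variables as a point
#' score but with continuous variables kept numeric and categorical
#' variables at their raw levels, then reports its AUC (with 95% CI) on the
#' test set.
#'
#' @param train,test data frames.
#' @param variables predictor columns.
#' @param outcome name of the binary outcome column.
#' @return an `auc_estimate` (see [auc_with_ci()]).
#' @export
fit_uncategorized_lr <- function(train, test, variables, outcome = "rosc") {
  y <- as_binary_outcome(train[[outcome]])
  stop_if_not(length(unique(y)) == 2, "outcome must have both classes present")
  dat <- train[variables]
  for (v in variables) {
    stop_if_not(!anyNA(dat[[v]]) && !anyNA(test[[v]]),
                "variable '", v, "' has missing values")
    if (!is.numeric(dat[[v]])) dat[[v]] <- factor(dat[[v]])
  }
  dat$.y <- y
  fit <- suppressWarnings(stats::glm(.y ~ ., data = dat,
                                     family = stats::binomial()))
  newdat <- test[variables]
  for (v in variables) {
    if (!is.numeric(newdat[[v]])) {
      newdat[[v]] <- factor(newdat[[v]], levels = levels(dat[[v]]))
    }
  }
  pred <- suppressWarnings(stats::predict(fit, newdata = newdat,
                                          type = "response"))
  auc_with_ci(pred, test[[outcome]])
}
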