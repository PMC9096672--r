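# Divide-and-combine: per-community score derivation, the AUC- and
# size-weighted aggregation, and the end-to-end weighted derivation wrapper.

#' Bundle one community's fitted score
#'
#' @param community_id identifier.
#' @param table the community's fitted [score_table()].
#' @param auc validation AUC of the community score, in (0,1].
#' @param n_train training sample size (positive integer).
#' @return object of class `community_score_set`.
#' @export
community_score_set <- function(community_id, table, auc, n_train) {
  validate_score_table(table)
  stop_if_not(auc > 0 && auc <= 1, "AUC must lie in (0,1]",
              class = "proscore_domain_error")
  stop_if_not(n_train >= 1 && n_train == round(n_train),
              "n_train must be a positive integer",
              class = "proscore_domain_error")
  structure(list(community_id = community_id, table = table,
                 auc = auc, n_train = n_train),
            class = "community_score_set")
}

#' Community weightages for score aggregation
#'
#' Computes, for community i, the weight
#' \deqn{w_i = \frac{AUC_i \cdot N_i^p}{\sum_j AUC_j \cdot N_j^p}}
#' where \eqn{AUC_i} is the community score's validation AUC, \eqn{N_i} its
#' training sample size and \eqn{p} the size exponent (default 3). With
#' \eqn{p = 3} the largest community dominates heavily; the exponent is kept
#' configurable so the sensitivity of the aggregate to this choice can be
#' examined. Weights are computed on size ratios, so a common rescaling of
#' all \eqn{N_i} (or all \eqn{AUC_i}) leaves them unchanged.
#'
#' @param sets list of [community_score_set()] objects, or a numeric vector
#'   of AUCs (in which case `n` must be supplied).
#' @param n numeric vector of training sizes (used when `sets` is numeric).
#' @param exponent the power p applied to the training size.
#' @return named numeric vector of weights summing to 1, of class
#'   `weight_vector`, with attributes `auc`, `n` and `exponent`.
#' @export
#' @examples
#' compute_weights(c(a = 0.8, b = 0.7), n = c(2000, 1000))
compute_weights <- function(sets, n = NULL, exponent = 3) {
  if (is.list(sets)) {
    auc <- vapply(sets, function(s) s$auc, numeric(1))
    n <- vapply(sets, function(s) s$n_train, numeric(1))
    names(auc) <- vapply(sets, function(s) as.character(s$community_id),
                         character(1))
  } else {
    auc <- sets
    stop_if_not(!is.null(n) && length(n) == length(auc),
                "n must accompany a numeric AUC vector",
                class = "proscore_domain_error")
  }
  stop_if_not(length(auc) >= 1, "need at least one community",
              class = "proscore_domain_error")
  stop_if_not(all(auc > 0), "all AUC values must be positive",
              class = "proscore_domain_error")
  stop_if_not(all(n >= 1), "all training sizes must be >= 1",
              class = "proscore_domain_error")
  # scale-free form: ratios to the largest community avoid overflow for any p
  raw <- auc * (n / max(n))^exponent
  w <- raw / sum(raw)
  names(w) <- names(auc)
  structure(w, auc = unname(auc), n = unname(n), exponent = exponent,
            class = c("weight_vector", "numeric"))
}

#' Aggregate per-community score tables by weighted average
#'
#' Each category's aggregated point value is the weighted average of the
#' per-community points, rounded half-away-from-zero; the aggregated table
#' is then rescaled with [normalize_table()] so its maximum equals
#' `target_max`. All tables must share an identical structure (same
#' variables, category labels and cut points); per-community tables that
#' are already normalised to `target_max` and identical are a fixed point.
#'
#' @param sets list of [community_score_set()] objects (or bare
#'   [score_table()]s).
#' @param weights a `weight_vector` aligned with `sets`.
#' @param target_max maximum of the aggregated score (default 100).
#' @return the aggregated, normalised [score_table()].
#' @export
aggregate_tables <- function(sets, weights, target_max = 100L) {
  tabs <- lapply(sets, function(s) if (inherits(s, "score_table")) s else s$table)
  stop_if_not(length(tabs) == length(weights),
              "weights not aligned with score sets")
  ref <- tabs[[1]]
  for (t in tabs[-1]) {
    stop_if_not(identical(names(t$variables), names(ref$variables)),
                "alignment error: tables disagree on variables: ",
                paste(union(setdiff(names(t$variables), names(ref$variables)),
                            setdiff(names(ref$variables), names(t$variables))),
                      collapse = ", "),
                class = "proscore_alignment_error")
    for (v in names(ref$variables)) {
      stop_if_not(identical(t$variables[[v]]$levels, ref$variables[[v]]$levels),
                  "alignment error: variable '", v,
                  "' has discrepant categories across communities",
                  class = "proscore_alignment_error")
    }
  }
  w <- as.numeric(weights)
  vars <- lapply(names(ref$variables), function(v) {
    pts <- sapply(tabs, function(t) t$variables[[v]]$points)  # levels x M
    if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
    out <- list(levels = ref$variables[[v]]$levels,
                points = round_half_away(as.numeric(pts %*% w)))
    if (!is.null(ref$variables[[v]]$cuts)) out$cuts <- ref$variables[[v]]$cuts
    out
  })
  names(vars) <- names(ref$variables)
  normalize_table(score_table(vars), target_max = target_max)
}

#' Derive a community-weighted point score end to end
#'
#' Runs the full divide-and-combine derivation on a split cohort: fits one
#' shared binning scheme for the continuous predictors on the pooled
#' training data (so all communities share one category structure), derives
#' a point table per community on that community's training records,
#' evaluates each table's AUC on the community's validation records, weights
#' the communities by [compute_weights()], and aggregates with
#' [aggregate_tables()] into a single table normalised to `target_max`.
#'
#' @param records cohort data frame (eligible, complete for `variables`).
#' @param split character vector from [temporal_stratified_split()].
#' @param variables the selected predictor columns.
#' @param binning optional named list of cut vectors overriding the fitted
#'   quantile binning (the human fine-tuning hook for cut-offs).
#' @param binning_probs quantile probabilities for the fitted binning.
#' @param exponent weight exponent p on the training size.
#' @param target_max maximum of the final score.
#' @param outcome name of the binary outcome column.
#' @return list of class `weighted_score_fit` with elements `table` (the
#'   aggregated [score_table()]), `communities` (list of
#'   [community_score_set()]), `weights` and `binning`.
#' @export
derive_weighted_score <- function(records, split, variables, binning = NULL,
                                  binning_probs = c(0.25, 0.5, 0.75),
                                  exponent = 3, target_max = 100L,
                                  outcome = "rosc") {
  stop_if_not(length(split) == nrow(records), "split not aligned with records")
  train <- records[split == "train", , drop = FALSE]
  val <- records[split == "validation", , drop = FALSE]
  if (is.null(binning)) {
    binning <- list()
    for (v in variables) {
      if (is.numeric(train[[v]])) {
        binning[[v]] <- bin_continuous(train[[v]], binning_probs)
      }
    }
  }
  # shared category structure: pooled level sets for categorical predictors
  level_sets <- list()
  for (v in variables) {
    if (!is.numeric(train[[v]])) {
      level_sets[[v]] <- sort(unique(as.character(train[[v]])))
    }
  }
  sets <- lapply(unique(train$community_id), function(comm) {
    tr <- train[train$community_id == comm, , drop = FALSE]
    va <- val[val$community_id == comm, , drop = FALSE]
    tab <- derive_points(tr, variables, binning = binning,
                         level_sets = level_sets, outcome = outcome)
    auc <- auc_with_ci(apply_score_table(va[variables], tab),
                       va[[outcome]])$auc
    community_score_set(comm, tab, auc, nrow(tr))
  })
  weights <- compute_weights(sets, exponent = exponent)
  table <- aggregate_tables(sets, weights, target_max = target_max)
  structure(list(table = table, communities = sets, weights = weights,
                 binning = binning),
            class = "weighted_score_fit")
}
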