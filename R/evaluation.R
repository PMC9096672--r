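# Discrimination analysis and cohort description.

#' AUC with a DeLong 95% confidence interval
#'
#' The AUC is the Mann-Whitney two-sample statistic divided by the number of
#' positive-negative pairs, with ties counted one half; the confidence
#' interval uses the DeLong variance estimate.
#'
#' @param scores numeric scores (higher means more likely positive).
#' @param outcomes binary outcome vector aligned with `scores`.
#' @param conf confidence level.
#' @return list of class `auc_estimate`: `auc`, `ci_lo`, `ci_hi`, `n_pos`,
#'   `n_neg`.
#' @export
auc_with_ci <- function(scores, outcomes, conf = 0.95) {
  y <- as_binary_outcome(outcomes)
  stop_if_not(!anyNA(y) && !anyNA(scores), "scores and outcomes must be complete")
  stop_if_not(length(unique(y)) == 2, "both outcome classes must be present")
  r <- pROC::roc(response = y, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- suppressWarnings(pROC::ci.auc(r, conf.level = conf, method = "delong"))
  structure(list(auc = as.numeric(pROC::auc(r)),
                 ci_lo = as.numeric(ci[1]), ci_hi = as.numeric(ci[3]),
                 n_pos = sum(y == 1), n_neg = sum(y == 0)),
            class = "auc_estimate")
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f; %d positive / %d negative)\n",
              x$auc, x$ci_lo, x$ci_hi, x$n_pos, x$n_neg))
  invisible(x)
}

#' Paired DeLong comparison of two correlated AUCs
#'
#' Both score vectors must be computed on the same records (same outcome
#' vector); the test accounts for the correlation between the two ROC
#' curves.
#'
#' @param scores_a,scores_b numeric score vectors on the same records.
#' @param outcomes shared binary outcome vector.
#' @return list: `auc_a`, `auc_b`, `diff` (= auc_a - auc_b), `p_value`.
#' @export
delong_compare <- function(scores_a, scores_b, outcomes) {
  stop_if_not(length(scores_a) == length(scores_b) &&
                length(scores_a) == length(outcomes),
              "score vectors and outcomes must have equal length")
  y <- as_binary_outcome(outcomes)
  ra <- pROC::roc(y, as.numeric(scores_a), levels = c(0, 1), direction = "<",
                  quiet = TRUE)
  rb <- pROC::roc(y, as.numeric(scores_b), levels = c(0, 1), direction = "<",
                  quiet = TRUE)
  tst <- suppressWarnings(pROC::roc.test(ra, rb, method = "delong",
                                         paired = TRUE))
  d <- as.numeric(pROC::auc(ra)) - as.numeric(pROC::auc(rb))
  p <- tst$p.value
  if (is.nan(p) && isTRUE(all.equal(d, 0))) p <- 1  # identical curves
  list(auc_a = as.numeric(pROC::auc(ra)), auc_b = as.numeric(pROC::auc(rb)),
       diff = d, p_value = p)
}

#' Pairwise evaluation report for several scorers
#'
#' Computes each scorer's AUC with CI and all pairwise DeLong comparisons on
#' a common test set.
#'
#' @param scores named list of numeric score vectors on the same records.
#' @param outcomes shared binary outcome vector.
#' @return list of class `eval_report`: `auc` (data frame per scorer) and
#'   `pairwise` (data frame of differences and p-values).
#' @export
evaluate_scorers <- function(scores, outcomes) {
  stop_if_not(is.list(scores) && length(scores) >= 1 && !is.null(names(scores)),
              "'scores' must be a non-empty named list")
  aucs <- do.call(rbind, lapply(names(scores), function(nm) {
    a <- auc_with_ci(scores[[nm]], outcomes)
    data.frame(scorer = nm, auc = a$auc, ci_lo = a$ci_lo, ci_hi = a$ci_hi,
               stringsAsFactors = FALSE)
  }))
  pair <- NULL
  nms <- names(scores)
  if (length(nms) >= 2) {
    combs <- utils::combn(nms, 2)
    pair <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
      a <- combs[1, i]; b <- combs[2, i]
      cmp <- delong_compare(scores[[a]], scores[[b]], outcomes)
      data.frame(scorer_a = a, scorer_b = b, diff = cmp$diff,
                 p_value = cmp$p_value, stringsAsFactors = FALSE)
    }))
  }
  structure(list(auc = aucs, pairwise = pair), class = "eval_report")
}

#' Mean score by outcome group
#'
#' @param scores numeric scores.
#' @param outcomes binary outcome vector.
#' @return named numeric vector `c(rosc = , no_rosc = )`; an absent group
#'   yields `NA` with a warning.
#' @export
mean_score_by_outcome <- function(scores, outcomes) {
  y <- as_binary_outcome(outcomes)
  out <- c(rosc = if (any(y == 1)) mean(scores[y == 1]) else NA_real_,
           no_rosc = if (any(y == 0)) mean(scores[y == 0]) else NA_real_)
  if (anyNA(out)) warning("one outcome group is absent; partial result")
  out
}

#' Descriptive cohort summary by outcome group
#'
#' Produces a study-table-style description: continuous variables are
#' summarised as median [IQR] and mean (SD) per outcome group with a
#' Mann-Whitney U p-value and a Kolmogorov-Smirnov normality check (against
#' a normal with the sample moments); categorical variables as counts and
#' percentages per group with a chi-square p-value (no continuity
#' correction). Degenerate comparisons (a single group or a single level)
#' report `NA` p-values.
#'
#' @param records data frame.
#' @param variables columns to describe; defaults to the candidate variables
#'   present in `records`.
#' @param outcome name of the binary outcome column.
#' @return list of class `descriptive_summary` with data frames
#'   `continuous` and `categorical`.
#' @export
describe_cohort <- function(records, variables = NULL, outcome = "rosc") {
  stop_if_not(nrow(records) > 0, "empty cohort")
  y <- as_binary_outcome(records[[outcome]])
  stop_if_not(!anyNA(y), "outcome must be non-missing")
  variables <- variables %||%
    setdiff(intersect(candidate_variables(), names(records)), "community_id")
  cont <- list(); cate <- list()
  for (v in variables) {
    x <- records[[v]]
    if (is.numeric(x)) {
      grp <- function(g) x[y == g & !is.na(x)]
      x1 <- grp(1); x0 <- grp(0)
      p <- if (length(x1) && length(x0)) {
        suppressWarnings(stats::wilcox.test(x1, x0)$p.value)
      } else NA_real_
      xx <- x[!is.na(x)]
      norm_p <- if (length(xx) >= 5 && stats::sd(xx) > 0) {
        suppressWarnings(stats::ks.test(xx, "pnorm", mean(xx),
                                        stats::sd(xx))$p.value)
      } else NA_real_
      cont[[v]] <- data.frame(
        variable = v,
        median_pos = stats::median(x1), q1_pos = unname(stats::quantile(x1, .25)),
        q3_pos = unname(stats::quantile(x1, .75)),
        mean_pos = mean(x1), sd_pos = stats::sd(x1),
        median_neg = stats::median(x0), q1_neg = unname(stats::quantile(x0, .25)),
        q3_neg = unname(stats::quantile(x0, .75)),
        mean_neg = mean(x0), sd_neg = stats::sd(x0),
        p_value = p, normality_p = norm_p, stringsAsFactors = FALSE)
    } else {
      keep <- !is.na(x)
      tab <- table(x[keep], y[keep])
      p <- if (nrow(tab) >= 2 && ncol(tab) >= 2) {
        suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      } else NA_real_
      n1 <- if ("1" %in% colnames(tab)) tab[, "1"] else rep(0L, nrow(tab))
      n0 <- if ("0" %in% colnames(tab)) tab[, "0"] else rep(0L, nrow(tab))
      cate[[v]] <- data.frame(
        variable = v, level = rownames(tab),
        n_pos = as.integer(n1),
        pct_pos = 100 * as.integer(n1) / max(1, sum(n1)),
        n_neg = as.integer(n0),
        pct_neg = 100 * as.integer(n0) / max(1, sum(n0)),
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  structure(list(continuous = if (length(cont)) do.call(rbind, cont),
                 categorical = if (length(cate)) do.call(rbind, cate)),
            class = "descriptive_summary")
}
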