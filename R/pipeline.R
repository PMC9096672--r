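# Cohort eligibility, missing-data policy and temporal splitting.

# Fields checked by the complete-case rule. Arrest location and bystander
# AED are exempt: their missingness is structural (whole source registries
# did not record them) and is recoded to an explicit "unknown" category
# instead of dropping the record.
complete_case_fields <- function() {
  c("age", "response_time", "first_rhythm", "witnessed", "prehospital_drug",
    "gender", "etiology", "bystander_cpr", "daytime_call",
    "prehospital_defib", "advanced_airway")
}

#' Apply study eligibility filters
#'
#' Filters a parsed cohort with the derivation study's rules, applied in a
#' fixed sequential order with each excluded record attributed to the first
#' rule it fails: resuscitation not attempted (pronounced dead in the
#' field), not conveyed by EMS, DNR order, missing outcome, missing age,
#' pediatric (age < 18), incomplete non-designated fields, and finally
#' communities left with fewer than `min_community_size` records. Arrest
#' location and bystander AED never trigger the complete-case rule (see
#' [encode_missing_as_unknown()]).
#'
#' @param records cohort data frame.
#' @param min_community_size integer; communities smaller than this after
#'   the record-level filters are dropped entirely (study value: 1000).
#' @return list with `records` (eligible rows) and `tally`, a named integer
#'   vector of exclusion counts per reason plus `retained`; the tally always
#'   reconciles exactly with the input size.
#' @export
apply_exclusions <- function(records, min_community_size = 1000L) {
  stop_if_not(is.data.frame(records), "'records' must be a data frame")
  stop_if_not(min_community_size >= 1, "min_community_size must be >= 1")
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  flag <- function(cond, label) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- label
  }
  if (n > 0) {
    flag(!(records$resuscitation_attempted %||% TRUE), "no_resuscitation")
    flag(!(records$conveyed_by_ems %||% TRUE), "not_conveyed")
    flag(records$dnr_order %||% FALSE, "dnr_order")
    flag(is.na(records$rosc), "missing_outcome")
    flag(is.na(records$age), "no_age")
    flag(records$age < 18, "pediatric")
    cc <- intersect(complete_case_fields(), names(records))
    if (length(cc)) {
      incomplete <- Reduce(`|`, lapply(records[cc], is.na))
      flag(incomplete, "incomplete_fields")
    }
    keep <- is.na(reason)
    small <- names(which(table(records$community_id[keep]) < min_community_size))
    flag(keep & records$community_id %in% small, "small_community")
  }
  labels <- c("no_resuscitation", "not_conveyed", "dnr_order",
              "missing_outcome", "no_age", "pediatric", "incomplete_fields",
              "small_community")
  tally <- vapply(labels, function(l) sum(reason == l, na.rm = TRUE), integer(1))
  tally <- c(tally, retained = sum(is.na(reason)))
  out <- records[is.na(reason), , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, tally = tally)
}

#' Recode structurally missing fields to an explicit unknown category
#'
#' Missing arrest location and missing bystander-AED status are rewritten to
#' the `"unknown"` category so the information that the field was not
#' recorded is kept as a modelling category rather than causing the record
#' to be dropped. All other fields are untouched.
#'
#' @param records cohort data frame.
#' @return the records with the two designated fields recoded.
#' @export
encode_missing_as_unknown <- function(records) {
  for (f in c("arrest_location", "bystander_aed")) {
    if (f %in% names(records)) {
      records[[f]][is.na(records[[f]])] <- "unknown"
    }
  }
  records
}

#' Standard cohort preparation for score derivation
#'
#' Convenience wrapper chaining the study's data policy: recode structurally
#' missing location/AED to "unknown", apply the eligibility filters, and
#' regroup the first rhythm to shockable/unshockable.
#'
#' @inheritParams apply_exclusions
#' @return list with `records` (analysis-ready rows) and `tally`.
#' @export
prepare_cohort <- function(records, min_community_size = 1000L) {
  records <- encode_missing_as_unknown(records)
  ex <- apply_exclusions(records, min_community_size = min_community_size)
  ex$records$first_rhythm <- regroup_rhythm(ex$records$first_rhythm)
  ex
}

#' Temporal test split with outcome-stratified train/validation split
#'
#' Within each community the most recent `fractions[3]` of records (by event
#' time, ties broken by record id) form the test set; the remainder is split
#' into training and validation in ratio `fractions[1] : fractions[2]`,
#' stratified by outcome so both sets see a similar ROSC prevalence. The
#' temporal part is seed-free; only the train/validation shuffle uses the
#' seed.
#'
#' @param records cohort data frame; `event_time` and `rosc` must be
#'   non-missing.
#' @param fractions numeric length 3 summing to 1 (train, validation, test).
#' @param seed integer RNG seed for the stratified shuffle.
#' @return character vector (`"train"`, `"validation"`, `"test"`), one per
#'   record, in input order.
#' @export
temporal_stratified_split <- function(records, fractions = c(0.7, 0.1, 0.2),
                                      seed = 1L) {
  stop_if_not(is.data.frame(records) && nrow(records) > 0, "empty cohort")
  stop_if_not(length(fractions) == 3 && all(fractions > 0) &&
                abs(sum(fractions) - 1) < 1e-8,
              "fractions must be three positive numbers summing to 1")
  stop_if_not(!anyNA(records$event_time) && !anyNA(records$rosc),
              "event_time and outcome must be non-missing before splitting")
  assignment <- rep(NA_character_, nrow(records))
  ids <- records$record_id %||% as.character(seq_len(nrow(records)))
  with_seed(seed, {
    for (comm in unique(records$community_id)) {
      idx <- which(records$community_id == comm)
      stop_if_not(length(idx) >= 5, "split error: community '", comm,
                  "' has fewer than 5 records", class = "proscore_split_error")
      n_test <- round(fractions[3] * length(idx))
      ord <- idx[order(records$event_time[idx], ids[idx])]
      test_idx <- utils::tail(ord, n_test)
      rest <- setdiff(ord, test_idx)
      assignment[test_idx] <- "test"
      # stratified train/validation split of the remainder
      p_val <- fractions[2] / (fractions[1] + fractions[2])
      for (lev in unique(records$rosc[rest])) {
        stratum <- rest[records$rosc[rest] == lev]
        stratum <- stratum[sample.int(length(stratum))]
        n_val <- round(p_val * length(stratum))
        assignment[utils::head(stratum, n_val)] <- "validation"
        assignment[setdiff(stratum, utils::head(stratum, n_val))] <- "train"
      }
    }
  })
  assignment
}
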