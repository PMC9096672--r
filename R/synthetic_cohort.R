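# Synthetic multi-community cardiac-arrest registry.
#
# The real registry behind prehospital-ROSC scores is access-restricted, so
# every downstream stage of this package is exercised against simulated
# cohorts with the same statistical structure: several communities of very
# different sizes, a rare binary ROSC outcome driven by a logistic-additive
# model, realistic marginals for the candidate predictors, event timestamps
# for the temporal test split, and injected missingness.

#' Declared category sets for registry fields
#'
#' @return named list of character vectors: the legal values for every
#'   enumerated field of a patient record. Missing values are `NA` in memory
#'   and empty cells in CSV.
#' @export
cohort_enums <- function() {
  list(
    first_rhythm = c("vf", "vt", "unknown_shockable",
                     "pea", "asystole", "unknown_unshockable"),
    witnessed = c("none", "professional", "layperson"),
    prehospital_drug = c("yes", "no"),
    gender = c("male", "female"),
    etiology = c("cardiac", "trauma", "other"),
    arrest_location = c("home", "street", "workplace", "public_building",
                        "industrial_area", "transportation_center",
                        "nursing_home", "unknown"),
    bystander_cpr = c("yes", "no"),
    bystander_aed = c("yes", "no", "unknown"),
    daytime_call = c("yes", "no"),
    prehospital_defib = c("yes", "no"),
    advanced_airway = c("yes", "no"),
    rosc = c("yes", "no")
  )
}

#' Published community case counts
#'
#' The community sizes and ROSC count of the derivation cohort reported for
#' the P-ROSC score: 130,370 cases from Japan, 14,388 from South Korea,
#' 12,067 from Taiwan and 13,853 from Singapore, of which 14,104 attained
#' prehospital ROSC. The default simulated community sizes are these counts
#' scaled down by a factor of ten.
#'
#' @return list with elements `communities` (named integer vector of included
#'   cases per community), `total` (their sum) and `rosc` (number of cases
#'   with prehospital ROSC).
#' @export
published_cohort_counts <- function() {
  list(
    communities = c(japan = 130370L, south_korea = 14388L,
                    taiwan = 12067L, singapore = 13853L),
    total = 170678L,
    rosc = 14104L
  )
}

default_marginals <- function() {
  list(
    age = list(mean = 72, sd = 17, max = 110, pediatric = 0.017),
    response_time = list(meanlog = log(6.3), sdlog = 0.45),
    first_rhythm = c(vf = 0.070, vt = 0.010, unknown_shockable = 0.013,
                     pea = 0.250, asystole = 0.550, unknown_unshockable = 0.107),
    witnessed = c(none = 0.572, professional = 0.071, layperson = 0.357),
    prehospital_drug = c(yes = 0.123, no = 0.877),
    gender = c(male = 0.60, female = 0.40),
    etiology = c(cardiac = 0.85, trauma = 0.05, other = 0.10),
    arrest_location = c(home = 0.65, street = 0.10, workplace = 0.05,
                        public_building = 0.08, industrial_area = 0.02,
                        transportation_center = 0.03, nursing_home = 0.07,
                        unknown = 0.0),
    bystander_cpr = c(yes = 0.45, no = 0.55),
    bystander_aed = c(yes = 0.02, no = 0.98, unknown = 0.0),
    daytime_call = c(yes = 0.65, no = 0.35),
    prehospital_defib = c(yes = 0.25, no = 0.75),
    advanced_airway = c(yes = 0.40, no = 0.60)
  )
}

default_missingness <- function() {
  list(
    rates = c(age = 0.005, response_time = 0.010, first_rhythm = 0.065,
              witnessed = 0.010, prehospital_drug = 0.010, gender = 0.005,
              etiology = 0.020, arrest_location = 0.100, bystander_cpr = 0.010,
              bystander_aed = 0.050, daytime_call = 0.005,
              prehospital_defib = 0.010, advanced_airway = 0.010,
              rosc = 0.044),
    by_community = list(JP = c(arrest_location = 0.70),
                        TW = c(bystander_aed = 0.99))
  )
}

#' Default outcome effects: a point-model truth
#'
#' The default generative model places the log-odds of prehospital ROSC at a
#' community-calibrated intercept plus `per_point` times an additive point
#' score with the published P-ROSC structure (age and response time as step
#' functions, shockable rhythm, witness status, prehospital drug). All other
#' candidate variables carry zero effect. With the default
#' `per_point = 0.075` the true score discriminates at an AUC near 0.8,
#' the regime reported for prehospital-ROSC scores.
#'
#' @param per_point log-odds increment per score point.
#' @return named list of effect specifications (see [cohort_config()]).
#' @export
default_effects <- function(per_point = 0.075) {
  list(
    age = list(cuts = c(60, 85, 90), values = per_point * c(13, 10, 7, 0)),
    response_time = list(cuts = c(5, 9, 12), values = per_point * c(9, 7, 3, 0)),
    first_rhythm = per_point * c(vf = 30, vt = 30, unknown_shockable = 30,
                                 pea = 0, asystole = 0, unknown_unshockable = 0),
    witnessed = per_point * c(none = 0, professional = 27, layperson = 19),
    prehospital_drug = per_point * c(yes = 21, no = 0)
  )
}

#' Configure a synthetic registry simulation
#'
#' @param communities data frame with columns `id`, `n` (records to draw) and
#'   `base_rate` (target marginal ROSC prevalence). Defaults: four
#'   communities sized proportionally to the published cohort (13,037 /
#'   1,439 / 1,207 / 1,385, total 17,068), with prevalences 8.8%, 7.0%,
#'   4.6% and 8.0% so the Japanese-like community has roughly twice the
#'   ROSC rate of the Taiwanese-like one and the overall rate sits near
#'   8.26%.
#' @param effects named list of per-variable contributions to the ROSC
#'   log-odds. Each element is either a single numeric (linear effect of a
#'   numeric field), a named numeric vector (per-category offsets of an
#'   enumerated field), or `list(cuts=, values=)` (step function of a
#'   numeric field, intervals lower-closed/upper-open). Fields not listed
#'   carry no effect.
#' @param marginals named list of sampling distributions per field (see
#'   `default_marginals()`); categorical entries are probability vectors
#'   over the field's categories.
#' @param marginal_overrides optional list keyed by community id of marginal
#'   entries replacing the shared ones for that community. The default makes
#'   prehospital drug administration common in the Singapore-like community
#'   (50%) and rare in the Korean-like one (3%).
#' @param missingness list with `rates` (named per-field missing
#'   probabilities) and optional `by_community` overrides. Defaults give the
#'   Japanese-like community 70% missing arrest location and the
#'   Taiwanese-like community 99% missing bystander-AED status, mirroring
#'   fields the source registries did not record.
#' @param not_conveyed_rate,dnr_rate,no_resuscitation_rate rates of records
#'   flagged as not conveyed by EMS, under a do-not-resuscitate order, or
#'   pronounced dead without attempted resuscitation.
#' @param date_range two timestamps; event times are uniform between them.
#' @param seed integer; fully determines the generated cohort.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(communities = data.frame(
                            id = c("JP", "KR", "TW", "SG"),
                            n = c(13037L, 1439L, 1207L, 1385L),
                            base_rate = c(0.088, 0.070, 0.046, 0.080),
                            stringsAsFactors = FALSE),
                          effects = default_effects(),
                          marginals = default_marginals(),
                          marginal_overrides = list(
                            SG = list(prehospital_drug = c(yes = 0.50, no = 0.50)),
                            KR = list(prehospital_drug = c(yes = 0.03, no = 0.97))),
                          missingness = default_missingness(),
                          not_conveyed_rate = 0.016,
                          dnr_rate = 0.002,
                          no_resuscitation_rate = 0.031,
                          date_range = as.POSIXct(c("2009-01-01", "2018-06-17"),
                                                  tz = "UTC"),
                          seed = 1L) {
  stop_if_not(is.data.frame(communities) &&
                all(c("id", "n", "base_rate") %in% names(communities)),
              "communities must have columns id, n, base_rate",
              class = "proscore_config_error")
  stop_if_not(all(communities$n == round(communities$n)) &&
                all(communities$n >= 1),
              "community sizes must be positive integers",
              class = "proscore_config_error")
  stop_if_not(all(communities$base_rate > 0 & communities$base_rate < 1),
              "base rates must lie in (0,1)", class = "proscore_config_error")
  rates <- c(missingness$rates, not_conveyed_rate, dnr_rate,
             no_resuscitation_rate,
             unlist(missingness$by_community, use.names = FALSE))
  stop_if_not(all(rates >= 0 & rates <= 1), "rates must lie in [0,1]",
              class = "proscore_config_error")
  stop_if_not(length(date_range) == 2 && date_range[1] < date_range[2],
              "invalid date range", class = "proscore_config_error")
  structure(list(communities = communities, effects = effects,
                 marginals = marginals, marginal_overrides = marginal_overrides,
                 missingness = missingness,
                 not_conveyed_rate = not_conveyed_rate, dnr_rate = dnr_rate,
                 no_resuscitation_rate = no_resuscitation_rate,
                 date_range = as.POSIXct(date_range, tz = "UTC"), seed = seed),
            class = "cohort_config")
}

sample_categorical <- function(n, probs, levels) {
  probs <- probs[levels]
  probs[is.na(probs)] <- 0
  sample(levels, n, replace = TRUE, prob = probs / sum(probs))
}

# log-odds contribution of one field under one effect specification
effect_contribution <- function(x, eff) {
  if (is.list(eff)) {
    idx <- findInterval(x, eff$cuts) + 1L
    return(eff$values[idx])
  }
  if (length(eff) == 1 && is.null(names(eff))) return(eff * x)
  out <- eff[as.character(x)]
  out[is.na(out)] <- 0
  unname(out)
}

#' Generate a synthetic registry cohort
#'
#' Draws, per community, the candidate predictor fields from the configured
#' marginals, computes each record's ROSC log-odds as a community intercept
#' plus the configured additive effects, calibrates the intercept so the
#' marginal prevalence matches the community's `base_rate`, draws the
#' outcome, then injects missingness field by field. Eligibility flags
#' (conveyed by EMS, DNR order, resuscitation attempted) and uniform event
#' timestamps are attached so the exclusion and temporal-split stages have
#' realistic input.
#'
#' @param config a [cohort_config()].
#' @return data frame with one row per arrest and a `record_id` column;
#'   missing values are `NA`.
#' @export
#' @examples
#' cfg <- cohort_config(communities = data.frame(id = "A", n = 500,
#'                                               base_rate = 0.08), seed = 7)
#' coh <- generate_cohort(cfg)
#' mean(coh$rosc == "yes", na.rm = TRUE)
generate_cohort <- function(config) {
  stop_if_not(inherits(config, "cohort_config"), "config must be a cohort_config",
              class = "proscore_config_error")
  enums <- cohort_enums()
  with_seed(config$seed, {
    out <- lapply(seq_len(nrow(config$communities)), function(ci) {
      id <- config$communities$id[ci]
      n <- config$communities$n[ci]
      base_rate <- config$communities$base_rate[ci]
      marg <- config$marginals
      over <- config$marginal_overrides[[id]]
      if (!is.null(over)) marg[names(over)] <- over

      a <- marg$age
      ped <- stats::runif(n) < (a$pediatric %||% 0)
      age <- ifelse(ped,
                    floor(stats::runif(n, 0, 18)),
                    round(pmin(a$max %||% 110,
                               pmax(18, stats::rnorm(n, a$mean, a$sd)))))
      rt <- round(stats::rlnorm(n, marg$response_time$meanlog,
                                marg$response_time$sdlog), 1)
      rec <- data.frame(
        record_id = sprintf("%s-%06d", id, seq_len(n)),
        community_id = id,
        age = as.integer(age),
        response_time = rt,
        stringsAsFactors = FALSE
      )
      for (f in names(enums)) {
        if (f == "rosc") next
        rec[[f]] <- sample_categorical(n, marg[[f]], enums[[f]])
      }

      eta <- numeric(n)
      for (f in names(config$effects)) {
        stop_if_not(f %in% names(rec), "effect refers to unknown field '", f, "'",
                    class = "proscore_config_error")
        eta <- eta + effect_contribution(rec[[f]], config$effects[[f]])
      }
      # calibrate the community intercept to the target marginal prevalence
      alpha <- if (all(eta == 0)) {
        stats::qlogis(base_rate)
      } else {
        stats::uniroot(function(a) mean(stats::plogis(a + eta)) - base_rate,
                       interval = c(-40, 40))$root
      }
      rec$rosc <- ifelse(stats::rbinom(n, 1, stats::plogis(alpha + eta)) == 1,
                         "yes", "no")

      rec$conveyed_by_ems <- stats::runif(n) >= config$not_conveyed_rate
      rec$dnr_order <- stats::runif(n) < config$dnr_rate
      rec$resuscitation_attempted <- stats::runif(n) >= config$no_resuscitation_rate
      t0 <- as.numeric(config$date_range[1])
      t1 <- as.numeric(config$date_range[2])
      rec$event_time <- as.POSIXct(floor(stats::runif(n, t0, t1)),
                                   origin = "1970-01-01", tz = "UTC")

      miss <- config$missingness$rates
      over_m <- config$missingness$by_community[[id]]
      if (!is.null(over_m)) miss[names(over_m)] <- over_m
      for (f in names(miss)) {
        if (!f %in% names(rec)) next
        rec[[f]][stats::runif(n) < miss[[f]]] <- NA
      }
      rec
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

#' Write or read a cohort CSV
#'
#' The on-disk form is a plain CSV with one row per arrest; missing cells are
#' written as empty strings and event times as UTC ISO-8601 timestamps.
#'
#' @param records cohort data frame as produced by [generate_cohort()].
#' @param path file path.
#' @export
write_cohort <- function(records, path) {
  out <- records
  out$event_time <- format(records$event_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort CSV with enum validation
#'
#' Parses a delimited cohort file back into typed records. Cells that cannot
#' be parsed under a field's declared type or category set become the missing
#' state (`NA`), and a parse report counts, per field, how many non-empty
#' cells were coerced to missing.
#'
#' @param path CSV file with a header row.
#' @param schema optional named character vector mapping package field names
#'   to the file's column names (for files with different headers).
#' @return list with `records` (typed data frame) and `parse_report` (named
#'   integer vector of coerced-cell counts per field).
#' @export
ingest_cohort <- function(path, schema = NULL) {
  stop_if_not(file.exists(path), "file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL)
  if (!is.null(schema)) {
    hit <- match(unname(schema), names(raw))
    stop_if_not(!anyNA(hit), "schema error: mapped columns absent from file",
                class = "proscore_schema_error")
    names(raw)[hit] <- names(schema)
  }
  mandatory <- c("age", "community_id", "rosc", "event_time")
  missing_cols <- setdiff(mandatory, names(raw))
  stop_if_not(length(missing_cols) == 0,
              "schema error: mandatory column(s) absent: ",
              paste(missing_cols, collapse = ", "),
              class = "proscore_schema_error")

  report <- integer(0)
  coerce <- function(x, f) {
    x[!nzchar(x)] <- NA
    n_in <- sum(!is.na(x))
    y <- f(x)
    report[length(report) + 1L] <<- n_in - sum(!is.na(y))
    names(report)[length(report)] <<- col
    y
  }
  enums <- cohort_enums()
  rec <- raw
  for (col in names(raw)) {
    x <- raw[[col]]
    rec[[col]] <- if (col == "age") {
      coerce(x, function(v) suppressWarnings(as.integer(v)))
    } else if (col == "response_time") {
      coerce(x, function(v) suppressWarnings(as.numeric(v)))
    } else if (col == "event_time") {
      coerce(x, function(v) as.POSIXct(v, format = "%Y-%m-%dT%H:%M:%SZ",
                                       tz = "UTC"))
    } else if (col %in% names(enums)) {
      coerce(x, function(v) ifelse(v %in% enums[[col]], v, NA))
    } else if (col %in% c("conveyed_by_ems", "dnr_order",
                          "resuscitation_attempted")) {
      coerce(x, function(v) as.logical(v))
    } else {
      x[!nzchar(x)] <- NA
      x
    }
  }
  neg_age <- !is.na(rec$age) & rec$age < 0
  if (any(neg_age)) {
    rec$age[neg_age] <- NA
    report["age"] <- report["age"] + sum(neg_age)
  }
  list(records = rec, parse_report = report)
}
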