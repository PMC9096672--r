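# Independent oracles and small fixture builders used across test files.

# Brute-force AUC: enumerate every positive x negative pair, ties count 1/2.
oracle_auc <- function(scores, outcomes) {
  y <- as.integer(outcomes)
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Rank-based AUC (Mann-Whitney identity), fast enough for permutation loops.
fast_auc <- function(scores, y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# A single-community cohort config with given effects, no missingness and no
# ineligibility, for clean calibration checks.
clean_config <- function(n, base_rate = 0.0826, effects = list(), seed = 1L) {
  cohort_config(
    communities = data.frame(id = "A", n = as.integer(n),
                             base_rate = base_rate, stringsAsFactors = FALSE),
    effects = effects,
    marginal_overrides = list(),
    missingness = list(rates = numeric(0), by_community = list()),
    not_conveyed_rate = 0, dnr_rate = 0, no_resuscitation_rate = 0,
    seed = seed
  )
}

# Hand-built ten-record cohort: one pediatric, one DNR, one not conveyed,
# one missing outcome, six clean.
toy_exclusion_cohort <- function() {
  n <- 10
  rec <- data.frame(
    record_id = sprintf("T-%02d", 1:n),
    community_id = "T",
    age = c(17L, rep(60L, 9)),
    response_time = rep(6, n),
    first_rhythm = rep("asystole", n),
    witnessed = rep("none", n),
    prehospital_drug = rep("no", n),
    gender = rep("male", n),
    etiology = rep("cardiac", n),
    arrest_location = rep("home", n),
    bystander_cpr = rep("no", n),
    bystander_aed = rep("no", n),
    daytime_call = rep("yes", n),
    prehospital_defib = rep("no", n),
    advanced_airway = rep("no", n),
    rosc = c(rep("no", 9), NA),
    conveyed_by_ems = c(TRUE, TRUE, FALSE, rep(TRUE, 7)),
    dnr_order = c(FALSE, TRUE, rep(FALSE, 8)),
    resuscitation_attempted = rep(TRUE, n),
    event_time = as.POSIXct("2015-01-01", tz = "UTC") + 86400 * (1:n),
    stringsAsFactors = FALSE
  )
  rec
}
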