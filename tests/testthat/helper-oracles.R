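# Independent oracles and small fixture builders shared across tests.

# Brute-force restatement of the three classification rules, written
# directly from their prose definitions and kept independent of
# classify_cohort()'s vectorized implementation.
oracle_classify <- function(bc_status, dates) {
  n <- length(dates)
  crit1 <- identical(bc_status, "confirmed")
  crit2 <- bc_status %in% c("pending", "ds") && n >= 2
  crit3 <- FALSE
  if (n >= 3) {
    span <- as.numeric(max(dates) - min(dates))
    crit3 <- span >= 30
  }
  list(criterion1 = crit1, criterion2 = crit2, criterion3 = crit3,
       algorithm_ds = crit1 || crit2 || crit3,
       suspected = bc_status != "none" || n >= 1)
}

# Wilson bound by numeric inversion of the score test
# |phat - p| / sqrt(p (1 - p) / n) = z, independent of the closed form.
wilson_oracle <- function(x, n, level = 0.95) {
  z <- qnorm((1 + level) / 2)
  phat <- x / n
  lower <- if (phat == 0) 0 else {
    uniroot(function(p) (phat - p) / sqrt(p * (1 - p) / n) - z,
            c(1e-12, phat - 1e-14), tol = 1e-12)$root
  }
  upper <- if (phat == 1) 1 else {
    uniroot(function(p) (p - phat) / sqrt(p * (1 - p) / n) - z,
            c(phat + 1e-14, 1 - 1e-12), tol = 1e-12)$root
  }
  c(lower = lower, upper = upper)
}

# Build a ds_histories frame from parallel vectors; dates_list entries are
# day offsets from birth.
make_histories <- function(bc_status, day_offsets,
                           birth = as.Date("2010-01-01")) {
  n <- length(bc_status)
  h <- data.frame(child_id = sprintf("H%03d", seq_len(n)),
                  birth_date = rep(birth, n),
                  followup_end = rep(add_years(birth, 6L), n),
                  bc_status = bc_status, stringsAsFactors = FALSE)
  h$ds_encounter_dates <- lapply(day_offsets,
                                 function(d) sort(unique(birth + d)))
  class(h) <- c("ds_histories", "data.frame")
  h
}

# Random small history for property tests: any bc status, 0-6 distinct
# encounter dates within ~6 years of birth, including span boundaries.
random_history <- function() {
  bc <- sample(c("none", "ds", "pending", "confirmed"), 1)
  k <- sample(0:6, 1)
  offsets <- if (k == 0) integer(0) else {
    base <- sample(0:2100, k)
    # occasionally force the 29/30-day span boundary
    if (k >= 3 && runif(1) < 0.3) base <- c(0, sample(0:30, k - 2, TRUE),
                                            sample(29:30, 1))
    unique(base)
  }
  list(bc = bc, offsets = offsets)
}

write_cohort_csvs <- function(cohort, dir) {
  c(encounters = write_encounters(cohort$encounters,
                                  file.path(dir, "encounters.csv")),
    birth_certificates = write_birth_certificates(
      cohort$birth_certificates, file.path(dir, "birth_certificates.csv")),
    censoring = write_censoring(cohort$censoring,
                                file.path(dir, "censoring.csv")),
    chart_review = write_chart_review(cohort$labels,
                                      file.path(dir, "chart_review.csv")))
}
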