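# Synthetic cohort generator. Emulates the statistical structure the
# classifier assumes: a latent true DS status per child, imperfect and
# era-aware birth-certificate capture, DS-coded encounter streams as
# homogeneous Poisson processes (with rare miscoding in non-DS children),
# background non-DS encounters carrying filler codes, and early
# disenrollment. Identical (params, seed) pairs yield identical cohorts.

FILLER_CODES_ICD9 <- c("486", "382.9", "780.60", "V20.2")
FILLER_CODES_ICD10 <- c("J18.9", "H66.90", "R50.9", "Z00.129")
ICD10_START <- as.Date("2015-10-01")

#' Simulation parameters for a synthetic DS cohort
#'
#' Defaults describe an enriched referral-style cohort in which validation
#' statistics are estimable at a few thousand children (see the methods
#' vignette for the rationale behind each value).
#'
#' @param seed RNG seed (mandatory; integer).
#' @param n_children number of children.
#' @param ds_prevalence probability a child truly has DS.
#' @param birth_year_range inclusive (first, last) birth years.
#' @param bc_sensitivity probability a true-DS child gets any
#'   birth-certificate DS indication.
#' @param bc_confirmed_fraction probability an indicated 2004+ certificate
#'   is karyotype-confirmed rather than karyotype-pending (pre-2004
#'   certificates only have the unspecified DS box).
#' @param bc_false_positive_rate probability a non-DS child gets a DS
#'   indication.
#' @param ds_visit_rate mean DS-coded encounters per year for true-DS
#'   children.
#' @param miscode_rate mean DS-coded encounters per year for non-DS
#'   children (billing miscoding).
#' @param background_visit_rate mean non-DS encounters per year (all
#'   children); these carry filler codes only and exercise code matching.
#' @param followup_censor_prob probability of early disenrollment, with the
#'   censoring time uniform over the six-year window.
#' @param study_end administrative end-of-study date.
#' @return an object of class `ds_sim_params`.
#' @export
sim_params <- function(seed,
                       n_children = 2000L,
                       ds_prevalence = 0.1,
                       birth_year_range = c(2000L, 2017L),
                       bc_sensitivity = 0.28,
                       bc_confirmed_fraction = 0.35,
                       bc_false_positive_rate = 0.002,
                       ds_visit_rate = 2,
                       miscode_rate = 0.02,
                       background_visit_rate = 3,
                       followup_censor_prob = 0.2,
                       study_end = as.Date("2020-12-31")) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  p <- list(seed = as.integer(seed), n_children = as.integer(n_children),
            ds_prevalence = ds_prevalence,
            birth_year_range = as.integer(birth_year_range),
            bc_sensitivity = bc_sensitivity,
            bc_confirmed_fraction = bc_confirmed_fraction,
            bc_false_positive_rate = bc_false_positive_rate,
            ds_visit_rate = ds_visit_rate, miscode_rate = miscode_rate,
            background_visit_rate = background_visit_rate,
            followup_censor_prob = followup_censor_prob,
            study_end = as.Date(study_end))
  probs <- c(ds_prevalence = p$ds_prevalence,
             bc_sensitivity = p$bc_sensitivity,
             bc_confirmed_fraction = p$bc_confirmed_fraction,
             bc_false_positive_rate = p$bc_false_positive_rate,
             followup_censor_prob = p$followup_censor_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "),
         call. = FALSE)
  }
  rates <- c(ds_visit_rate = p$ds_visit_rate,
             miscode_rate = p$miscode_rate,
             background_visit_rate = p$background_visit_rate)
  if (any(rates < 0)) {
    stop("rates must be >= 0: ",
         paste(names(rates)[rates < 0], collapse = ", "), call. = FALSE)
  }
  if (p$n_children < 1L) stop("n_children must be >= 1", call. = FALSE)
  if (length(p$birth_year_range) != 2L ||
      p$birth_year_range[1] > p$birth_year_range[2]) {
    stop("birth_year_range must be an ordered (first, last) pair",
         call. = FALSE)
  }
  structure(p, class = "ds_sim_params")
}

# Encounter streams are homogeneous Poisson processes inside [birth, end):
# event counts ~ Poisson(rate * window-years), event days uniform over the
# window, same-day collisions collapsed to one encounter.

# Interleave the DS code into the filler codes at slot `pos` (1..n_filler+1).
with_ds_code <- function(ds_code, f1, f2, n_filler, pos) {
  out <- character(length(ds_code))
  one <- n_filler == 1L
  out[one & pos == 1L] <- paste(ds_code, f1, sep = "|")[one & pos == 1L]
  out[one & pos == 2L] <- paste(f1, ds_code, sep = "|")[one & pos == 2L]
  two <- n_filler == 2L
  out[two & pos == 1L] <- paste(ds_code, f1, f2, sep = "|")[two & pos == 1L]
  out[two & pos == 2L] <- paste(f1, ds_code, f2, sep = "|")[two & pos == 2L]
  out[two & pos == 3L] <- paste(f1, f2, ds_code, sep = "|")[two & pos == 3L]
  out
}

#' Simulate a synthetic cohort
#'
#' Generates the four tables the pipeline consumes (encounters, birth
#' certificates, censoring, gold-standard labels) from a latent true DS
#' status per child. DS-coded encounters place the configured DS code
#' (dotted or undotted at random) in a random diagnostic field among filler
#' codes; ICD version follows the service date (ICD-9 before 2015-10-01,
#' ICD-10 after).
#'
#' @param params a [sim_params()] object.
#' @return an object of class `ds_cohort`: a list with `encounters`,
#'   `birth_certificates`, `censoring`, `labels` (all in the formats of the
#'   corresponding readers) and `params`.
#' @export
simulate_ds_cohort <- function(params) {
  stopifnot(inherits(params, "ds_sim_params"))
  set.seed(params$seed)
  n <- params$n_children
  id <- sprintf("C%06d", seq_len(n))
  yr <- params$birth_year_range
  d0 <- as.Date(sprintf("%d-01-01", yr[1]))
  d1 <- as.Date(sprintf("%d-12-31", yr[2]))
  birth <- d0 + floor(stats::runif(n, 0, as.numeric(d1 - d0) + 1))
  true_ds <- stats::runif(n) < params$ds_prevalence

  censored <- stats::runif(n) < params$followup_censor_prob
  disenroll <- as.Date(rep(NA_character_, n))
  six_years_days <- as.numeric(add_years(birth, 6L) - birth)
  disenroll[censored] <- birth[censored] +
    ceiling(stats::runif(sum(censored), 0, six_years_days[censored]))
  fend <- follow_up_end(birth, NULL, disenroll, params$study_end)
  window_days <- as.numeric(fend - birth)

  ds_rate <- ifelse(true_ds, params$ds_visit_rate, params$miscode_rate)
  k_ds <- stats::rpois(n, ds_rate * window_days / 365.25)
  k_bg <- stats::rpois(n, params$background_visit_rate * window_days / 365.25)
  idx <- c(rep(seq_len(n), k_ds), rep(seq_len(n), k_bg))
  is_ds_visit <- rep(c(TRUE, FALSE), c(sum(k_ds), sum(k_bg)))
  if (length(idx)) {
    date <- birth[idx] + floor(stats::runif(length(idx)) * window_days[idx])
    # collapse same-day claims per child; a DS-coded claim wins the day
    ord <- order(idx, date, !is_ds_visit)
    idx <- idx[ord]; date <- date[ord]; is_ds_visit <- is_ds_visit[ord]
    dup <- duplicated(idx * 1e5 + as.numeric(date))
    idx <- idx[!dup]; date <- date[!dup]; is_ds_visit <- is_ds_visit[!dup]
    m <- length(idx)
    ver <- ifelse(date >= ICD10_START, 10L, 9L)
    n_filler <- sample(1:2, m, replace = TRUE)
    f1 <- ifelse(ver == 10L, sample(FILLER_CODES_ICD10, m, replace = TRUE),
                 sample(FILLER_CODES_ICD9, m, replace = TRUE))
    f2 <- ifelse(ver == 10L, sample(FILLER_CODES_ICD10, m, replace = TRUE),
                 sample(FILLER_CODES_ICD9, m, replace = TRUE))
    ds_code <- ifelse(ver == 10L,
                      sample(c("Q90.9", "Q909", "Q90.0"), m, replace = TRUE),
                      sample(c("758.0", "7580"), m, replace = TRUE))
    pos <- 1L + floor(stats::runif(m) * (n_filler + 1L))  # DS code slot
    codes_str <- ifelse(n_filler == 2L, paste(f1, f2, sep = "|"), f1)
    codes_str[is_ds_visit] <- with_ds_code(ds_code, f1, f2, n_filler,
                                           pos)[is_ds_visit]
    encounters <- data.frame(child_id = id[idx], service_date = date,
                             icd_version = ver, stringsAsFactors = FALSE)
    encounters$diagnosis_codes <- strsplit(codes_str, "|", fixed = TRUE)
  } else {
    encounters <- data.frame(child_id = character(0),
                             service_date = as.Date(character(0)),
                             icd_version = integer(0),
                             stringsAsFactors = FALSE)
    encounters$diagnosis_codes <- list()
  }
  rownames(encounters) <- NULL

  indicated <- ifelse(true_ds,
                      stats::runif(n) < params$bc_sensitivity,
                      stats::runif(n) < params$bc_false_positive_rate)
  pre2004 <- as.integer(format(birth, "%Y")) < 2004L
  confirmed_draw <- stats::runif(n) < params$bc_confirmed_fraction
  ds_indication <- rep("none", n)
  ds_indication[indicated & pre2004] <- "ds"
  ds_indication[indicated & !pre2004] <-
    ifelse(confirmed_draw[indicated & !pre2004], "confirmed", "pending")
  birth_certificates <- data.frame(child_id = id, birth_date = birth,
                                   ds_indication = ds_indication,
                                   stringsAsFactors = FALSE)

  censoring <- data.frame(child_id = id, birth_date = birth,
                          death_date = as.Date(rep(NA_character_, n)),
                          disenrollment_date = disenroll,
                          continuously_enrolled_infancy = rep(TRUE, n),
                          stringsAsFactors = FALSE)
  labels <- data.frame(child_id = id, confirmed_ds = true_ds,
                       stringsAsFactors = FALSE)
  structure(list(encounters = encounters,
                 birth_certificates = birth_certificates,
                 censoring = censoring, labels = labels, params = params),
            class = "ds_cohort")
}

#' @export
print.ds_cohort <- function(x, ...) {
  cat(sprintf("Synthetic DS cohort: %d children (%d true DS), %d encounter rows, seed %d\n",
              nrow(x$censoring), sum(x$labels$confirmed_ds),
              nrow(x$encounters), x$params$seed))
  invisible(x)
}

#' Simulation recovery experiment
#'
#' Runs simulate -> assemble -> classify -> validate over replicates (the
#' replicate index is added to the base seed) and reports, per replicate and
#' as Monte-Carlo means: the empirical PPV against the true labels and the
#' fraction of true-DS children the algorithm classifies as DS.
#'
#' @param params a [sim_params()] object (its seed seeds replicate 1).
#' @param n_replicates number of replicates (>= 1).
#' @param config DS-code predicate used for assembly.
#' @return an object of class `ds_recovery`: per-replicate data frame plus
#'   mean PPV and mean detected fraction.
#' @export
recovery_experiment <- function(params, n_replicates = 10,
                                config = ds_code_config()) {
  stopifnot(inherits(params, "ds_sim_params"), n_replicates >= 1)
  reps <- lapply(seq_len(n_replicates), function(r) {
    p <- params
    p$seed <- params$seed + r - 1L
    cohort <- simulate_ds_cohort(p)
    h <- assemble_histories(cohort$encounters, cohort$birth_certificates,
                            cohort$censoring, config, p$study_end)
    det <- classify_cohort(h)
    v <- validate_ds(det, cohort$labels)
    true_ids <- cohort$labels$child_id[cohort$labels$confirmed_ds]
    detected <- det$algorithm_ds[match(true_ids, det$child_id)]
    data.frame(replicate = r, seed = p$seed,
               n_suspected = v$n_suspected,
               n_algorithm_ds = v$n_algorithm_ds,
               ppv = v$ppv,
               n_true_ds = length(true_ids),
               ds_detected_fraction = if (length(true_ids))
                 mean(detected) else NA_real_)
  })
  tab <- do.call(rbind, reps)
  structure(list(replicates = tab,
                 mean_ppv = mean(tab$ppv, na.rm = TRUE),
                 mean_detected_fraction = mean(tab$ds_detected_fraction,
                                               na.rm = TRUE),
                 params = params),
            class = "ds_recovery")
}

#' @export
print.ds_recovery <- function(x, ...) {
  cat(sprintf("Recovery experiment: %d replicates of n = %d\n",
              nrow(x$replicates), x$params$n_children))
  cat(sprintf("  mean PPV %.4f; mean true-DS detected fraction %.4f\n",
              x$mean_ppv, x$mean_detected_fraction))
  invisible(x)
}
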