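# Readers and writers for the four delimited input tables, with schema
# validation, plus per-child history assembly. All readers are strict: a
# missing column is a schema error naming the column; a malformed value is a
# row-level error carrying the line number.

BC_LEVELS <- c("none", "ds", "pending", "confirmed")

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("schema error in '%s': missing required column(s) %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
}

read_table_raw <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: '%s'", path), call. = FALSE)
  }
  utils::read.csv(path, colClasses = "character", check.names = TRUE,
                  strip.white = TRUE)
}

#' Read an encounters table
#'
#' Expected columns: `child_id`, `service_date` (ISO-8601), `icd_version`
#' (9 or 10), and one or more diagnosis-code columns `dx1`, `dx2`, ...
#' Empty diagnosis cells are dropped (shorter code lists, never empty-string
#' codes); a row with no codes at all is rejected.
#'
#' @param path path to a CSV file.
#' @return a data frame with columns `child_id`, `service_date` (`Date`),
#'   `icd_version` (integer), and `diagnosis_codes` (list column of
#'   character vectors).
#' @export
read_encounters <- function(path) {
  df <- read_table_raw(path)
  check_columns(df, c("child_id", "service_date", "icd_version"), path)
  dx_cols <- grep("^dx[0-9]+$", names(df), value = TRUE)
  if (length(dx_cols) == 0L) {
    stop(sprintf("schema error in '%s': missing required column(s) dx1",
                 path), call. = FALSE)
  }
  dx_cols <- dx_cols[order(as.integer(sub("^dx", "", dx_cols)))]
  n <- nrow(df)
  service_date <- parse_date_column(df$service_date, "service_date")
  icd_version <- suppressWarnings(as.integer(df$icd_version))
  bad_ver <- is.na(icd_version) | !(icd_version %in% c(9L, 10L))
  if (any(bad_ver)) {
    stop(sprintf("invalid icd_version at line(s) %s (must be 9 or 10)",
                 paste(which(bad_ver) + 1L, collapse = ", ")), call. = FALSE)
  }
  dx <- as.matrix(df[dx_cols])
  diagnosis_codes <- lapply(seq_len(n), function(i) {
    codes <- trimws(dx[i, ])
    unname(codes[nzchar(codes)])
  })
  empty <- lengths(diagnosis_codes) == 0L
  if (any(empty)) {
    stop(sprintf("no diagnosis codes at line(s) %s",
                 paste(which(empty) + 1L, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(child_id = df$child_id, service_date = service_date,
                    icd_version = icd_version, stringsAsFactors = FALSE)
  out$diagnosis_codes <- diagnosis_codes
  out
}

#' Write an encounters table
#'
#' Inverse of [read_encounters()]: the `diagnosis_codes` list column is
#' spread over `dx1..dxN` with `N` the longest code list.
#'
#' @param encounters data frame as returned by [read_encounters()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_encounters <- function(encounters, path) {
  n_dx <- max(1L, max(lengths(encounters$diagnosis_codes), 0L))
  dx <- t(vapply(encounters$diagnosis_codes,
                 function(x) c(x, rep("", n_dx - length(x))),
                 character(n_dx)))
  if (nrow(encounters) == 0L) dx <- matrix(character(0), 0, n_dx)
  colnames(dx) <- paste0("dx", seq_len(n_dx))
  out <- cbind(data.frame(child_id = encounters$child_id,
                          service_date = format(encounters$service_date),
                          icd_version = encounters$icd_version,
                          stringsAsFactors = FALSE),
               as.data.frame(dx, stringsAsFactors = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a birth-certificate table
#'
#' Expected columns: `child_id`, `birth_date`, `ds_indication` with values
#' `none`, `ds` (DS box checked, test type unspecified), `pending`
#' (karyotype-pending), or `confirmed` (karyotype-confirmed). The certificate
#' format changed in 2004: births before 2004 may only carry `none` or `ds`
#' (a single check box existed); births in 2004 or later may only carry
#' `none`, `pending`, or `confirmed`.
#'
#' @param path path to a CSV file.
#' @return data frame with `child_id`, `birth_date` (`Date`),
#'   `ds_indication` (character).
#' @export
read_birth_certificates <- function(path) {
  df <- read_table_raw(path)
  check_columns(df, c("child_id", "birth_date", "ds_indication"), path)
  birth_date <- parse_date_column(df$birth_date, "birth_date")
  ind <- tolower(trimws(df$ds_indication))
  bad <- !(ind %in% BC_LEVELS)
  if (any(bad)) {
    stop(sprintf("invalid ds_indication at line(s) %s (must be one of %s)",
                 paste(which(bad) + 1L, collapse = ", "),
                 paste(BC_LEVELS, collapse = "/")), call. = FALSE)
  }
  year <- as.integer(format(birth_date, "%Y"))
  era_bad <- (year < 2004L & !(ind %in% c("none", "ds"))) |
             (year >= 2004L & !(ind %in% c("none", "pending", "confirmed")))
  if (any(era_bad)) {
    stop(sprintf(paste0("ds_indication inconsistent with birth-certificate ",
                        "era at line(s) %s (pre-2004: none/ds; 2004+: ",
                        "none/pending/confirmed)"),
                 paste(which(era_bad) + 1L, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(df$child_id)) {
    stop("duplicate child_id in birth-certificate table: ",
         paste(unique(df$child_id[duplicated(df$child_id)]), collapse = ", "),
         call. = FALSE)
  }
  data.frame(child_id = df$child_id, birth_date = birth_date,
             ds_indication = ind, stringsAsFactors = FALSE)
}

#' @rdname read_birth_certificates
#' @param birth_certs data frame as returned by [read_birth_certificates()].
#' @param path output CSV path.
#' @export
write_birth_certificates <- function(birth_certs, path) {
  out <- data.frame(child_id = birth_certs$child_id,
                    birth_date = format(birth_certs$birth_date),
                    ds_indication = birth_certs$ds_indication,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an enrollment/censoring table
#'
#' Expected columns: `child_id`, `birth_date`, `death_date`,
#' `disenrollment_date` (empty cells mean not applicable), and optionally
#' `continuously_enrolled_infancy` (0/1; assumed 1 when the column is
#' absent). Death and disenrollment must not precede birth. One row per
#' child.
#'
#' @param path path to a CSV file.
#' @return data frame with `Date` columns and a logical
#'   `continuously_enrolled_infancy`.
#' @export
read_censoring <- function(path) {
  df <- read_table_raw(path)
  check_columns(df, c("child_id", "birth_date", "death_date",
                      "disenrollment_date"), path)
  if (anyDuplicated(df$child_id)) {
    stop("duplicate child_id in censoring table: ",
         paste(unique(df$child_id[duplicated(df$child_id)]), collapse = ", "),
         call. = FALSE)
  }
  birth_date <- parse_date_column(df$birth_date, "birth_date")
  death_date <- parse_date_column(df$death_date, "death_date", allow_na = TRUE)
  disenrollment_date <- parse_date_column(df$disenrollment_date,
                                          "disenrollment_date",
                                          allow_na = TRUE)
  bad <- (!is.na(death_date) & death_date < birth_date) |
    (!is.na(disenrollment_date) & disenrollment_date < birth_date)
  if (any(bad)) {
    stop(sprintf("death/disenrollment before birth at line(s) %s",
                 paste(which(bad) + 1L, collapse = ", ")), call. = FALSE)
  }
  enrolled <- if ("continuously_enrolled_infancy" %in% names(df)) {
    v <- trimws(df$continuously_enrolled_infancy)
    if (!all(v %in% c("0", "1"))) {
      stop("continuously_enrolled_infancy must be 0 or 1", call. = FALSE)
    }
    v == "1"
  } else {
    rep(TRUE, nrow(df))
  }
  data.frame(child_id = df$child_id, birth_date = birth_date,
             death_date = death_date,
             disenrollment_date = disenrollment_date,
             continuously_enrolled_infancy = enrolled,
             stringsAsFactors = FALSE)
}

#' @rdname read_censoring
#' @param censoring data frame as returned by [read_censoring()].
#' @param path output CSV path.
#' @export
write_censoring <- function(censoring, path) {
  fmt <- function(d) ifelse(is.na(d), "", format(d))
  out <- data.frame(child_id = censoring$child_id,
                    birth_date = format(censoring$birth_date),
                    death_date = fmt(censoring$death_date),
                    disenrollment_date = fmt(censoring$disenrollment_date),
                    continuously_enrolled_infancy =
                      as.integer(censoring$continuously_enrolled_infancy),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a chart-review (gold standard) label table
#'
#' Expected columns: `child_id`, `confirmed_ds` (0/1); one row per child.
#'
#' @param path path to a CSV file.
#' @return data frame with `child_id` and logical `confirmed_ds`.
#' @export
read_chart_review <- function(path) {
  df <- read_table_raw(path)
  check_columns(df, c("child_id", "confirmed_ds"), path)
  if (anyDuplicated(df$child_id)) {
    stop("duplicate child_id in chart-review table: ",
         paste(unique(df$child_id[duplicated(df$child_id)]), collapse = ", "),
         call. = FALSE)
  }
  v <- trimws(df$confirmed_ds)
  if (!all(v %in% c("0", "1"))) {
    stop("confirmed_ds must be 0 or 1", call. = FALSE)
  }
  data.frame(child_id = df$child_id, confirmed_ds = v == "1",
             stringsAsFactors = FALSE)
}

#' @rdname read_chart_review
#' @param labels data frame as returned by [read_chart_review()].
#' @param path output CSV path.
#' @export
write_chart_review <- function(labels, path) {
  out <- data.frame(child_id = labels$child_id,
                    confirmed_ds = as.integer(labels$confirmed_ds),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble per-child DS evidence histories
#'
#' Joins encounters, birth certificates, and censoring into one row per
#' child: birth date, follow-up window end, birth-certificate DS status, and
#' the distinct service dates inside the follow-up window on which at least
#' one diagnosis code (in any position) matched the DS predicate. Multiple
#' claim lines or codes on one date count as a single encounter. The window
#' is inclusive of death/disenrollment/study-end dates but excludes the
#' sixth birthday itself.
#'
#' Children with no DS evidence at all are still emitted (empty histories)
#' so callers can apply their own suspicion filter; children lacking a
#' birth-certificate row get status `none`.
#'
#' @param encounters data frame from [read_encounters()] (or
#'   [simulate_ds_cohort()]).
#' @param birth_certs data frame from [read_birth_certificates()].
#' @param censoring data frame from [read_censoring()]; every encounter
#'   `child_id` must appear here.
#' @param config DS-code predicate, a [ds_code_config()].
#' @param study_end administrative end-of-study date.
#' @param require_infancy_enrollment drop children whose
#'   `continuously_enrolled_infancy` flag is `FALSE` (the cohort's
#'   inclusion filter, carried as a column rather than recomputed from
#'   enrollment spells).
#' @return a data frame of class `ds_histories`: `child_id`, `birth_date`,
#'   `followup_end`, `bc_status`, and list column `ds_encounter_dates`
#'   (sorted distinct `Date`s).
#' @export
assemble_histories <- function(encounters, birth_certs, censoring,
                               config = ds_code_config(),
                               study_end = as.Date("2020-12-31"),
                               require_infancy_enrollment = TRUE) {
  study_end <- as.Date(study_end)
  orphans <- setdiff(unique(encounters$child_id), censoring$child_id)
  if (length(orphans)) {
    stop("encounter child_id absent from censoring table: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(censoring$child_id)) {
    stop("duplicate child_id in censoring table", call. = FALSE)
  }
  if (require_infancy_enrollment &&
      "continuously_enrolled_infancy" %in% names(censoring)) {
    censoring <- censoring[censoring$continuously_enrolled_infancy, ,
                           drop = FALSE]
    encounters <- encounters[encounters$child_id %in% censoring$child_id, ,
                             drop = FALSE]
  }
  followup_end <- follow_up_end(censoring$birth_date, censoring$death_date,
                                censoring$disenrollment_date, study_end)
  sixth <- add_years(censoring$birth_date, 6L)

  # which encounters carry >= 1 DS code in any diagnostic field
  ds_hit <- logical(nrow(encounters))
  if (nrow(encounters)) {
    row_of <- rep(seq_len(nrow(encounters)),
                  lengths(encounters$diagnosis_codes))
    codes <- unlist(encounters$diagnosis_codes, use.names = FALSE)
    hit <- is_ds_code(codes, encounters$icd_version[row_of], config)
    ds_hit[unique(row_of[hit])] <- TRUE
  }
  ds_enc <- encounters[ds_hit, c("child_id", "service_date"), drop = FALSE]
  dates_by_child <- split(ds_enc$service_date, ds_enc$child_id)

  idx <- match(censoring$child_id, birth_certs$child_id)
  bc_status <- ifelse(is.na(idx), "none", birth_certs$ds_indication[idx])

  ds_encounter_dates <- lapply(seq_len(nrow(censoring)), function(i) {
    d <- dates_by_child[[censoring$child_id[i]]]
    if (is.null(d)) return(as.Date(character(0)))
    d <- d[d >= censoring$birth_date[i] & d <= followup_end[i] & d < sixth[i]]
    sort(unique(d))
  })

  out <- data.frame(child_id = censoring$child_id,
                    birth_date = censoring$birth_date,
                    followup_end = followup_end,
                    bc_status = bc_status,
                    stringsAsFactors = FALSE)
  out$ds_encounter_dates <- ds_encounter_dates
  class(out) <- c("ds_histories", "data.frame")
  out
}

#' @export
print.ds_histories <- function(x, ...) {
  cat(sprintf("DS evidence histories: %d children, %d with >=1 DS-coded encounter, %d with a birth-certificate DS indication\n",
              nrow(x), sum(lengths(x$ds_encounter_dates) > 0L),
              sum(x$bc_status != "none")))
  invisible(x)
}
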