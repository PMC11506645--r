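enc_csv <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  p <- file.path(dir, "enc.csv")
  writeLines(lines, p)
  p
}

test_that("encounter rows parse into code lists, dropping empty cells", {
  p <- enc_csv(c("child_id,service_date,icd_version,dx1,dx2",
                 "C1,2005-03-01,9,7580,486",
                 "C2,2016-01-05,10,Q90.9,",
                 "C3,2003-07-20,9,486,"))
  enc <- read_encounters(p)
  expect_equal(nrow(enc), 3L)
  expect_equal(enc$diagnosis_codes[[1]], c("7580", "486"))
  expect_equal(enc$diagnosis_codes[[2]], "Q90.9")
  expect_s3_class(enc$service_date, "Date")
  expect_equal(enc$icd_version, c(9L, 10L, 9L))
})

test_that("encounter schema and row errors are specific", {
  p <- enc_csv(c("child_id,service_date,icd_version,dx1",
                 "C1,2005-03-01,8,7580"))
  expect_error(read_encounters(p), "icd_version at line\\(s\\) 2")
  p <- enc_csv(c("child_id,service_date,icd_version,dx1",
                 "C1,not-a-date,9,7580"))
  expect_error(read_encounters(p), "service_date at line\\(s\\) 2")
  p <- enc_csv(c("child_id,service_date,icd_version,dx1",
                 "C1,2005-03-01,9,"))
  expect_error(read_encounters(p), "no diagnosis codes at line\\(s\\) 2")
  p <- enc_csv(c("child_id,service_date,dx1", "C1,2005-03-01,7580"))
  expect_error(read_encounters(p), "missing required column.*icd_version")
  expect_error(read_encounters(file.path(tempdir(), "nope.csv")),
               "not found")
  # empty file with valid header -> empty table
  p <- enc_csv("child_id,service_date,icd_version,dx1")
  expect_equal(nrow(read_encounters(p)), 0L)
})

test_that("birth-certificate indications are era-checked", {
  d <- withr::local_tempdir()
  p <- file.path(d, "bc.csv")
  writeLines(c("child_id,birth_date,ds_indication",
               "C1,2003-05-01,ds",
               "C2,2010-05-01,confirmed",
               "C3,2010-05-01,pending",
               "C4,2001-01-01,none"), p)
  bc <- read_birth_certificates(p)
  expect_equal(bc$ds_indication, c("ds", "confirmed", "pending", "none"))
  writeLines(c("child_id,birth_date,ds_indication",
               "C1,2003-05-01,confirmed"), p)
  expect_error(read_birth_certificates(p), "era at line\\(s\\) 2")
  writeLines(c("child_id,birth_date,ds_indication",
               "C1,2010-05-01,ds"), p)
  expect_error(read_birth_certificates(p), "era at line\\(s\\) 2")
  writeLines(c("child_id,birth_date,ds_indication",
               "C1,2010-05-01,maybe"), p)
  expect_error(read_birth_certificates(p), "invalid ds_indication")
})

test_that("all four tables round-trip through write/read exactly", {
  cohort <- simulate_ds_cohort(sim_params(seed = 7L, n_children = 60L))
  d <- withr::local_tempdir()
  paths <- write_cohort_csvs(cohort, d)
  expect_equal(read_encounters(paths["encounters"]), cohort$encounters,
               ignore_attr = TRUE)
  expect_equal(read_birth_certificates(paths["birth_certificates"]),
               cohort$birth_certificates, ignore_attr = TRUE)
  expect_equal(read_censoring(paths["censoring"]), cohort$censoring,
               ignore_attr = TRUE)
  expect_equal(read_chart_review(paths["chart_review"]), cohort$labels,
               ignore_attr = TRUE)
})

test_that("assembly deduplicates same-day claims and applies the window", {
  enc <- data.frame(child_id = c("A", "A", "A", "A", "B"),
                    service_date = as.Date(c("2010-02-01", "2010-02-01",
                                             "2015-12-31", "2016-01-01",
                                             "2010-03-01")),
                    icd_version = 9L, stringsAsFactors = FALSE)
  enc$diagnosis_codes <- list(c("758.0", "486"), "7580", "7580",
                              "7580",  # on A's 6th birthday: excluded
                              "486")   # B: no DS code
  bc <- data.frame(child_id = "B", birth_date = as.Date("2009-01-01"),
                   ds_indication = "confirmed", stringsAsFactors = FALSE)
  cen <- data.frame(child_id = c("A", "B"),
                    birth_date = as.Date(c("2010-01-01", "2009-01-01")),
                    death_date = as.Date(c(NA, NA)),
                    disenrollment_date = as.Date(c(NA, NA)),
                    continuously_enrolled_infancy = TRUE,
                    stringsAsFactors = FALSE)
  h <- assemble_histories(enc, bc, cen)
  expect_equal(h$ds_encounter_dates[[which(h$child_id == "A")]],
               as.Date(c("2010-02-01", "2015-12-31")))
  # B has a certificate but no DS-coded encounter: still emitted, empty
  expect_equal(length(h$ds_encounter_dates[[which(h$child_id == "B")]]), 0L)
  expect_equal(h$bc_status, c("none", "confirmed"))
  expect_equal(h$followup_end, as.Date(c("2016-01-01", "2015-01-01")))
})

test_that("assembly enforces referential integrity and infancy enrollment", {
  enc <- data.frame(child_id = "ghost", service_date = as.Date("2010-01-01"),
                    icd_version = 9L, stringsAsFactors = FALSE)
  enc$diagnosis_codes <- list("758.0")
  cen <- data.frame(child_id = "A", birth_date = as.Date("2010-01-01"),
                    death_date = as.Date(NA), disenrollment_date = as.Date(NA),
                    continuously_enrolled_infancy = TRUE,
                    stringsAsFactors = FALSE)
  bc <- data.frame(child_id = character(0),
                   birth_date = as.Date(character(0)),
                   ds_indication = character(0), stringsAsFactors = FALSE)
  expect_error(assemble_histories(enc, bc, cen), "ghost")
  cen2 <- rbind(cen, data.frame(child_id = "ghost",
                                birth_date = as.Date("2010-01-01"),
                                death_date = as.Date(NA),
                                disenrollment_date = as.Date(NA),
                                continuously_enrolled_infancy = FALSE,
                                stringsAsFactors = FALSE))
  h <- assemble_histories(enc, bc, cen2)
  expect_equal(h$child_id, "A")  # non-enrolled child filtered with its rows
})

test_that("assembled encounter dates are sorted, distinct, and in-window", {
  cohort <- simulate_ds_cohort(sim_params(seed = 3L, n_children = 300L))
  h <- assemble_histories(cohort$encounters, cohort$birth_certificates,
                          cohort$censoring)
  for (i in seq_len(nrow(h))) {
    d <- h$ds_encounter_dates[[i]]
    if (length(d) == 0L) next
    expect_true(all(diff(as.numeric(d)) > 0))
    expect_true(all(d >= h$birth_date[i]))
    expect_true(all(d <= h$followup_end[i]))
    expect_true(all(d < add_years(h$birth_date[i], 6L)))
  }
})
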