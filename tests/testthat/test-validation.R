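test_that("Wilson interval reproduces its closed form at the published counts", {
  expect_equal(round(wilson_interval(347, 354)[1, ], 3),
               c(lower = 0.960, upper = 0.990))
  expect_equal(round(wilson_interval(50, 57)[1, ], 3),
               c(lower = 0.768, upper = 0.939))
  expect_identical(wilson_interval(0, 10)[1, "lower"], c(lower = 0))
  expect_identical(wilson_interval(10, 10)[1, "upper"], c(upper = 1))
  expect_error(wilson_interval(1, 0), "n must be >= 1")
  expect_error(wilson_interval(5, 3), "successes")
})

test_that("Wilson interval matches the score-test inversion oracle and prop.test", {
  set.seed(5)
  for (i in 1:60) {
    n <- sample(1:1000, 1)
    x <- sample(0:n, 1)
    got <- wilson_interval(x, n)[1, ]
    expect_equal(unname(got), unname(wilson_oracle(x, n)), tolerance = 1e-9)
    pt <- suppressWarnings(prop.test(x, n, correct = FALSE))$conf.int
    expect_equal(unname(got), as.numeric(pt), tolerance = 1e-9)
  }
})

test_that("Wilson interval contains the point estimate and narrows with n", {
  set.seed(8)
  for (i in 1:50) {
    n <- sample(5:500, 1)
    x <- sample(0:n, 1)
    ci <- wilson_interval(x, n)[1, ]
    p <- x / n
    expect_lte(ci[["lower"]], p)
    expect_gte(ci[["upper"]], p)
    wider <- wilson_interval(x * 4, n * 4)[1, ]  # same phat, larger n
    expect_lte(wider[["upper"]] - wider[["lower"]],
               ci[["upper"]] - ci[["lower"]])
  }
})

make_det <- function(c1, c2, c3, suspected = TRUE) {
  n <- length(c1)
  out <- data.frame(child_id = sprintf("V%03d", seq_len(n)),
                    bc_status = ifelse(c1, "confirmed", "none"),
                    suspected = rep_len(suspected, n),
                    criterion1 = c1, criterion2 = c2, criterion3 = c3,
                    algorithm_ds = c1 | c2 | c3,
                    n_ds_encounters = 0L, first_last_span_days = NA_integer_,
                    stringsAsFactors = FALSE)
  class(out) <- c("ds_determinations", "data.frame")
  out
}

test_that("PPV and true-negative proportion come out as direct ratios with intervals", {
  det <- make_det(c1 = c(TRUE, TRUE, TRUE, FALSE, FALSE),
                  c2 = rep(FALSE, 5), c3 = rep(FALSE, 5))
  labels <- data.frame(child_id = det$child_id,
                       confirmed_ds = c(TRUE, TRUE, FALSE, FALSE, TRUE))
  v <- validate_ds(det, labels)
  expect_equal(v$n_suspected, 5L)
  expect_equal(v$n_algorithm_ds, 3L)
  expect_equal(v$ppv, 2 / 3)
  expect_equal(v$n_algorithm_negative, 2L)
  expect_equal(v$tn_proportion, 1 / 2)
  expect_equal(unname(v$ppv_ci), unname(wilson_interval(2, 3)[1, ]))
  expect_equal(v$n_algorithm_ds + v$n_algorithm_negative, v$n_suspected)
  expect_equal(sum(v$combination_rows$n_total), v$n_suspected)
  # perfect agreement
  labels2 <- data.frame(child_id = det$child_id,
                        confirmed_ds = det$algorithm_ds)
  v2 <- validate_ds(det, labels2)
  expect_equal(v2$ppv, 1)
  expect_equal(v2$tn_proportion, 1)
})

test_that("degenerate cohorts report absent proportions, never zero", {
  det <- make_det(c1 = c(FALSE, FALSE), c2 = c(FALSE, FALSE),
                  c3 = c(FALSE, FALSE))
  labels <- data.frame(child_id = det$child_id, confirmed_ds = c(FALSE, TRUE))
  v <- validate_ds(det, labels)
  expect_true(is.na(v$ppv))
  expect_true(all(is.na(v$ppv_ci)))
  expect_equal(v$tn_proportion, 1 / 2)
  # all-false cohort yields the single no-criterion row with no PPV
  expect_equal(nrow(v$combination_rows), 1L)
  expect_true(is.na(v$combination_rows$ppv))
  expect_error(validate_ds(det, labels[1, , drop = FALSE]),
               "missing chart-review label.*V002")
})

test_that("combination table partitions the cohort and orders rows canonically", {
  set.seed(31)
  n <- 120L
  det <- make_det(c1 = runif(n) < 0.3, c2 = runif(n) < 0.3,
                  c3 = runif(n) < 0.5)
  labels <- data.frame(child_id = det$child_id, confirmed_ds = runif(n) < 0.8)
  tab <- combination_table(det, labels)
  expect_equal(sum(tab$n_total), n)
  expect_equal(sum(tab$n_confirmed_ds), sum(labels$confirmed_ds))
  expect_equal(sum(tab$n_confirmed_no_ds), sum(!labels$confirmed_ds))
  # each child contributes to exactly one row
  expect_equal(anyDuplicated(tab[c("criterion1", "criterion2", "criterion3")]),
               0L)
  # all-false row present, last, and PPV-free; positive rows have PPV
  last <- tab[nrow(tab), ]
  expect_false(any(last$criterion1, last$criterion2, last$criterion3))
  expect_true(is.na(last$ppv))
  pos <- tab$criterion1 | tab$criterion2 | tab$criterion3
  expect_true(all(!is.na(tab$ppv[pos & tab$n_total > 0])))
  expect_true(all(tab$ppv[pos] >= tab$ppv_lower[pos] - 1e-12))
  expect_true(all(tab$ppv[pos] <= tab$ppv_upper[pos] + 1e-12))
})

test_that("labelled-subset operating characteristics are opt-in and annotated", {
  det <- make_det(c1 = c(TRUE, TRUE, FALSE, FALSE), c2 = rep(FALSE, 4),
                  c3 = rep(FALSE, 4))
  labels <- data.frame(child_id = det$child_id,
                       confirmed_ds = c(TRUE, FALSE, TRUE, FALSE))
  v <- validate_ds(det, labels)
  expect_null(v$labelled_subset_operating)
  vo <- validate_ds(det, labels, operating = TRUE)
  expect_equal(vo$labelled_subset_operating$sensitivity, 1 / 2)
  expect_equal(vo$labelled_subset_operating$specificity, 1 / 2)
  expect_match(vo$labelled_subset_operating$note, "labelled")
})

test_that("display rounding is half away from zero", {
  expect_equal(round_half_up(97.15, 1), 97.2)
  expect_equal(round_half_up(c(86.1314, 98.0226, 87.719), 1),
               c(86.1, 98.0, 87.7))
  expect_equal(round_half_up(-0.25, 1), -0.3)
})
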