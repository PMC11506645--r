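#' Wilson score confidence interval for a binomial proportion
#'
#' The interval obtained by inverting the normal-approximation score test,
#' with better small-sample behaviour than the Wald interval:
#' \deqn{\frac{\hat p + z^2/2n \pm z\sqrt{\hat p(1-\hat p)/n + z^2/4n^2}}{1 + z^2/n}}
#' The exact normal quantile is used (1.959964 at the default 95% level,
#' not 1.96). Bounds are clamped to \[0, 1\]; at \eqn{\hat p = 0} the lower
#' bound is exactly 0 and at \eqn{\hat p = 1} the upper bound exactly 1.
#'
#' @param successes integer vector of success counts.
#' @param n integer vector of trial counts (>= 1), recycled.
#' @param conf.level confidence level in (0, 1).
#' @return a two-column matrix (`lower`, `upper`), one row per input.
#' @examples
#' wilson_interval(347, 354)  # c. (0.960, 0.990)
#' @export
wilson_interval <- function(successes, n, conf.level = 0.95) {
  if (!is.numeric(conf.level) || length(conf.level) != 1L ||
      conf.level <= 0 || conf.level >= 1) {
    stop("conf.level must be a single probability in (0, 1)", call. = FALSE)
  }
  k <- max(length(successes), length(n))
  successes <- rep_len(as.numeric(successes), k)
  n <- rep_len(as.numeric(n), k)
  if (any(n < 1)) stop("n must be >= 1 (interval undefined)", call. = FALSE)
  if (any(successes < 0 | successes > n)) {
    stop("successes must lie in [0, n]", call. = FALSE)
  }
  z <- stats::qnorm((1 + conf.level) / 2)
  p <- successes / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  denom <- 1 + z^2 / n
  lower <- pmax(0, pmin(1, (centre - half) / denom))
  upper <- pmax(0, pmin(1, (centre + half) / denom))
  lower[p == 0] <- 0
  upper[p == 1] <- 1
  cbind(lower = lower, upper = upper)
}

#' Validate algorithm determinations against chart-review labels
#'
#' Restricts to suspected children (the population the validation design
#' supports) and computes, with Wilson intervals: the positive predictive
#' value (confirmed DS among algorithm-positives) and the true-negative
#' proportion (confirmed non-DS among algorithm-negatives), plus a
#' criterion-combination breakdown via [combination_table()]. When there are
#' no algorithm-positives the PPV is reported as `NA`, not 0 (and likewise
#' for the true-negative proportion).
#'
#' Sensitivity and specificity are not reported by default: the suspected-DS
#' design cannot see DS children with no coded evidence, so population-level
#' operating characteristics are unidentifiable. `operating = TRUE` computes
#' them against the labelled subset only, clearly annotated as such.
#'
#' @param determinations a `ds_determinations` data frame from
#'   [classify_cohort()] (or any data frame with the same columns).
#' @param labels chart-review gold standard: data frame with `child_id` and
#'   logical/0-1 `confirmed_ds`. Every suspected child must have a label.
#' @param conf.level confidence level for the Wilson intervals.
#' @param operating also compute sensitivity/specificity within the
#'   labelled subset.
#' @return an object of class `ds_validation` (a list of counts,
#'   proportions, intervals, and the combination table).
#' @export
validate_ds <- function(determinations, labels, conf.level = 0.95,
                        operating = FALSE) {
  s <- determinations[determinations$suspected, , drop = FALSE]
  if (anyDuplicated(labels$child_id)) {
    stop("duplicate child_id in labels", call. = FALSE)
  }
  idx <- match(s$child_id, labels$child_id)
  if (anyNA(idx)) {
    stop("missing chart-review label for child_id: ",
         paste(s$child_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  confirmed <- as.logical(labels$confirmed_ds)[idx]
  pos <- s$algorithm_ds
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  n_conf_pos <- sum(confirmed & pos)
  n_tn <- sum(!confirmed & !pos)
  ppv <- if (n_pos > 0) n_conf_pos / n_pos else NA_real_
  ppv_ci <- if (n_pos > 0) wilson_interval(n_conf_pos, n_pos, conf.level)[1, ]
            else c(lower = NA_real_, upper = NA_real_)
  tn_prop <- if (n_neg > 0) n_tn / n_neg else NA_real_
  tn_ci <- if (n_neg > 0) wilson_interval(n_tn, n_neg, conf.level)[1, ]
           else c(lower = NA_real_, upper = NA_real_)
  out <- list(
    n_suspected = nrow(s),
    n_algorithm_ds = n_pos,
    n_confirmed_among_positive = n_conf_pos,
    ppv = ppv, ppv_ci = ppv_ci,
    n_algorithm_negative = n_neg,
    n_true_negative = n_tn,
    tn_proportion = tn_prop, tn_ci = tn_ci,
    combination_rows = combination_table(s, labels, conf.level),
    conf.level = conf.level
  )
  if (operating) {
    n_label_pos <- sum(confirmed)
    n_label_neg <- sum(!confirmed)
    out$labelled_subset_operating <- list(
      sensitivity = if (n_label_pos > 0) sum(pos & confirmed) / n_label_pos
                    else NA_real_,
      specificity = if (n_label_neg > 0) sum(!pos & !confirmed) / n_label_neg
                    else NA_real_,
      note = "within the labelled (suspected) subset only; not population operating characteristics"
    )
  }
  class(out) <- "ds_validation"
  out
}

#' Criterion-combination breakdown with per-pattern PPV
#'
#' Partitions the suspected cohort by the observed pattern of the three
#' criteria, always including the all-false (no criterion met) row. Each row
#' reports the total, chart-review-confirmed DS and non-DS counts, and the
#' per-pattern PPV with its Wilson interval; the all-false row carries no
#' PPV (there are no positives to predict).
#'
#' @inheritParams validate_ds
#' @return a data frame with logical columns `criterion1..3`, counts, and
#'   `ppv`, `ppv_lower`, `ppv_upper`.
#' @export
combination_table <- function(determinations, labels, conf.level = 0.95) {
  s <- determinations[determinations$suspected, , drop = FALSE]
  idx <- match(s$child_id, labels$child_id)
  if (anyNA(idx)) {
    stop("missing chart-review label for child_id: ",
         paste(s$child_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  confirmed <- as.logical(labels$confirmed_ds)[idx]
  pattern <- paste0(as.integer(s$criterion1), as.integer(s$criterion2),
                    as.integer(s$criterion3))
  patterns <- union(unique(pattern), "000")
  rows <- lapply(patterns, function(p) {
    in_p <- pattern == p
    data.frame(criterion1 = substr(p, 1, 1) == "1",
               criterion2 = substr(p, 2, 2) == "1",
               criterion3 = substr(p, 3, 3) == "1",
               n_total = sum(in_p),
               n_confirmed_ds = sum(in_p & confirmed),
               n_confirmed_no_ds = sum(in_p & !confirmed))
  })
  out <- do.call(rbind, rows)
  is_pos <- out$criterion1 | out$criterion2 | out$criterion3
  ci <- wilson_interval(pmax(out$n_confirmed_ds, 0),
                        pmax(out$n_total, 1), conf.level)
  out$ppv <- ifelse(is_pos & out$n_total > 0,
                    out$n_confirmed_ds / out$n_total, NA_real_)
  out$ppv_lower <- ifelse(is.na(out$ppv), NA_real_, ci[, "lower"])
  out$ppv_upper <- ifelse(is.na(out$ppv), NA_real_, ci[, "upper"])
  out <- out[order_combination_rows(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.ds_validation <- function(x, ...) {
  pct <- function(p) fmt_num(100 * p)
  cat(sprintf("DS algorithm validation against chart review (%g%% Wilson CIs)\n",
              100 * x$conf.level))
  cat(sprintf("  Suspected DS: %d children; algorithm-positive: %d (%s%%)\n",
              x$n_suspected, x$n_algorithm_ds,
              pct(x$n_algorithm_ds / max(x$n_suspected, 1L))))
  if (is.na(x$ppv)) {
    cat("  PPV: not applicable (no algorithm-positive children)\n")
  } else {
    cat(sprintf("  PPV: %d/%d = %s%% (CI: %s-%s%%)\n",
                x$n_confirmed_among_positive, x$n_algorithm_ds, pct(x$ppv),
                pct(x$ppv_ci[["lower"]]), pct(x$ppv_ci[["upper"]])))
  }
  if (is.na(x$tn_proportion)) {
    cat("  True-negative proportion: not applicable (no algorithm-negative children)\n")
  } else {
    cat(sprintf("  True negatives: %d/%d = %s%% (CI: %s-%s%%)\n",
                x$n_true_negative, x$n_algorithm_negative,
                pct(x$tn_proportion),
                pct(x$tn_ci[["lower"]]), pct(x$tn_ci[["upper"]])))
  }
  cat("  Criterion-combination breakdown:\n")
  writeLines(paste0("    ", format_combination_table(x$combination_rows)))
  if (!is.null(x$labelled_subset_operating)) {
    o <- x$labelled_subset_operating
    cat(sprintf("  Labelled-subset sensitivity %s%%, specificity %s%% (%s)\n",
                pct(o$sensitivity), pct(o$specificity), o$note))
  }
  invisible(x)
}

#' @export
summary.ds_validation <- function(object, ...) object

# Text rendering of the combination table: X marks a met criterion, PPV
# blank on the no-criterion row.
format_combination_table <- function(tab) {
  mark <- function(b) ifelse(b, "X", " ")
  body <- data.frame(
    crit1 = mark(tab$criterion1), crit2 = mark(tab$criterion2),
    crit3 = mark(tab$criterion3), n = tab$n_total,
    confirmed_ds = tab$n_confirmed_ds, confirmed_no_ds = tab$n_confirmed_no_ds,
    ppv = ifelse(is.na(tab$ppv), "NA",
                 paste0(fmt_num(100 * tab$ppv), "%")),
    stringsAsFactors = FALSE)
  utils::capture.output(print.data.frame(body, row.names = FALSE))
}

#' Write a validation report to disk
#'
#' Produces `validation_report.json` (all counts, proportions, intervals,
#' and combination rows) and `validation_table.txt` (the human-readable
#' criterion-combination table) in `dir`.
#'
#' @param validation a `ds_validation` object.
#' @param dir output directory (created if needed).
#' @return named character vector of the two file paths, invisibly.
#' @export
write_validation_report <- function(validation, dir) {
  stopifnot(inherits(validation, "ds_validation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, "validation_report.json")
  txt_path <- file.path(dir, "validation_table.txt")
  payload <- unclass(validation)
  payload$ppv_ci <- as.list(payload$ppv_ci)
  payload$tn_ci <- as.list(payload$tn_ci)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  writeLines(format_combination_table(validation$combination_rows), txt_path)
  invisible(c(json = json_path, table = txt_path))
}

#' Round half away from zero
#'
#' Display rounding convention used throughout the package's reports:
#' `round_half_up(97.15, 1)` is 97.2, where base `round()` would give 97.1
#' (round-half-to-even). Matters only at exact .5 ties.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

fmt_num <- function(x, digits = 1) {
  ifelse(is.na(x), "NA", formatC(round_half_up(x, digits),
                                 format = "f", digits = digits))
}
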