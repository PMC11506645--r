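# The three-criteria DS classifier. A child with suspected DS (any
# birth-certificate indication or any DS-coded encounter) is classified as
# having DS if at least one criterion holds:
#   1. karyotype-confirmed DS on the birth certificate;
#   2. karyotype-pending DS (or the pre-2004 unspecified DS box) on the
#      birth certificate AND >= 2 DS-coded encounters before age six;
#   3. >= 3 DS-coded encounters before age six, first and last separated by
#      >= 30 calendar days.
# Criteria are evaluated independently and all flags are reported; the final
# label is their disjunction, with no precedence.

#' Suspected-DS screen
#'
#' A child enters the suspected-DS pool when they have any birth-certificate
#' DS indication or at least one DS-coded encounter inside the follow-up
#' window.
#'
#' @param histories a `ds_histories` data frame from [assemble_histories()].
#' @return logical vector, one element per child.
#' @export
is_suspected <- function(histories) {
  histories$bc_status != "none" | lengths(histories$ds_encounter_dates) >= 1L
}

#' Classify a cohort with the three-criteria DS algorithm
#'
#' Applies the classifier to each child's assembled evidence history. The
#' encounter dates are assumed already window-restricted and deduplicated
#' (as [assemble_histories()] guarantees); classification is invariant to
#' the order dates are supplied in, and the 30-day separation rule depends
#' only on the first and last dates.
#'
#' @param histories a `ds_histories` data frame from [assemble_histories()].
#' @return a data frame of class `ds_determinations` with one row per child,
#'   order-preserving: `child_id`, `bc_status`, `suspected`, `criterion1`,
#'   `criterion2`, `criterion3`, `algorithm_ds`, `n_ds_encounters`, and
#'   `first_last_span_days` (`NA` when there are no DS-coded encounters).
#' @examples
#' h <- data.frame(child_id = c("a", "b"), stringsAsFactors = FALSE)
#' h$birth_date <- as.Date(c("2010-01-01", "2010-01-01"))
#' h$followup_end <- as.Date(c("2016-01-01", "2016-01-01"))
#' h$bc_status <- c("confirmed", "none")
#' h$ds_encounter_dates <- list(as.Date(character(0)),
#'                              as.Date("2010-02-01") + c(0, 10, 30))
#' class(h) <- c("ds_histories", "data.frame")
#' classify_cohort(h)
#' @export
classify_cohort <- function(histories) {
  if (anyDuplicated(histories$child_id)) {
    stop("duplicate child_id in histories: ",
         paste(unique(histories$child_id[duplicated(histories$child_id)]),
               collapse = ", "), call. = FALSE)
  }
  dates <- histories$ds_encounter_dates
  n_enc <- lengths(dates)
  span <- vapply(dates, function(d) {
    if (length(d) == 0L) return(NA_real_)
    as.numeric(max(d) - min(d))
  }, numeric(1))
  bc <- histories$bc_status
  criterion1 <- bc == "confirmed"
  criterion2 <- bc %in% c("pending", "ds") & n_enc >= 2L
  criterion3 <- n_enc >= 3L & !is.na(span) & span >= 30
  out <- data.frame(
    child_id = histories$child_id,
    bc_status = bc,
    suspected = is_suspected(histories),
    criterion1 = criterion1,
    criterion2 = criterion2,
    criterion3 = criterion3,
    algorithm_ds = criterion1 | criterion2 | criterion3,
    n_ds_encounters = as.integer(n_enc),
    first_last_span_days = as.integer(span),
    stringsAsFactors = FALSE
  )
  class(out) <- c("ds_determinations", "data.frame")
  out
}

#' @export
print.ds_determinations <- function(x, n = 6L, ...) {
  cat(sprintf("DS determinations: %d children, %d suspected, %d algorithm-positive\n",
              nrow(x), sum(x$suspected), sum(x$algorithm_ds)))
  if (nrow(x)) {
    print.data.frame(utils::head(as.data.frame(x), n))
    if (nrow(x) > n) cat(sprintf("... and %d more rows\n", nrow(x) - n))
  }
  invisible(x)
}

#' @export
summary.ds_determinations <- function(object, ...) {
  s <- object[object$suspected, , drop = FALSE]
  combos <- stats::aggregate(list(n = seq_len(nrow(s))),
                             by = list(criterion1 = s$criterion1,
                                       criterion2 = s$criterion2,
                                       criterion3 = s$criterion3),
                             FUN = length)
  combos <- combos[order_combination_rows(combos), , drop = FALSE]
  rownames(combos) <- NULL
  out <- list(n_children = nrow(object), n_suspected = nrow(s),
              n_algorithm_ds = sum(s$algorithm_ds), combinations = combos)
  class(out) <- "summary.ds_determinations"
  out
}

#' @export
print.summary.ds_determinations <- function(x, ...) {
  cat(sprintf("%d children; %d suspected of DS; %d classified DS by the algorithm (%s%%)\n",
              x$n_children, x$n_suspected, x$n_algorithm_ds,
              fmt_num(100 * x$n_algorithm_ds / max(x$n_suspected, 1L))))
  cat("Counts by criterion combination (suspected children):\n")
  print.data.frame(x$combinations)
  invisible(x)
}

# Table ordering convention for criterion combinations: group rows by the
# first criterion met (1, 2, 3, then none), then by the remaining flags.
order_combination_rows <- function(df) {
  first_met <- ifelse(df$criterion1, 1L,
                      ifelse(df$criterion2, 2L, ifelse(df$criterion3, 3L, 4L)))
  rest <- df$criterion2 * 2L + df$criterion3
  order(first_met, rest)
}
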