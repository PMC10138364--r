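#' @name habits
#' @title Multi-day movement-habit change detection
#' @description
#' Classifies a patient's movement-habit change from three consecutive
#' daily totals of active hours (walking + sitting + standing). Two
#' consecutive day-over-day percentage differences are compared with a
#' threshold `kth` (default 12.5%): both at or below `-kth` means the
#' habits slowed down, both at or above `+kth` means they increased,
#' anything else is unchanged. The verdict feeds the `MoveH` field of the
#' patient state.
NULL

#' Active hours for one ledger day
#'
#' `ActH = walking + sitting + standing` hours; lying, sleeping and fallen
#' time is excluded.
#'
#' @param ledger An [activity_ledger()].
#' @param day A `Date` (or coercible string).
#' @param subject Optional subject filter for multi-subject ledgers.
#' @return Active hours for that day.
#' @export
daily_active_hours <- function(ledger, day, subject = NULL) {
  day <- as.Date(day)
  rows <- ledger$day == day
  if (!is.null(subject)) rows <- rows & ledger$subject == subject
  if (!any(rows)) stop("day ", format(day), " not present in ledger")
  sum(ledger[rows, "walking"]) + sum(ledger[rows, "sitting"]) +
    sum(ledger[rows, "standing"])
}

#' Percentage difference
#'
#' `((a - b) / b) * 100`. The division is unguarded in the printed form;
#' here `b = 0` with `a > 0` returns `+Inf` (which preserves the monotone
#' semantics of the threshold comparison) and `a = b = 0` returns 0.
#'
#' @param a,b Hour values.
#' @return Percentage difference of `a` relative to `b`.
#' @export
percent_diff <- function(a, b) {
  if (is.na(a) || is.na(b)) return(NA_real_)
  if (b == 0) {
    if (a == 0) return(0)
    return(Inf)
  }
  ((a - b) / b) * 100
}

#' Classify movement-habit change over three days
#'
#' @param acth Numeric vector `c(ActH(t_m-1), ActH(t_m-2), ActH(t_m-3))`:
#'   active hours for yesterday, the day before, and two days before.
#' @param kth Percentage-change threshold (default 12.5).
#' @return List of class `habit_verdict` with `value` (`unchanged`,
#'   `slowed_down` or `increased`), `diffs` (the two percentage
#'   differences), and `insufficient_data` (`TRUE` when a day was missing
#'   and the verdict defaulted to unchanged).
#' @export
classify_movement_change <- function(acth, kth = 12.5) {
  stopifnot(length(acth) == 3, kth > 0)
  acth <- as.numeric(acth)
  d1 <- percent_diff(acth[1], acth[2])
  d2 <- percent_diff(acth[2], acth[3])
  if (is.na(d1) || is.na(d2)) {
    return(structure(list(value = "unchanged", diffs = c(d1, d2),
                          insufficient_data = TRUE),
                     class = "habit_verdict"))
  }
  value <- if (d1 <= -kth && d2 <= -kth) {
    "slowed_down"
  } else if (d1 >= kth && d2 >= kth) {
    "increased"
  } else {
    "unchanged"
  }
  structure(list(value = value, diffs = c(d1, d2),
                 insufficient_data = FALSE),
            class = "habit_verdict")
}

#' @export
print.habit_verdict <- function(x, ...) {
  cat(sprintf("<habit_verdict> %s (diffs %.1f%%, %.1f%%)%s\n",
              x$value, x$diffs[1], x$diffs[2],
              if (isTRUE(x$insufficient_data)) " [insufficient data]" else ""))
  invisible(x)
}

#' Movement-habit verdict straight from a ledger
#'
#' Convenience wrapper: looks up active hours for the three days before
#' `date` and classifies the change. A missing day yields an unchanged
#' verdict flagged `insufficient_data`.
#'
#' @param ledger An [activity_ledger()].
#' @param date The current day `t_m`; the verdict uses days
#'   `t_m-1 .. t_m-3`.
#' @param kth Percentage-change threshold.
#' @param subject Optional subject filter.
#' @return A `habit_verdict`.
#' @export
habit_verdict_for_date <- function(ledger, date, kth = 12.5, subject = NULL) {
  date <- as.Date(date)
  acth <- vapply(1:3, function(n) {
    tryCatch(daily_active_hours(ledger, date - n, subject = subject),
             error = function(e) NA_real_)
  }, numeric(1))
  classify_movement_change(acth, kth = kth)
}
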