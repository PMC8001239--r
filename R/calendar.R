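#' Build a weekly/monthly study calendar
#'
#' Partitions an inclusive date range into consecutive 7-day bins anchored at
#' the start date and enumerates the calendar months the range covers.  The
#' number of weekly bins is `ceiling(days / 7)`, so the final bin may be a
#' partial week; set `keep_partial_week = FALSE` to drop it.  Each weekly bin
#' belongs to the month containing its start date.
#'
#' The study window of the motivating application, 2000-01-01 through
#' 2015-09-30, yields 822 weekly bins and 189 months.
#'
#' @param start_date,end_date Dates (or strings coercible via [as.Date()]);
#'   `start_date` must precede `end_date`.
#' @param keep_partial_week Keep a trailing bin that extends past `end_date`?
#'   Default `TRUE`.
#' @return An object of class `spill_calendar`: a list with `start`, `end`,
#'   `week_starts` (Date vector), `n_weeks`, `months` (data frame with
#'   `year`, `month`, `label`), `n_months`, and `week_month` (index of the
#'   month each week belongs to).
#' @examples
#' cal <- make_calendar("2000-01-01", "2015-09-30")
#' cal$n_weeks   # 822
#' cal$n_months  # 189
#' @export
make_calendar <- function(start_date, end_date, keep_partial_week = TRUE) {
  start <- as.Date(start_date)
  end <- as.Date(end_date)
  if (is.na(start) || is.na(end))
    stop_input("calendar dates must be parseable as ISO-8601 dates")
  if (start >= end)
    stop_input("start_date (%s) must be strictly before end_date (%s)",
               format(start), format(end))
  n_days <- as.integer(end - start) + 1L
  n_weeks <- as.integer(ceiling(n_days / 7))
  week_starts <- start + 7L * (seq_len(n_weeks) - 1L)
  if (!keep_partial_week && (week_starts[n_weeks] + 6L) > end) {
    n_weeks <- n_weeks - 1L
    week_starts <- week_starts[seq_len(n_weeks)]
  }

  sy <- as.integer(format(start, "%Y")); sm <- as.integer(format(start, "%m"))
  ey <- as.integer(format(end, "%Y"));   em <- as.integer(format(end, "%m"))
  idx <- seq.int(sy * 12L + sm, ey * 12L + em)
  months <- data.frame(
    year = (idx - 1L) %/% 12L,
    month = (idx - 1L) %% 12L + 1L
  )
  months$label <- sprintf("%04d-%02d", months$year, months$month)

  wk_lab <- format(week_starts, "%Y-%m")
  week_month <- match(wk_lab, months$label)
  if (anyNA(week_month))
    stop_input("internal error: week start outside month range")

  structure(
    list(start = start, end = end,
         week_starts = week_starts, n_weeks = n_weeks,
         months = months, n_months = nrow(months),
         week_month = week_month),
    class = "spill_calendar"
  )
}

#' @export
print.spill_calendar <- function(x, ...) {
  cat(sprintf("<spill_calendar> %s .. %s: %d weekly bins, %d months\n",
              format(x$start), format(x$end), x$n_weeks, x$n_months))
  invisible(x)
}

#' Aggregate weekly series to monthly means
#'
#' Converts one or more weekly series into monthly series by averaging the
#' weekly values whose bin start date falls in each month (the convention
#' used to align weekly connectedness indices with monthly covariates).
#'
#' @param x Numeric vector or matrix with one row (element) per weekly bin of
#'   `calendar`.
#' @param calendar A [make_calendar()] object aligned with `x`.
#' @return A numeric vector (or matrix) with one value per calendar month;
#'   row names are the month labels.
#' @export
aggregate_weekly_to_monthly <- function(x, calendar) {
  if (!inherits(calendar, "spill_calendar"))
    stop_input("`calendar` must be a spill_calendar")
  vec <- is.null(dim(x))
  m <- if (vec) matrix(as.numeric(x), ncol = 1) else as.matrix(x)
  if (nrow(m) != calendar$n_weeks)
    stop_input("series length (%d) does not match calendar weekly bins (%d)",
               nrow(m), calendar$n_weeks)
  if (anyNA(m)) stop_input("weekly input contains missing values")
  g <- factor(calendar$week_month, levels = seq_len(calendar$n_months))
  if (any(tabulate(g, calendar$n_months) == 0))
    stop_input("calendar month %s contains no weekly bin",
               calendar$months$label[which(tabulate(g, calendar$n_months) == 0)[1]])
  out <- apply(m, 2, function(col) tapply(col, g, mean))
  out <- matrix(out, nrow = calendar$n_months,
                dimnames = list(calendar$months$label, colnames(m)))
  if (vec) out[, 1] else out
}
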