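# Time-to-onset: days from therapy initiation to adverse-event onset, with
# validity exclusions. Both dates must be complete (year+month+day) and
# parseable; negative intervals are excluded as implausible sequences.

tto_bin_breaks <- c(-Inf, 30, 60, 90, 120, 150, 180, 360, Inf)
tto_bin_labels <- c("0-30", "31-60", "61-90", "91-120", "121-150",
                    "151-180", "181-360", ">360")

#' Compute per-report time to onset with validity status
#'
#' `tto_days = event date - therapy start date` in whole days, evaluated only
#' when both dates carry full day precision. Statuses: `included`;
#' `excluded_negative` (event precedes start); `excluded_incomplete_date`
#' (either date present but partial/unparseable); `excluded_missing` (either
#' date absent).
#'
#' @param start_dt character vector of therapy start dates (FAERS form).
#' @param event_dt character vector of event onset dates (FAERS form).
#' @param caseid optional identifier column carried through.
#' @return tibble with `caseid` (if given), `start_dt`, `event_dt`,
#'   `tto_days` (integer, `NA` unless included) and `status`.
#' @export
compute_tto <- function(start_dt, event_dt, caseid = NULL) {
  start_dt <- as.character(start_dt)
  event_dt <- as.character(event_dt)
  miss <- function(x) is.na(x) | x == ""
  status <- rep("included", length(start_dt))
  status[miss(start_dt) | miss(event_dt)] <- "excluded_missing"
  incomplete <- status == "included" &
    (!faers_date_complete(start_dt) | !faers_date_complete(event_dt))
  status[incomplete] <- "excluded_incomplete_date"
  tto <- rep(NA_integer_, length(start_dt))
  ok <- status == "included"
  tto[ok] <- as.integer(parse_faers_date(event_dt[ok]) -
                          parse_faers_date(start_dt[ok]))
  neg <- ok & tto < 0
  status[neg] <- "excluded_negative"
  tto[neg] <- NA_integer_
  out <- tibble::tibble(start_dt, event_dt, tto_days = tto, status)
  if (!is.null(caseid)) out <- tibble::tibble(caseid, out)
  out
}

#' Binned and quartile summary of time-to-onset values
#'
#' Bins are upper-inclusive integer-day intervals matching the conventional
#' presentation (`0-30` means `0 <= t <= 30`; same-day onset falls in the
#' first bin). Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7); the method is recorded in the result so that
#' summaries are reproducible.
#'
#' @param records a tibble from [compute_tto()], or a bare numeric vector of
#'   onset days (all treated as included).
#' @return a list of class `tto_summary`: `bins` (tibble `group`, `n`,
#'   `percent` with percent to 2 dp), `n_included`, exclusion counts,
#'   `mean`, `median`, `q1`, `q3`, `iqr`, `quantile_method`. With zero
#'   included records the quartile fields are `NA` and `flagged` is `TRUE`.
#' @export
summarize_tto <- function(records) {
  if (is.numeric(records)) {
    records <- tibble::tibble(tto_days = as.integer(records),
                              status = "included")
  }
  excl <- table(factor(records$status,
                       levels = c("included", "excluded_negative",
                                  "excluded_incomplete_date",
                                  "excluded_missing")))
  t_inc <- records$tto_days[records$status == "included"]
  n_inc <- length(t_inc)
  binned <- cut(t_inc, breaks = tto_bin_breaks, labels = tto_bin_labels,
                right = TRUE)
  counts <- as.integer(table(binned))
  bins <- tibble::tibble(
    group = paste0(tto_bin_labels, " days"),
    n = counts,
    percent = if (n_inc > 0) round(100 * counts / n_inc, 2) else rep(NA_real_, length(counts))
  )
  q <- if (n_inc > 0) unname(quantile(t_inc, c(0.25, 0.5, 0.75), type = 7)) else rep(NA_real_, 3)
  structure(
    list(
      bins = bins,
      n_included = n_inc,
      n_excluded_negative = unname(excl[["excluded_negative"]]),
      n_excluded_incomplete_date = unname(excl[["excluded_incomplete_date"]]),
      n_excluded_missing = unname(excl[["excluded_missing"]]),
      mean = if (n_inc > 0) mean(t_inc) else NA_real_,
      median = q[2], q1 = q[1], q3 = q[3], iqr = q[3] - q[1],
      quantile_method = "linear interpolation (type 7)",
      flagged = n_inc == 0
    ),
    class = "tto_summary"
  )
}

#' @export
print.tto_summary <- function(x, ...) {
  cat("<tto_summary>\n")
  cat(sprintf("  included: %d (negative: %d, incomplete date: %d, missing: %d)\n",
              x$n_included, x$n_excluded_negative,
              x$n_excluded_incomplete_date, x$n_excluded_missing))
  if (!x$flagged) {
    cat(sprintf("  median %.1f days (IQR %.1f; Q1 %.1f, Q3 %.1f), mean %.1f\n",
                x$median, x$iqr, x$q1, x$q3, x$mean))
    print(as.data.frame(x$bins), row.names = FALSE)
  }
  invisible(x)
}

#' Time-to-onset records for the event cases of a cleaned dataset
#'
#' Convenience wrapper: computes [compute_tto()] over the cases that carry a
#' matched target drug and at least one mapped event PT (the population whose
#' onset profile is of interest).
#'
#' @param clean a `faers_clean` object.
#' @return tibble as from [compute_tto()], one row per event case.
#' @export
tto_records <- function(clean) {
  sel <- clean$cases[!is.na(clean$cases$target_drug) & clean$cases$any_event, ,
                     drop = FALSE]
  compute_tto(sel$start_dt, sel$event_dt, caseid = sel$caseid)
}
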