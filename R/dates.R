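# FAERS calendar fields arrive as character strings in YYYYMMDD form, with
# partial precision (YYYYMM or YYYY) common in older quarters. They are kept
# as strings end-to-end; only fully specified dates are ever converted to Date.

#' Test whether a FAERS date string carries full day precision
#'
#' A date is complete when it has all of year, month and day and parses as a
#' real calendar date (e.g. "20230230" is incomplete in the validity sense).
#'
#' @param x character vector of FAERS date strings (`YYYYMMDD`, `YYYYMM`,
#'   `YYYY`, or `NA`).
#' @return logical vector, `FALSE` for `NA`, partial, or unparseable input.
#' @export
faers_date_complete <- function(x) {
  x <- as.character(x)
  ok <- !is.na(x) & nchar(x) == 8L & grepl("^[0-9]{8}$", x)
  ok[ok] <- !is.na(as.Date(x[ok], format = "%Y%m%d"))
  ok
}

#' Parse complete FAERS date strings to Date
#'
#' Partial or malformed strings give `NA`.
#'
#' @inheritParams faers_date_complete
#' @return a `Date` vector.
#' @export
parse_faers_date <- function(x) {
  x <- as.character(x)
  out <- rep(as.Date(NA), length(x))
  ok <- faers_date_complete(x)
  out[ok] <- as.Date(x[ok], format = "%Y%m%d")
  out
}

format_faers_date <- function(d) format(d, "%Y%m%d")

# Pad partial FAERS dates so that lexicographic order is a total order with
# missing components treated as earliest ("202303" -> "20230300" sorts before
# any real March date). Used only for deduplication ordering, never for TTO.
pad_faers_date <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == ""] <- "00000000"
  n <- nchar(x)
  x[n == 4L] <- paste0(x[n == 4L], "0000")
  n <- nchar(x)
  x[n == 6L] <- paste0(x[n == 6L], "00")
  x
}

# Truncate a complete YYYYMMDD string to a coarser precision.
truncate_faers_date <- function(x, keep = c("month", "year")) {
  keep <- match.arg(keep)
  substr(x, 1L, if (keep == "month") 6L else 4L)
}
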