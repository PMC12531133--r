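#' Parse FAERS-style partial dates
#'
#' FAERS date fields are numeric strings in `YYYYMMDD`, `YYYYMM` or `YYYY`
#' form, frequently truncated. Partial dates are retained with the missing
#' day (and month) imputed as the 1st so that interval arithmetic remains
#' possible, and the original precision is kept alongside so downstream
#' summaries can exclude imputed intervals.
#'
#' @param x character vector of date tokens; `NA`, `""` and unparseable
#'   tokens yield a missing date.
#' @return a data frame with columns `date` (class `Date`) and `prec`
#'   (`"day"`, `"month"`, `"year"` or `NA` when the date is missing).
#' @examples
#' parse_faers_date(c("20200315", "202003", "2020", "XX", NA))
#' @export
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  x[!is.na(x) & x == ""] <- NA_character_
  digits <- !is.na(x) & grepl("^[0-9]+$", x)
  prec <- rep(NA_character_, length(x))
  prec[digits & nchar(x) == 8] <- "day"
  prec[digits & nchar(x) == 6] <- "month"
  prec[digits & nchar(x) == 4] <- "year"
  full <- rep(NA_character_, length(x))
  full[which(prec == "day")] <- x[which(prec == "day")]
  full[which(prec == "month")] <- paste0(x[which(prec == "month")], "01")
  full[which(prec == "year")] <- paste0(x[which(prec == "year")], "0101")
  date <- as.Date(full, format = "%Y%m%d")
  # impossible calendar dates (e.g. 20200230) fall back to missing
  prec[is.na(date)] <- NA_character_
  data.frame(date = date, prec = prec, stringsAsFactors = FALSE)
}

#' Format dates back to FAERS tokens at their recorded precision
#'
#' Inverse of [parse_faers_date()]: a date with precision `"month"` is
#' written as `YYYYMM`, `"year"` as `YYYY`, so that a read/write round trip
#' preserves partial dates exactly.
#'
#' @param date `Date` vector.
#' @param prec precision vector as returned by [parse_faers_date()].
#' @return character vector; missing dates become `""`.
#' @export
format_faers_date <- function(date, prec) {
  out <- rep("", length(date))
  ok <- !is.na(date) & !is.na(prec)
  fmt <- c(day = "%Y%m%d", month = "%Y%m", year = "%Y")
  for (p in names(fmt)) {
    i <- ok & prec == p
    out[i] <- format(date[i], fmt[[p]])
  }
  out
}

#' @keywords internal
date_is_imputed <- function(prec) !is.na(prec) & prec != "day"
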