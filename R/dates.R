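#' Parse FAERS-style compact dates
#'
#' FAERS date fields arrive as digit strings of length 4 (`YYYY`), 6
#' (`YYYYMM`) or 8 (`YYYYMMDD`). Partial dates are preserved, not imputed:
#' the result records the populated components and a precision label, and
#' downstream stages decide whether a value is usable (time-to-onset, for
#' example, requires day precision). Anything empty or malformed — wrong
#' length, non-digits, month outside 1–12, day invalid for its month and
#' year — becomes a missing row rather than an error.
#'
#' @param x Character vector of raw date strings (`NA` and `""` allowed).
#' @return A tibble with one row per element: `raw`, `year`, `month`, `day`
#'   (integer or `NA`) and `precision` (`"year"`, `"month"`, `"day"`, or
#'   `NA` when unparseable).
#' @examples
#' parse_fda_date(c("20200315", "202003", "2020", "20200230", ""))
#' @export
parse_fda_date <- function(x) {
  x <- as.character(x)
  n <- length(x)
  year <- month <- day <- rep(NA_integer_, n)
  precision <- rep(NA_character_, n)

  ok <- !is.na(x) & grepl("^[0-9]+$", x) & nchar(x) %in% c(4L, 6L, 8L)
  if (any(ok)) {
    xo <- x[ok]
    y <- as.integer(substr(xo, 1, 4))
    m <- ifelse(nchar(xo) >= 6, as.integer(substr(xo, 5, 6)), NA_integer_)
    d <- ifelse(nchar(xo) == 8, as.integer(substr(xo, 7, 8)), NA_integer_)
    valid <- y >= 1000 &
      (is.na(m) | (m >= 1L & m <= 12L)) &
      (is.na(d) | (!is.na(m) & d >= 1L & d <= days_in_month(y, m)))
    prec <- dplyr::case_when(!is.na(d) ~ "day", !is.na(m) ~ "month", TRUE ~ "year")
    idx <- which(ok)[valid]
    year[idx] <- y[valid]
    month[idx] <- m[valid]
    day[idx] <- d[valid]
    precision[idx] <- prec[valid]
  }
  tibble(raw = x, year = year, month = month, day = day, precision = precision)
}

days_in_month <- function(year, month) {
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  out <- base[ifelse(is.na(month) | month < 1 | month > 12, NA_integer_, month)]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  out[!is.na(month) & month == 2L & leap] <- 29L
  out
}

#' Format parsed dates back to the compact FAERS dialect
#'
#' Inverse of [parse_fda_date()]: a day-precision row becomes `YYYYMMDD`,
#' month precision `YYYYMM`, year precision `YYYY`, and unparseable rows an
#' empty string.
#'
#' @param parsed A tibble as returned by [parse_fda_date()].
#' @return Character vector of compact date strings.
#' @export
format_fda_date <- function(parsed) {
  out <- rep("", nrow(parsed))
  d <- !is.na(parsed$precision) & parsed$precision == "day"
  m <- !is.na(parsed$precision) & parsed$precision == "month"
  y <- !is.na(parsed$precision) & parsed$precision == "year"
  out[d] <- sprintf("%04d%02d%02d", parsed$year[d], parsed$month[d], parsed$day[d])
  out[m] <- sprintf("%04d%02d", parsed$year[m], parsed$month[m])
  out[y] <- sprintf("%04d", parsed$year[y])
  out
}

# Date (class Date) for day-precision values, NA otherwise.
fda_date_as_date <- function(x) {
  p <- parse_fda_date(x)
  out <- rep(as.Date(NA), nrow(p))
  d <- !is.na(p$precision) & p$precision == "day"
  out[d] <- as.Date(sprintf("%04d-%02d-%02d", p$year[d], p$month[d], p$day[d]))
  out
}

# numeric YYYYMMDD for ordering receipt dates (NA if not 8-digit)
fda_date_num <- function(x) {
  suppressWarnings(ifelse(grepl("^[0-9]{8}$", x), as.numeric(x), NA_real_))
}
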