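FAERS_TABLES <- c("demo", "drug", "reac", "outc", "rpsr", "ther", "indi")

faers_columns <- list(
  demo = c("primaryid", "caseid", "caseversion", "fda_dt", "event_dt",
           "age", "age_cod", "sex", "occr_country", "occp_cod"),
  drug = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname"),
  reac = c("primaryid", "caseid", "pt"),
  outc = c("primaryid", "caseid", "outc_cod"),
  rpsr = c("primaryid", "caseid", "rpsr_cod"),
  ther = c("primaryid", "caseid", "dsg_drug_seq", "start_dt", "end_dt"),
  indi = c("primaryid", "caseid", "indi_drug_seq", "indi_pt")
)

#' Read a FAERS-style quarterly extract
#'
#' Reads the seven `$`-delimited ASCII tables (`demo`, `drug`, `reac`,
#' `outc`, `rpsr`, `ther`, `indi`) from a directory into a list of character
#' tibbles. Every field is kept as a string exactly as found (missing values
#' stay `""`), so a write/read round trip is bit-exact; typed views (ages in
#' years, parsed dates) are produced downstream by [case_reports()] and
#' friends. Rows whose field count disagrees with the header are skipped
#' with a message naming the line; `drug`/`reac`/... rows whose `primaryid`
#' is absent from `demo` are retained but flagged `orphan`. Input is decoded
#' as Latin-1 (FAERS archives contain non-UTF-8 bytes).
#'
#' @param path Directory containing `<table>.txt` files.
#' @param quarter Quarter label such as `"2024Q4"`; defaults to the
#'   directory's basename when that matches the pattern, otherwise `NA`.
#' @param delim Field delimiter (default `"$"`).
#' @param encoding Input encoding (default `"latin1"`).
#' @return A `faers_quarter`: named list of tibbles plus a `quarter` label.
#' @seealso [write_faers_quarter()], [case_reports()]
#' @export
read_faers_quarter <- function(path, quarter = NULL, delim = "$",
                               encoding = "latin1") {
  stopifnot(dir.exists(path))
  files <- file.path(path, paste0(FAERS_TABLES, ".txt"))
  missing <- !file.exists(files)
  if (any(missing)) {
    abort(paste0("missing mandatory FAERS table file(s): ",
                 paste(basename(files[missing]), collapse = ", ")))
  }
  tables <- purrr::map(seq_along(FAERS_TABLES), function(i) {
    read_faers_table(files[i], delim = delim, encoding = encoding)
  })
  names(tables) <- FAERS_TABLES

  known <- tables$demo$primaryid
  for (tb in setdiff(FAERS_TABLES, "demo")) {
    tables[[tb]]$orphan <- !(tables[[tb]]$primaryid %in% known)
    n_orph <- sum(tables[[tb]]$orphan)
    if (n_orph > 0) {
      inform(sprintf("%s: %d record(s) reference a primaryid absent from demo (flagged orphan)",
                     tb, n_orph))
    }
  }
  if (is.null(quarter)) {
    bn <- basename(normalizePath(path))
    quarter <- if (grepl("^[0-9]{4}Q[1-4]$", bn)) bn else NA_character_
  }
  new_faers_quarter(tables, quarter)
}

new_faers_quarter <- function(tables, quarter) {
  structure(c(tables, list(quarter = quarter)), class = "faers_quarter")
}

#' @export
print.faers_quarter <- function(x, ...) {
  cat("<faers_quarter ", x$quarter %||% "?", ">\n", sep = "")
  for (tb in FAERS_TABLES) {
    cat(sprintf("  %s: %d records\n", tb, nrow(x[[tb]])))
  }
  invisible(x)
}

read_faers_table <- function(file, delim = "$", encoding = "latin1") {
  lines <- readLines(file, encoding = encoding, warn = FALSE)
  if (length(lines) == 0) abort(paste0("empty table file: ", basename(file)))
  header <- strsplit(lines[1], delim, fixed = TRUE)[[1]]
  nf <- stringr::str_count(lines, stringr::fixed(delim)) + 1L
  bad <- which(nf != length(header))
  bad <- bad[bad > 1L]
  if (length(bad) > 0) {
    warn(sprintf("%s: skipped %d row(s) with wrong field count (lines %s)",
                 basename(file), length(bad),
                 paste(utils::head(bad, 10), collapse = ", ")))
    lines <- lines[-bad]
  }
  if (length(lines) == 1) {
    out <- as_tibble(setNames(rep(list(character()), length(header)), header))
    return(out)
  }
  readr::read_delim(I(lines), delim = delim,
                    col_types = readr::cols(.default = readr::col_character()),
                    na = character(), progress = FALSE)
}

#' Write a FAERS-style quarterly extract
#'
#' Writes each table of a `faers_quarter` back to `<table>.txt` in the
#' `$`-delimited dialect read by [read_faers_quarter()]. Fields are written
#' verbatim, so read/write round trips are bit-exact.
#'
#' @param x A `faers_quarter`.
#' @param path Output directory (created if needed).
#' @param delim Field delimiter (default `"$"`).
#' @return `path`, invisibly.
#' @export
write_faers_quarter <- function(x, path, delim = "$") {
  stopifnot(inherits(x, "faers_quarter"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (tb in FAERS_TABLES) {
    tab <- x[[tb]]
    tab <- tab[, intersect(faers_columns[[tb]], names(tab)), drop = FALSE]
    readr::write_delim(tab, file.path(path, paste0(tb, ".txt")),
                       delim = delim, na = "", progress = FALSE)
  }
  invisible(path)
}

#' Deduplicate case reports
#'
#' FAERS distributes resubmitted cases as additional versions of the same
#' `caseid`; standard practice keeps, per case, the record with the latest
#' receipt date (`fda_dt`), breaking ties by the highest `primaryid`, and
#' removes cases named on the quarterly deleted-case lists. The operation is
#' idempotent and never increases the record count.
#'
#' @param demo Demographics tibble with at least `caseid`, `primaryid`,
#'   `fda_dt` columns (character, as read by [read_faers_quarter()]).
#' @param deleted_cases Character vector of `caseid`s to drop entirely.
#' @return One row per surviving `caseid`.
#' @export
deduplicate_cases <- function(demo, deleted_cases = character()) {
  no_id <- is.na(demo$caseid) | demo$caseid == ""
  if (any(no_id)) {
    warn(sprintf("rejected %d demo record(s) with missing caseid", sum(no_id)))
    demo <- demo[!no_id, , drop = FALSE]
  }
  demo |>
    filter(!.data$caseid %in% deleted_cases) |>
    mutate(
      .fda = fda_date_num(.data$fda_dt),
      .pid = suppressWarnings(as.numeric(.data$primaryid))
    ) |>
    arrange(.data$caseid, desc(.data$.fda), desc(.data$.pid)) |>
    distinct(.data$caseid, .keep_all = TRUE) |>
    select(-".fda", -".pid")
}

#' Convert FAERS age value/unit pairs to years
#'
#' Units: `DEC` decades, `YR` years, `MON` months, `WK` weeks, `DY` days.
#' Unknown units or values outside `[0, 130]` years become `NA` with a
#' warning (implausible ages are treated as data entry errors, not clipped).
#'
#' @param age Character or numeric age values.
#' @param age_cod Character unit codes.
#' @return Numeric vector of ages in years.
#' @examples
#' convert_age(c("5", "30", "18"), c("DEC", "YR", "MON"))
#' @export
convert_age <- function(age, age_cod) {
  val <- suppressWarnings(as.numeric(age))
  mult <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52, DY = 1 / 365.25)
  m <- unname(mult[toupper(trimws(age_cod))])
  yrs <- val * m
  bad <- !is.na(yrs) & (yrs < 0 | yrs > 130)
  if (any(bad)) {
    warn(sprintf("%d age value(s) outside [0, 130] years set to missing", sum(bad)))
    yrs[bad] <- NA_real_
  }
  yrs
}

#' Build the deduplicated case-report table
#'
#' Applies [deduplicate_cases()] to the demographics table and derives the
#' typed per-report fields used downstream: receipt date, sex (`M`/`F`/
#' `unknown`), age in years (via [convert_age()]), age band, country,
#' reporter occupation, and the report-level event date kept as a raw
#' partial-date string.
#'
#' @param quarter A `faers_quarter` from [read_faers_quarter()] or
#'   [generate_faers()].
#' @param deleted_cases Character vector of `caseid`s to drop.
#' @return Tibble with one row per deduplicated case.
#' @export
case_reports <- function(quarter, deleted_cases = character()) {
  demo <- deduplicate_cases(quarter$demo, deleted_cases)
  demo |>
    mutate(
      receipt_date = fda_date_num(.data$fda_dt),
      sex = ifelse(.data$sex %in% c("M", "F"), .data$sex, "unknown"),
      age_years = convert_age(.data$age, .data$age_cod),
      age_band = age_band(.data$age_years),
      country = na_if_blank(.data$occr_country),
      occupation = na_if_blank(.data$occp_cod)
    ) |>
    select("caseid", "primaryid", "fda_dt", "receipt_date", "event_dt",
           "sex", "age_years", "age_band", "country", "occupation")
}

na_if_blank <- function(x) ifelse(is.na(x) | x == "", NA_character_, x)

#' Age bands used for subgroup analyses
#'
#' Integer-year banding partitioning the age axis: `<18` is `[0, 18)`,
#' `18-45` is `[18, 46)`, `46-65` is `[46, 66)`, `>65` is `[66, Inf)`.
#'
#' @param age_years Numeric ages in years.
#' @return Character vector of band labels (`NA` for missing ages).
#' @export
age_band <- function(age_years) {
  dplyr::case_when(
    is.na(age_years) ~ NA_character_,
    age_years < 18 ~ "<18",
    age_years < 46 ~ "18-45",
    age_years < 66 ~ "46-65",
    TRUE ~ ">65"
  )
}

# per-report outcome code sets, restricted to deduplicated primaryids
report_outcomes <- function(outc, primaryids) {
  outc |>
    filter(.data$primaryid %in% primaryids) |>
    distinct(.data$primaryid, .data$outc_cod)
}
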