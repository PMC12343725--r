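#' Normalise a verbatim drug name
#'
#' Uppercases, trims, collapses internal whitespace and unifies the
#' separators used in combination-product names (`\\`, `+`, `;` become
#' `/`). Verbatim FAERS drug names are free text; synonym resolution on top
#' of this normalisation is configuration-driven (see
#' [select_primary_suspect()]), not dictionary-based.
#'
#' @param x Character vector of verbatim drug names.
#' @return Normalised names.
#' @examples
#' normalize_drug_name(" dolutegravir  sodium ")
#' @export
normalize_drug_name <- function(x) {
  x <- toupper(stringr::str_squish(x))
  x <- gsub("[\\\\;+]", "/", x)
  stringr::str_squish(gsub("\\s*/\\s*", "/", x))
}

#' Default target-drug synonym configuration for dolutegravir
#'
#' Name variants under which the integrase inhibitor dolutegravir appears
#' in spontaneous reports: the generic name and salt, brand names, and the
#' fixed-dose combinations that contain it. Each variant carries an
#' `enabled` flag; combination products can be switched off when a
#' single-agent cohort is wanted.
#'
#' @param include_combinations Include fixed-dose combination products
#'   (default `TRUE`).
#' @return Tibble with columns `variant`, `enabled`.
#' @export
dtg_synonyms <- function(include_combinations = TRUE) {
  tibble(
    variant = c("DOLUTEGRAVIR", "DOLUTEGRAVIR SODIUM", "TIVICAY",
                "TRIUMEQ", "DOVATO", "JULUCA",
                "ABACAVIR/DOLUTEGRAVIR/LAMIVUDINE",
                "DOLUTEGRAVIR/LAMIVUDINE", "DOLUTEGRAVIR/RILPIVIRINE"),
    combination = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)
  ) |>
    mutate(enabled = !.data$combination | include_combinations) |>
    select("variant", "enabled")
}

#' Select the primary-suspect cohort for a target drug
#'
#' Returns the reports in which the target drug (under any enabled name
#' variant, after [normalize_drug_name()]) is recorded with role code `PS`
#' (primary suspect). Monotone in the synonym set: enabling more variants
#' never shrinks the cohort.
#'
#' @param drug Drug tibble (columns `primaryid`, `role_cod`, `drugname`).
#' @param synonyms Tibble with columns `variant` and `enabled` (for example
#'   [dtg_synonyms()]), or a character vector of enabled variants.
#' @return Sorted character vector of cohort `primaryid`s.
#' @export
select_primary_suspect <- function(drug, synonyms) {
  if (is.character(synonyms)) {
    synonyms <- tibble(variant = synonyms, enabled = TRUE)
  }
  enabled <- normalize_drug_name(synonyms$variant[synonyms$enabled])
  if (length(enabled) == 0) abort("synonym configuration enables no drug name variants")
  drug |>
    filter(.data$role_cod == "PS",
           normalize_drug_name(.data$drugname) %in% enabled) |>
    pull("primaryid") |>
    unique() |>
    sort()
}

OUTC_LABELS <- c(
  CA = "Congenital anomaly",
  DE = "Death",
  DS = "Disability",
  HO = "Hospitalization - Initial or Prolonged",
  LT = "Life-threatening",
  OT = "Other serious (important medical event)",
  RI = "Required intervention to prevent permanent impairment/damage"
)

#' Descriptive summary of a report cohort
#'
#' Computes the descriptive blocks of a spontaneous-report characteristics
#' table: sex, age bands, top reporter countries, reporter occupations,
#' outcome categories, top indications, yearly report counts and totals.
#' Percentages are `100 * n / n_cases`, half-up rounded to two decimals;
#' every block's counts (including an explicit `Missing` row) sum to the
#' cohort size except outcomes, where a report can carry several outcome
#' codes and therefore contribute to several rows.
#'
#' @param cases Deduplicated case tibble from [case_reports()], already
#'   restricted to the cohort.
#' @param drugs Drug records for the cohort (used for totals only).
#' @param events Reaction records (`primaryid`, `pt`) for the cohort.
#' @param outcomes Outcome records (`primaryid`, `outc_cod`) for the cohort.
#' @param indications Indication records (`primaryid`, `indi_pt`), optional.
#' @param top_n How many countries/indications to list before `Others`.
#' @return A `cohort_summary` object; [generics::tidy()] flattens it to one
#'   long tibble of `(block, category, n, pct)`.
#' @export
summarize_cohort <- function(cases, drugs, events, outcomes,
                             indications = NULL, top_n = 5) {
  total <- nrow(cases)
  stopifnot(total > 0)

  block <- function(x, levels = NULL, label_missing = "Missing") {
    x <- ifelse(is.na(x), label_missing, x)
    tab <- tibble(category = x) |> count(.data$category)
    if (!is.null(levels)) {
      tab <- tibble(category = c(levels, label_missing)) |>
        left_join(tab, by = "category") |>
        mutate(n = coalesce(.data$n, 0L))
    }
    mutate(tab, pct = pct_of(.data$n, total))
  }
  top_block <- function(x, label_missing = "Missing") {
    x <- ifelse(is.na(x), label_missing, x)
    tab <- tibble(category = x) |>
      count(.data$category) |>
      arrange(desc(.data$n), .data$category)
    main <- tab |> filter(.data$category != label_missing) |> head(top_n)
    rest <- tab |>
      filter(!.data$category %in% main$category, .data$category != label_missing)
    out <- bind_rows(
      main,
      tibble(category = "Others", n = sum(rest$n)),
      tab |> filter(.data$category == label_missing)
    )
    mutate(out, pct = pct_of(.data$n, total))
  }

  sex <- block(ifelse(cases$sex == "unknown", NA, cases$sex), levels = c("F", "M"))
  age <- block(cases$age_band, levels = c("<18", "18-45", "46-65", ">65"))
  country <- top_block(cases$country)
  occupation <- block(cases$occupation)

  outc <- outcomes |>
    filter(.data$primaryid %in% cases$primaryid) |>
    distinct(.data$primaryid, .data$outc_cod) |>
    count(.data$outc_cod) |>
    mutate(category = coalesce(OUTC_LABELS[.data$outc_cod], .data$outc_cod)) |>
    select("category", "n")
  no_outcome <- total - n_distinct(intersect(outcomes$primaryid, cases$primaryid))
  outc <- bind_rows(outc, tibble(category = "Missing", n = no_outcome)) |>
    mutate(pct = pct_of(.data$n, total))

  indi_block <- if (!is.null(indications)) {
    per_case <- indications |>
      filter(.data$primaryid %in% cases$primaryid) |>
      distinct(.data$primaryid, .keep_all = TRUE)
    x <- rep(NA_character_, total)
    x[match(per_case$primaryid, cases$primaryid)] <- per_case$indi_pt
    top_block(x)
  } else NULL

  yearly <- cases |>
    mutate(year = as.integer(substr(.data$fda_dt, 1, 4))) |>
    count(.data$year)

  structure(list(
    n_cases = total,
    n_events = events |> filter(.data$primaryid %in% cases$primaryid) |>
      distinct(.data$primaryid, .data$pt) |> nrow(),
    sex = sex, age = age, country = country, occupation = occupation,
    outcomes = outc, indications = indi_block, yearly = yearly
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary: %d cases, %d adverse events>\n",
              x$n_cases, x$n_events))
  print(generics::tidy(x), n = 20)
  invisible(x)
}

#' @rdname summarize_cohort
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @method tidy cohort_summary
#' @export
tidy.cohort_summary <- function(x, ...) {
  blocks <- c("sex", "age", "country", "occupation", "outcomes", "indications")
  purrr::map_dfr(blocks, function(b) {
    if (is.null(x[[b]])) return(NULL)
    mutate(x[[b]], block = b, .before = 1)
  })
}

#' @rdname summarize_cohort
#' @method glance cohort_summary
#' @export
glance.cohort_summary <- function(x, ...) {
  tibble(n_cases = x$n_cases, n_events = x$n_events,
         years = nrow(x$yearly))
}

#' Concomitant-medication counts
#'
#' Counts, for each non-target normalised drug name, the number of distinct
#' cohort cases listing it (a case naming the same co-drug twice counts
#' once), sorted by descending count with alphabetical tie-break.
#'
#' @param cases Cohort case tibble ([case_reports()] rows).
#' @param drugs Drug records (any role).
#' @param target_variants Synonym tibble or character vector identifying
#'   the target drug (its own records are excluded).
#' @return Tibble `(drugname, n)`.
#' @export
comedication_counts <- function(cases, drugs, target_variants) {
  if (is.data.frame(target_variants)) {
    target_variants <- target_variants$variant[target_variants$enabled]
  }
  target_variants <- normalize_drug_name(target_variants)
  drugs |>
    filter(.data$primaryid %in% cases$primaryid) |>
    mutate(drugname = normalize_drug_name(.data$drugname)) |>
    filter(!.data$drugname %in% target_variants) |>
    distinct(.data$primaryid, .data$drugname) |>
    count(.data$drugname, name = "n") |>
    arrange(desc(.data$n), .data$drugname)
}
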