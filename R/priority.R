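#' Clinical-priority rubric components
#'
#' Scores a positive disproportionality signal on the four-criterion
#' rubric, each component worth 0-2 points:
#'
#' * **Reporting rate** (`100 * a / event_total`): 2 if > 10%, 1 if in
#'   (1%, 10%], 0 if <= 1%. The denominator is the drug's total
#'   adverse-event count (the subgroup's own total for subgroup screens).
#' * **Signal stability**: the four method flags are mapped onto three
#'   analysis families — ROR, PRR, and the Bayesian pair (IC and EBGM
#'   jointly) — and the count of positive families scores 3-of-3 = 2,
#'   2-of-3 = 1, otherwise 0.
#' * **Fatal report proportion** (`100 * fatal_count / a`): 2 if > 50%,
#'   1 if in \[25%, 50%\], 0 if < 25%.
#' * **Clinical relevance**: 2 if the PT is a designated medical event
#'   (DME), 1 if an important medical event (IME), else 0 (DME takes
#'   precedence when a term is on both lists).
#'
#' Totals of 0-2, 3-5 and 6-8 band as `low`, `moderate`, `high`.
#'
#' @param a Report count for the drug-event pair (vectorised).
#' @param fatal_count Reports with a death (`DE`) outcome among `a`.
#' @param event_total Total adverse-event count for the drug in the same
#'   (sub)population — the reporting-rate denominator.
#' @param ror_flag,prr_flag,ic_flag,ebgm_flag Per-method positivity.
#' @param dme,ime Logical: term membership of the DME / IME list.
#' @return Tibble with the four component scores, `total` and `band`.
#' @examples
#' # a DME with 41.67% fatal reports, all methods positive, rate << 1%
#' priority_components(24, 10, 32383, TRUE, TRUE, TRUE, TRUE,
#'                     dme = TRUE, ime = FALSE)
#' @export
priority_components <- function(a, fatal_count, event_total,
                                ror_flag, prr_flag, ic_flag, ebgm_flag,
                                dme, ime) {
  if (any(event_total <= 0)) abort("event_total must be positive")
  if (any(fatal_count > a)) abort("fatal_count cannot exceed the report count a")
  if (any(fatal_count < 0 | a < 0)) abort("counts must be nonnegative")

  rate <- 100 * a / event_total
  rate_points <- ifelse(rate > 10, 2L, ifelse(rate > 1, 1L, 0L))

  families <- ror_flag + prr_flag + (ic_flag & ebgm_flag)
  stability_points <- ifelse(families == 3, 2L, ifelse(families == 2, 1L, 0L))

  fatal_pct <- ifelse(a > 0, 100 * fatal_count / a, 0)
  fatality_points <- ifelse(fatal_pct > 50, 2L, ifelse(fatal_pct >= 25, 1L, 0L))

  relevance_points <- ifelse(dme, 2L, ifelse(ime, 1L, 0L))

  total <- rate_points + stability_points + fatality_points + relevance_points
  tibble(
    rate_points = rate_points, stability_points = stability_points,
    fatality_points = fatality_points, relevance_points = relevance_points,
    total = total, band = priority_band(total)
  )
}

#' @rdname priority_components
#' @param total Integer total score(s) in 0-8.
#' @export
priority_band <- function(total) {
  stopifnot(all(total >= 0 & total <= 8))
  factor(ifelse(total <= 2, "low", ifelse(total <= 5, "moderate", "high")),
         levels = c("low", "moderate", "high"))
}

#' Prioritise the positive signals of a screen
#'
#' Annotates every positive PT-level signal with the rubric score. The
#' fatal count per term is the number of distinct reports carrying both the
#' event and a death (`DE`) outcome; the reporting-rate denominator is the
#' total adverse-event count of the target drug within the screened
#' (sub)population. Output is ordered by band (high first), then total
#' score, then term.
#'
#' @param signals A PT-level [screen_signals()] result.
#' @param reac Reaction records for the same extract.
#' @param outc Outcome records (`primaryid`, `outc_cod`).
#' @param target_ids Cohort `primaryid`s (same as passed to the screen).
#' @param lists DME/IME term lists from [load_event_lists()].
#' @param event_total Reporting-rate denominator; default computed as the
#'   number of distinct (report, PT) pairs among the cohort's reports in
#'   the screened subgroup.
#' @param cases Case table; needed only to apply the subgroup filter when
#'   `event_total` is not supplied.
#' @return The positive signals with `fatal_count`, `fatal_pct`, the four
#'   component scores, `total` and `band` appended.
#' @export
prioritize_signals <- function(signals, reac, outc, target_ids, lists,
                               event_total = NULL, cases = NULL) {
  pos <- filter(signals, .data$positive)
  if (nrow(pos) == 0) {
    return(mutate(pos, fatal_count = integer(), fatal_pct = numeric(),
                  rate_points = integer(), stability_points = integer(),
                  fatality_points = integer(), relevance_points = integer(),
                  total = integer(), band = priority_band(integer())))
  }
  subgroup <- pos$subgroup[1]
  ids <- target_ids
  if (!is.null(cases)) {
    ids <- intersect(ids, filter_subgroup(cases, subgroup)$primaryid)
  }
  if (is.null(event_total)) {
    event_total <- reac |>
      filter(.data$primaryid %in% ids) |>
      distinct(.data$primaryid, .data$pt) |>
      nrow()
  }
  dead <- unique(outc$primaryid[outc$outc_cod == "DE"])
  fatal <- reac |>
    filter(.data$primaryid %in% ids, .data$primaryid %in% dead) |>
    distinct(.data$primaryid, .data$pt) |>
    count(.data$pt, name = "fatal_count")
  pos <- pos |>
    left_join(fatal, by = c(term = "pt")) |>
    mutate(fatal_count = coalesce(.data$fatal_count, 0L),
           fatal_pct = round_half_up(100 * .data$fatal_count / .data$a, 2))
  scores <- priority_components(
    pos$a, pos$fatal_count, event_total,
    pos$ror_flag, pos$prr_flag, pos$ic_flag, pos$ebgm_flag,
    dme = pos$term %in% lists$dme,
    ime = pos$term %in% lists$ime
  )
  bind_cols(pos, scores) |>
    arrange(desc(.data$band), desc(.data$total), .data$term)
}
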