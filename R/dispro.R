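#' Default signal-detection thresholds
#'
#' The conjunction rule used throughout: a drug-event pair is a *signal*
#' only when all four disproportionality methods flag it. Defaults are the
#' thresholds standard in the FAERS literature: ROR requires at least
#' `min_a` co-reports and a 95% CI lower bound above 1; PRR requires
#' `min_a` reports, PRR >= 2 and Yates chi-squared >= 4; BCPNN requires
#' IC025 > 0; EBGM requires EBGM05 > 2.
#'
#' @param min_a Minimum co-report count for ROR and PRR (default 3).
#' @param ror_low ROR CI lower-bound threshold (exclusive, default 1).
#' @param prr_min,chi2_min PRR point and chi-squared thresholds.
#' @param ic025_min IC025 threshold (exclusive, default 0).
#' @param ebgm05_min EBGM05 threshold (exclusive, default 2).
#' @return Named list of thresholds.
#' @export
default_thresholds <- function(min_a = 3, ror_low = 1, prr_min = 2,
                               chi2_min = 4, ic025_min = 0, ebgm05_min = 2) {
  list(min_a = min_a, ror_low = ror_low, prr_min = prr_min,
       chi2_min = chi2_min, ic025_min = ic025_min, ebgm05_min = ebgm05_min)
}

subgroup_levels <- c("overall", "M", "F", "<18", "18-45", "46-65", ">65")

filter_subgroup <- function(cases, subgroup) {
  subgroup <- match.arg(subgroup, subgroup_levels)
  switch(subgroup,
         overall = cases,
         M = filter(cases, .data$sex == "M"),
         F = filter(cases, .data$sex == "F"),
         filter(cases, !is.na(.data$age_band) & .data$age_band == subgroup))
}

# distinct (primaryid, term) pairs at the requested level; a report with
# several PTs in one SOC contributes once to that SOC
report_terms <- function(reac, dictionary, level = c("PT", "SOC")) {
  level <- match.arg(level)
  x <- reac |>
    filter(.data$pt %in% dictionary$pt) |>
    distinct(.data$primaryid, .data$pt)
  if (level == "SOC") {
    x <- x |>
      left_join(dictionary, by = "pt") |>
      distinct(.data$primaryid, term = .data$soc)
  } else {
    x <- rename(x, term = "pt")
  }
  x
}

#' Build 2x2 contingency tables for a drug-event screen
#'
#' For every event term at the requested level, counts reports in the 2x2
#' layout of disproportionality analysis: `a` target-drug reports with the
#' event, `b` target-drug reports without it, `c` other-drug reports with
#' it, `d` the remainder; `N = a+b+c+d` is the number of reports in the
#' (subgroup-filtered) deduplicated extract. Counting is report-level — a
#' report contributes at most once per term — and the comparator is the
#' rest of the extract. Subgroup filters apply to all four cells.
#'
#' @param cases Deduplicated case tibble ([case_reports()]); the full
#'   extract, not just the cohort.
#' @param reac Reaction records (`primaryid`, `pt`).
#' @param target_ids `primaryid`s of the target-drug cohort
#'   ([select_primary_suspect()]).
#' @param dictionary PT/SOC dictionary ([load_term_dictionary()]).
#' @param level `"PT"` or `"SOC"`.
#' @param subgroup One of `"overall"`, `"M"`, `"F"`, `"<18"`, `"18-45"`,
#'   `"46-65"`, `">65"`.
#' @param terms Restrict to these terms; default all terms observed
#'   (`a + c >= 1`) at the level.
#' @return Tibble `(term, level, subgroup, a, b, c, d, N)`.
#' @export
contingency_tables <- function(cases, reac, target_ids, dictionary,
                               level = c("PT", "SOC"), subgroup = "overall",
                               terms = NULL) {
  level <- match.arg(level)
  sub <- filter_subgroup(cases, subgroup)
  known_terms <- if (level == "PT") dictionary$pt else unique(dictionary$soc)
  if (!is.null(terms) && any(!terms %in% known_terms)) {
    abort(paste0("unknown term(s): ",
                 paste(setdiff(terms, known_terms), collapse = ", ")))
  }
  if (nrow(sub) == 0) {
    warn(sprintf("subgroup '%s' contains no reports; returning zero tables", subgroup))
    return(tibble(term = terms %||% character(), level = level,
                  subgroup = subgroup, a = 0L, b = 0L, c = 0L, d = 0L, N = 0L))
  }
  rt <- report_terms(reac, dictionary, level) |>
    filter(.data$primaryid %in% sub$primaryid)
  n_total <- nrow(sub)
  n_target <- sum(sub$primaryid %in% target_ids)
  counts <- rt |>
    mutate(is_target = .data$primaryid %in% target_ids) |>
    group_by(.data$term) |>
    summarise(a = sum(.data$is_target), ac = n(), .groups = "drop")
  if (!is.null(terms)) {
    counts <- tibble(term = terms) |>
      left_join(counts, by = "term") |>
      mutate(a = coalesce(.data$a, 0L), ac = coalesce(.data$ac, 0L))
  }
  counts |>
    transmute(
      term = .data$term, level = level, subgroup = subgroup,
      a = as.integer(.data$a),
      b = as.integer(n_target - .data$a),
      c = as.integer(.data$ac - .data$a),
      d = as.integer(n_total - n_target - (.data$ac - .data$a)),
      N = as.integer(n_total)
    ) |>
    arrange(.data$term)
}

#' @rdname contingency_tables
#' @param term A single term (required here).
#' @export
build_contingency <- function(cases, reac, target_ids, dictionary, term,
                              level = c("PT", "SOC"), subgroup = "overall") {
  contingency_tables(cases, reac, target_ids, dictionary, level = level,
                     subgroup = subgroup, terms = term)
}

#' Reporting odds ratio with Wald confidence interval
#'
#' `ROR = (a*d)/(b*c)`, with the two-sided interval
#' `exp(log ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. With a zero cell the
#' estimate is undefined and returned as `NA` unless the Haldane-Anscombe
#' continuity correction (+0.5 to every cell, interval computation only) is
#' enabled.
#'
#' @param a,b,c,d Cell counts (vectorised).
#' @param conf_level Confidence level (default 0.95).
#' @param continuity Apply the +0.5 correction when a cell is zero.
#' @return Tibble `(ror, ror_low, ror_high)`.
#' @examples
#' compute_ror(10, 20, 30, 240)
#' @export
compute_ror <- function(a, b, c, d, conf_level = 0.95, continuity = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  z <- qnorm(1 - (1 - conf_level) / 2)
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  if (continuity) {
    a <- ifelse(zero, a + 0.5, a); b <- ifelse(zero, b + 0.5, b)
    c <- ifelse(zero, c + 0.5, c); d <- ifelse(zero, d + 0.5, d)
    zero <- rep(FALSE, length(a))
  }
  ror <- ifelse(zero, NA_real_, (a * d) / (b * c))
  se <- ifelse(zero, NA_real_, sqrt(1 / a + 1 / b + 1 / c + 1 / d))
  tibble(ror = ror,
         ror_low = exp(log(ror) - z * se),
         ror_high = exp(log(ror) + z * se))
}

#' Proportional reporting ratio with Yates chi-squared
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; the accompanying statistic is the
#' Yates-continuity-corrected Pearson chi-squared of the 2x2 table
#' (matching `stats::chisq.test(correct = TRUE)`).
#'
#' @param a,b,c,d Cell counts (vectorised).
#' @param yates Apply the continuity correction (default `TRUE`).
#' @return Tibble `(prr, chi2)`.
#' @examples
#' compute_prr(10, 20, 30, 240)
#' @export
compute_prr <- function(a, b, c, d, yates = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  prr <- ifelse(a + b > 0 & c + d > 0 & c > 0,
                (a / (a + b)) / (c / (c + d)), NA_real_)
  N <- a + b + c + d
  num <- abs(a * d - b * c)
  if (yates) num <- pmax(0, num - N / 2)
  chi2 <- N * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  chi2[!is.finite(chi2)] <- NA_real_
  tibble(prr = prr, chi2 = chi2)
}

#' BCPNN information component
#'
#' The information component `IC = log2[ a*N / ((a+b)(a+c)) ]` measures
#' observed-versus-expected co-reporting on a base-2 log scale. In the
#' default `"simplified"` mode the point estimate is this closed form and
#' `IC025 = IC - 2*s`, where `s^2` is the Bate et al. variance
#' approximation of the BCPNN posterior (priors `alpha1 = beta1 =
#' gamma11 = 1`, `alpha = beta = 2`, and `gamma` chosen so the prior is
#' centred on independence). The `"full"` mode instead evaluates the
#' Beta/Dirichlet posterior expectations exactly (digamma/trigamma
#' moments of `log p11 - log p1. - log p.1`) and reports
#' `E[IC] - 2*sd[IC]`.
#'
#' @param a,b,c,d Cell counts (vectorised).
#' @param mode `"simplified"` (default) or `"full"`.
#' @return Tibble `(ic, ic025)`.
#' @examples
#' compute_ic(10, 20, 30, 240)
#' @export
compute_ic <- function(a, b, c, d, mode = c("simplified", "full")) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  a1 <- 1; b1 <- 1; g11 <- 1; al <- 2; be <- 2
  gam <- g11 * (N + al) * (N + be) / ((a + b + a1) * (a + c + b1))
  if (mode == "simplified") {
    ic <- log2(a * N / ((a + b) * (a + c)))
    v <- (1 / log(2)^2) * (
      (N - a + gam - g11) / ((a + g11) * (1 + N + gam)) +
      (N - (a + b) + al - a1) / ((a + b + a1) * (1 + N + al)) +
      (N - (a + c) + be - b1) / ((a + c + b1) * (1 + N + be))
    )
    ic025 <- ic - 2 * sqrt(v)
  } else {
    eln <- function(p, q) digamma(p) - digamma(p + q)
    vln <- function(p, q) trigamma(p) - trigamma(p + q)
    e <- (eln(a + g11, N - a + gam - g11) -
          eln(a + b + a1, N - (a + b) + al - a1) -
          eln(a + c + b1, N - (a + c) + be - b1)) / log(2)
    v <- (vln(a + g11, N - a + gam - g11) +
          vln(a + b + a1, N - (a + b) + al - a1) +
          vln(a + c + b1, N - (a + c) + be - b1)) / log(2)^2
    ic <- e
    ic025 <- e - 2 * sqrt(v)
  }
  ic[!is.finite(ic)] <- NA_real_
  ic025[is.na(ic)] <- NA_real_
  tibble(ic = ic, ic025 = ic025)
}

#' Empirical Bayes geometric mean
#'
#' In the default `"simplified"` mode the point estimate is the relative
#' reporting ratio `RRR = a*N / ((a+b)(a+c))` (so that `IC = log2(EBGM)`
#' exactly) and `EBGM05 = EBGM * exp(-1.645 / sqrt(a))`, a lognormal
#' lower 5th-percentile using the leading-order Poisson variance of
#' `log RRR`. The `"mgps"` mode applies the DuMouchel gamma-Poisson
#' shrinker: a two-component gamma mixture prior fitted over all tables of
#' the screen ([fit_mgps()]), posterior geometric mean and exact posterior
#' 5th percentile per table.
#'
#' @param a,b,c,d Cell counts (vectorised).
#' @param mode `"simplified"` (default) or `"mgps"`.
#' @param prior An `mgps_prior` from [fit_mgps()] (required for `"mgps"`).
#' @return Tibble `(ebgm, ebgm05)`.
#' @examples
#' compute_ebgm(10, 20, 30, 240)
#' @export
compute_ebgm <- function(a, b, c, d, mode = c("simplified", "mgps"),
                         prior = NULL) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  E <- (a + b) * (a + c) / N
  if (mode == "simplified") {
    ebgm <- a * N / ((a + b) * (a + c))
    ebgm05 <- ifelse(a > 0, ebgm * exp(-1.645 / sqrt(a)), NA_real_)
    ebgm[a == 0 | !is.finite(ebgm)] <- NA_real_
    return(tibble(ebgm = ebgm, ebgm05 = ebgm05))
  }
  if (is.null(prior)) abort("mgps mode requires a fitted prior; see fit_mgps()")
  mgps_scores(a, E, prior)
}

#' Evaluate the four-method conjunction signal rule
#'
#' Adds the four estimators, per-method positivity flags and the overall
#' signal flag (`positive` is true only when *all four* methods pass their
#' thresholds) to a table of 2x2 counts.
#'
#' @param tables Tibble with columns `a`, `b`, `c`, `d` (e.g. from
#'   [contingency_tables()]).
#' @param thresholds From [default_thresholds()].
#' @param ic_mode,ebgm_mode Estimator variants (see [compute_ic()],
#'   [compute_ebgm()]).
#' @param mgps_prior Optional prefitted [fit_mgps()] prior.
#' @param continuity Passed to [compute_ror()].
#' @return The input with estimator, flag and `positive` columns appended.
#' @export
evaluate_signals <- function(tables, thresholds = default_thresholds(),
                             ic_mode = "simplified", ebgm_mode = "simplified",
                             mgps_prior = NULL, continuity = FALSE) {
  if (ebgm_mode == "mgps" && is.null(mgps_prior)) {
    if (nrow(tables) < 50) {
      warn("mgps mode needs >= 50 tables to identify the prior; falling back to simplified EBGM")
      ebgm_mode <- "simplified"
    } else {
      mgps_prior <- fit_mgps(tables)
    }
  }
  out <- bind_cols(
    tables,
    compute_ror(tables$a, tables$b, tables$c, tables$d, continuity = continuity),
    compute_prr(tables$a, tables$b, tables$c, tables$d),
    compute_ic(tables$a, tables$b, tables$c, tables$d, mode = ic_mode),
    compute_ebgm(tables$a, tables$b, tables$c, tables$d, mode = ebgm_mode,
                 prior = mgps_prior)
  )
  th <- thresholds
  out <- out |>
    mutate(
      ror_flag = .data$a >= th$min_a & !is.na(.data$ror_low) & .data$ror_low > th$ror_low,
      prr_flag = .data$a >= th$min_a & !is.na(.data$prr) & .data$prr >= th$prr_min &
        !is.na(.data$chi2) & .data$chi2 >= th$chi2_min,
      ic_flag = !is.na(.data$ic025) & .data$ic025 > th$ic025_min,
      ebgm_flag = !is.na(.data$ebgm05) & .data$ebgm05 > th$ebgm05_min,
      positive = .data$ror_flag & .data$prr_flag & .data$ic_flag & .data$ebgm_flag
    )
  attr(out, "thresholds") <- th
  attr(out, "modes") <- list(ic = ic_mode, ebgm = ebgm_mode,
                             multiplicity_adjustment = "none")
  out
}

#' Run a disproportionality screen
#'
#' Builds the contingency tables for every term with at least `min_report`
#' target co-report at the requested level and subgroup, computes the four
#' estimators and applies the conjunction rule. Deterministic for fixed
#' input; results are sorted by term.
#'
#' @inheritParams contingency_tables
#' @inheritParams evaluate_signals
#' @param min_report Minimum `a` for a term to appear in the output
#'   (default 1).
#' @return A tibble of signal results (class `signal_screen`), one row per
#'   term, with the counts, the four estimators with their interval bounds,
#'   per-method flags and the overall `positive` flag.
#' @export
screen_signals <- function(cases, reac, target_ids, dictionary,
                           level = c("PT", "SOC"), subgroup = "overall",
                           thresholds = default_thresholds(),
                           ic_mode = "simplified", ebgm_mode = "simplified",
                           continuity = FALSE, min_report = 1) {
  level <- match.arg(level)
  tabs <- contingency_tables(cases, reac, target_ids, dictionary,
                             level = level, subgroup = subgroup) |>
    filter(.data$a >= min_report)
  out <- evaluate_signals(tabs, thresholds = thresholds, ic_mode = ic_mode,
                          ebgm_mode = ebgm_mode, continuity = continuity) |>
    arrange(.data$term)
  class(out) <- c("signal_screen", class(out))
  out
}
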