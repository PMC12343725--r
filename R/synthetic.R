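#' Configuration for the synthetic report generator
#'
#' Defines a FAERS-like population with known ground truth. Reports carry
#' one primary-suspect (PS) drug — the target drug in a configurable share
#' of cases — plus concomitant medications, demographic fields with
#' realistic missingness, multi-version duplicate records, therapy-start
#' and event dates with Weibull-distributed onset intervals, and adverse
#' events drawn per preferred term. A *planted signal* inflates the
#' per-case probability of one PT among target-exposed cases so that the
#' report-level relative reporting ratio `a*N / ((a+b)(a+c))` equals `rrr`
#' in expectation: the exposed-case probability is
#' `p1 = rrr*(1-f)*bg / (1 - rrr*f)` where `f` is the target share and `bg`
#' the background rate (the naive `rrr*bg` overshoots the margin). Configs
#' where this exceeds 1, or where `rrr*f >= 1`, are infeasible and abort.
#'
#' @param n_cases Number of distinct cases.
#' @param seed Integer seed; generation is fully reproducible.
#' @param target_drug Normalised name of the drug under study.
#' @param target_share Fraction of cases with the target as PS drug.
#' @param comparator_drugs PS drug names for the rest of the database.
#' @param comedications Vocabulary for concomitant (role `C`) drugs.
#' @param dictionary PT/SOC dictionary tibble ([load_term_dictionary()]).
#' @param background_rate Named per-PT event probabilities; default assigns
#'   rates between 0.002 and 0.05 cyclically over the dictionary.
#' @param planted_signals Tibble with columns `pt`, `rrr`, `fatal_prob`,
#'   `shape`, `scale` (onset Weibull, days) — one row per planted pair.
#' @param onset_shape,onset_scale Background onset Weibull parameters
#'   (days); the default 0.9/150 mimics the early-skewed onset profile of
#'   spontaneous reports.
#' @param sex_probs,countries,occupations Named sampling distributions
#'   (must each sum to 1); `unknown`/`missing` categories emit blanks.
#' @param age_mean,age_sd,age_missing Age model (years) and missing rate.
#' @param death_rate Background probability of a death (`DE`) outcome.
#' @param outcome_rate Probability of a non-death outcome code.
#' @param event_dt_missing,start_dt_missing Fractions of event/therapy
#'   dates blanked.
#' @param event_dt_partial Fraction of non-missing event dates emitted at
#'   month precision only.
#' @param duplicate_rate Fraction of cases that also carry an earlier
#'   version record (exercises deduplication).
#' @param window_start,window_end Study window (Dates).
#' @return A `synthetic_config` list, validated.
#' @export
synthetic_config <- function(n_cases = 10000,
                             seed = 1,
                             target_drug = "DOLUTEGRAVIR",
                             target_share = 0.05,
                             comparator_drugs = c(
                               "EFAVIRENZ", "RALTEGRAVIR", "BICTEGRAVIR",
                               "DARUNAVIR", "RILPIVIRINE", "ATAZANAVIR",
                               "METFORMIN", "ATORVASTATIN", "LISINOPRIL",
                               "OMEPRAZOLE", "IBUPROFEN", "AMOXICILLIN",
                               "SERTRALINE", "LEVOTHYROXINE", "AMLODIPINE"),
                             comedications = c(
                               "LAMIVUDINE", "TRUVADA",
                               "TENOFOVIR DISOPROXIL FUMARATE", "ABACAVIR",
                               "EMTRICITABINE", "RITONAVIR"),
                             dictionary = load_term_dictionary(),
                             background_rate = NULL,
                             planted_signals = empty_planted(),
                             onset_shape = 0.9, onset_scale = 150,
                             sex_probs = c(M = 0.50, F = 0.30, unknown = 0.20),
                             age_mean = 45, age_sd = 15, age_missing = 0.35,
                             countries = c(US = 0.55, JP = 0.08, FR = 0.06,
                                           GB = 0.05, IT = 0.03, BR = 0.05,
                                           ZA = 0.08, missing = 0.10),
                             occupations = c(CN = 0.45, MD = 0.25, OT = 0.14,
                                             PH = 0.10, HP = 0.04, LW = 0.001,
                                             missing = 0.019),
                             death_rate = 0.02,
                             outcome_rate = 0.5,
                             event_dt_missing = 0.30,
                             start_dt_missing = 0.20,
                             event_dt_partial = 0.10,
                             duplicate_rate = 0.05,
                             window_start = as.Date("2013-10-01"),
                             window_end = as.Date("2024-12-31")) {
  background_rate <- background_rate %||% default_background_rates(dictionary$pt)
  cfg <- list(
    n_cases = as.integer(n_cases), seed = as.integer(seed),
    target_drug = target_drug, target_share = target_share,
    comparator_drugs = comparator_drugs, comedications = comedications,
    dictionary = dictionary, background_rate = background_rate,
    planted_signals = as_tibble(planted_signals),
    onset_shape = onset_shape, onset_scale = onset_scale,
    sex_probs = sex_probs, age_mean = age_mean, age_sd = age_sd,
    age_missing = age_missing, countries = countries,
    occupations = occupations, death_rate = death_rate,
    outcome_rate = outcome_rate,
    event_dt_missing = event_dt_missing, start_dt_missing = start_dt_missing,
    event_dt_partial = event_dt_partial, duplicate_rate = duplicate_rate,
    window_start = window_start, window_end = window_end
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

empty_planted <- function() {
  tibble(pt = character(), rrr = numeric(), fatal_prob = numeric(),
         shape = numeric(), scale = numeric())
}

default_background_rates <- function(pts) {
  rates <- rep(c(0.03, 0.008, 0.02, 0.004, 0.012, 0.002, 0.05, 0.006),
               length.out = length(pts))
  setNames(rates, pts)
}

validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$n_cases > 0, cfg$target_share > 0, cfg$target_share < 1,
            cfg$onset_shape > 0, cfg$onset_scale > 0)
  for (nm in c("sex_probs", "countries", "occupations")) {
    p <- cfg[[nm]]
    if (any(p < 0 | p > 1) || abs(sum(p) - 1) > 1e-8) {
      abort(paste0(nm, " must be probabilities summing to 1"))
    }
  }
  rates <- c(cfg$age_missing, cfg$event_dt_missing, cfg$start_dt_missing,
             cfg$event_dt_partial, cfg$duplicate_rate, cfg$death_rate,
             cfg$outcome_rate, cfg$background_rate)
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  ps <- cfg$planted_signals
  if (nrow(ps) > 0) {
    stopifnot(all(c("pt", "rrr", "fatal_prob", "shape", "scale") %in% names(ps)))
    if (any(!ps$pt %in% cfg$dictionary$pt)) abort("planted PT not in dictionary")
    if (any(ps$rrr <= 0 | ps$shape <= 0 | ps$scale <= 0)) {
      abort("planted rrr, shape and scale must be positive")
    }
    if (any(ps$fatal_prob < 0 | ps$fatal_prob > 1)) abort("fatal_prob must be in [0, 1]")
    p1 <- planted_exposed_prob(ps$rrr, cfg$background_rate[ps$pt], cfg$target_share)
    if (any(!is.finite(p1) | p1 <= 0 | p1 > 1)) {
      abort("infeasible planted signal: implied exposed-case event probability outside (0, 1]")
    }
  }
  invisible(cfg)
}

# exact tilt so the report-level relative reporting ratio equals rrr
planted_exposed_prob <- function(rrr, bg, f) {
  ifelse(rrr * f >= 1, NA_real_, rrr * (1 - f) * bg / (1 - rrr * f))
}

#' Generate a synthetic FAERS-style dataset with known ground truth
#'
#' Emits a `faers_quarter` (the seven tables in the dialect written by
#' [write_faers_quarter()]) and a ground-truth record of the planted
#' drug-event pairs, their tilted probabilities and the continuous onset
#' intervals actually drawn. Fixed seed implies byte-identical output.
#'
#' @param config A [synthetic_config()].
#' @return List with elements `quarter` (a `faers_quarter`) and `truth`.
#' @examples
#' cfg <- synthetic_config(n_cases = 500, seed = 42)
#' sim <- generate_faers(cfg)
#' sim$quarter
#' @export
generate_faers <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_faers_impl(config))
}

generate_faers_impl <- function(cfg) {
  n <- cfg$n_cases
  dict <- cfg$dictionary
  pts <- dict$pt
  bg <- cfg$background_rate[pts]
  ps <- cfg$planted_signals

  caseid <- sprintf("%09d", 100000000 + seq_len(n))
  primaryid <- paste0(caseid, "2") # version-2 records

  n_t <- max(1L, round(n * cfg$target_share))
  target_idx <- sort(sample.int(n, n_t))
  is_target <- rep(FALSE, n); is_target[target_idx] <- TRUE
  f <- n_t / n

  drugname <- character(n)
  drugname[is_target] <- cfg$target_drug
  drugname[!is_target] <- sample(cfg$comparator_drugs, n - n_t, replace = TRUE)

  # per-PT event draws; planted PTs use the tilted probability for exposed cases
  p1 <- if (nrow(ps) > 0) planted_exposed_prob(ps$rrr, bg[ps$pt], f) else numeric()
  event_mat <- matrix(FALSE, n, length(pts), dimnames = list(NULL, pts))
  for (j in seq_along(pts)) {
    p <- rep(bg[j], n)
    k <- match(pts[j], ps$pt)
    if (!is.na(k)) p[is_target] <- p1[k]
    event_mat[, j] <- runif(n) < p
  }
  # guarantee >= 1 event per report using the commonest non-planted PT
  fallback_pt <- names(sort(bg[setdiff(pts, ps$pt)], decreasing = TRUE))[1]
  none <- rowSums(event_mat) == 0
  event_mat[none, fallback_pt] <- TRUE

  has_planted <- if (nrow(ps) > 0) {
    is_target & rowSums(event_mat[, ps$pt, drop = FALSE]) > 0
  } else rep(FALSE, n)

  # outcomes: planted pairs get the configured fatality probability
  fatal_p <- rep(cfg$death_rate, n)
  if (nrow(ps) > 0) {
    for (k in seq_len(nrow(ps))) {
      hit <- is_target & event_mat[, ps$pt[k]]
      fatal_p[hit] <- pmax(fatal_p[hit], ps$fatal_prob[k])
    }
  }
  died <- runif(n) < fatal_p
  other_out <- runif(n) < cfg$outcome_rate
  out_codes <- sample(c("HO", "OT", "LT", "DS", "CA", "RI"), n, replace = TRUE,
                      prob = c(0.35, 0.40, 0.08, 0.05, 0.08, 0.04))

  # dates: therapy start uniform in the window; onset Weibull; receipt lag
  span <- as.integer(cfg$window_end - cfg$window_start)
  start_date <- cfg$window_start + floor(runif(n) * (span - 60))
  onset <- rweibull(n, cfg$onset_shape, cfg$onset_scale)
  if (nrow(ps) > 0) {
    for (k in seq_len(nrow(ps))) {
      hit <- which(is_target & event_mat[, ps$pt[k]])
      onset[hit] <- rweibull(length(hit), ps$shape[k], ps$scale[k])
    }
  }
  event_date <- pmin(start_date + round(onset), cfg$window_end)
  fda_date <- pmin(event_date + floor(runif(n) * 180), cfg$window_end)

  sex <- sample_coded(cfg$sex_probs, n, blank = "unknown")
  age <- round(pmin(pmax(rnorm(n, cfg$age_mean, cfg$age_sd), 0), 100))
  age_chr <- ifelse(runif(n) < cfg$age_missing, "", as.character(age))
  age_cod <- ifelse(age_chr == "", "", "YR")
  country <- sample_coded(cfg$countries, n, blank = "missing")
  occp <- sample_coded(cfg$occupations, n, blank = "missing")

  event_dt <- compact_date(event_date)
  partial <- runif(n) < cfg$event_dt_partial
  event_dt[partial] <- substr(event_dt[partial], 1, 6)
  event_dt[runif(n) < cfg$event_dt_missing] <- ""
  start_dt <- compact_date(start_date)
  start_dt[runif(n) < cfg$start_dt_missing] <- ""

  demo <- tibble(
    primaryid = primaryid, caseid = caseid, caseversion = "2",
    fda_dt = compact_date(fda_date), event_dt = event_dt,
    age = age_chr, age_cod = age_cod, sex = sex,
    occr_country = country, occp_cod = occp
  )

  drug <- tibble(primaryid = primaryid, caseid = caseid, drug_seq = "1",
                 role_cod = "PS", drugname = drugname)
  n_co <- sample(0:3, n, replace = TRUE, prob = c(0.35, 0.3, 0.2, 0.15))
  co_idx <- rep(seq_len(n), n_co)
  if (length(co_idx) > 0) {
    co <- tibble(
      primaryid = primaryid[co_idx], caseid = caseid[co_idx],
      drug_seq = as.character(unlist(lapply(n_co[n_co > 0], function(k) 1 + seq_len(k)))),
      role_cod = "C",
      drugname = sample(cfg$comedications, length(co_idx), replace = TRUE)
    )
    drug <- bind_rows(drug, co)
  }

  which_evt <- which(event_mat, arr.ind = TRUE)
  reac <- tibble(primaryid = primaryid[which_evt[, 1]],
                 caseid = caseid[which_evt[, 1]],
                 pt = pts[which_evt[, 2]]) |>
    arrange(.data$primaryid, .data$pt)

  outc <- bind_rows(
    tibble(primaryid = primaryid[died], caseid = caseid[died], outc_cod = "DE"),
    tibble(primaryid = primaryid[other_out], caseid = caseid[other_out],
           outc_cod = out_codes[other_out])
  ) |> arrange(.data$primaryid, .data$outc_cod)

  rpsr <- tibble(primaryid = primaryid, caseid = caseid,
                 rpsr_cod = sample(c("FGN", "HP", "CSM"), n, replace = TRUE))
  ther <- tibble(primaryid = primaryid, caseid = caseid, dsg_drug_seq = "1",
                 start_dt = start_dt, end_dt = "")
  indi <- tibble(primaryid = primaryid, caseid = caseid, indi_drug_seq = "1",
                 indi_pt = ifelse(is_target,
                                  sample(c("HIV infection",
                                           "Product used for unknown indication"),
                                         n, replace = TRUE, prob = c(0.7, 0.3)),
                                  sample(c("Hypertension", "Product used for unknown indication",
                                           "HIV infection"), n, replace = TRUE,
                                         prob = c(0.4, 0.4, 0.2))))

  # earlier-version duplicates (exercise deduplication); their drug/reac rows
  # are also emitted under the superseded primaryid, as in the live database
  n_dup <- floor(cfg$duplicate_rate * n)
  if (n_dup > 0) {
    di <- sort(sample.int(n, n_dup))
    old_pid <- paste0(caseid[di], "1")
    old_fda <- pmax(fda_date[di] - sample(30:200, n_dup, replace = TRUE),
                    cfg$window_start)
    demo_old <- demo[di, ]
    demo_old$primaryid <- old_pid
    demo_old$caseversion <- "1"
    demo_old$fda_dt <- compact_date(old_fda)
    demo <- bind_rows(demo, demo_old) |> arrange(.data$primaryid)
    drug_old <- tibble(primaryid = old_pid, caseid = caseid[di],
                       drug_seq = "1", role_cod = "PS", drugname = drugname[di])
    drug <- bind_rows(drug, drug_old)
    reac_old <- tibble(primaryid = old_pid, caseid = caseid[di],
                       pt = pts[max.col(event_mat[di, , drop = FALSE], "first")])
    reac <- bind_rows(reac, reac_old)
  }
  drug <- arrange(drug, .data$primaryid, as.numeric(.data$drug_seq))
  reac <- arrange(reac, .data$primaryid, .data$pt)

  quarter <- new_faers_quarter(
    list(demo = demo, drug = drug, reac = reac, outc = outc,
         rpsr = rpsr, ther = ther, indi = indi),
    quarter = "2024Q4"
  )

  planted_truth <- if (nrow(ps) > 0) mutate(ps, exposed_prob = p1) else
    mutate(ps, exposed_prob = numeric(0))
  onset_truth <- if (nrow(ps) > 0) {
    hit <- which(has_planted)
    tibble(primaryid = primaryid[hit], onset_days = onset[hit])
  } else tibble(primaryid = character(), onset_days = numeric())

  truth <- list(
    seed = cfg$seed, n_cases = n, target_drug = cfg$target_drug,
    target_share = f, target_primaryids = primaryid[is_target],
    planted = planted_truth, planted_onsets = onset_truth,
    fallback_pt = fallback_pt
  )
  list(quarter = quarter, truth = truth)
}

sample_coded <- function(probs, n, blank) {
  x <- sample(names(probs), n, replace = TRUE, prob = probs)
  x[x == blank] <- ""
  x
}

compact_date <- function(d) format(d, "%Y%m%d")

#' Write the generator ground truth as a JSON sidecar
#'
#' @param truth The `truth` element returned by [generate_faers()].
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
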