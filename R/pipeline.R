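#' Configuration for a full pipeline run
#'
#' Bundles everything a run needs: either a directory with a FAERS-style
#' extract or a [synthetic_config()], the target-drug synonym set, the term
#' dictionary and DME/IME lists, thresholds, subgroup selections, estimator
#' modes, the output directory and the seed. All referenced files are
#' checked at validation time, before any computation.
#'
#' @param out_dir Output directory for the report bundle.
#' @param input Path to a quarterly extract directory, or `NULL` to
#'   generate data from `synthetic`.
#' @param synthetic A [synthetic_config()] (required when `input` is NULL).
#' @param synonyms Target-drug synonym tibble ([dtg_synonyms()]).
#' @param dictionary_path,dme_path,ime_path Paths to the term dictionary
#'   and event lists (`NULL` for the bundled toy versions).
#' @param deleted_cases_path Optional deleted-case list (one caseid per
#'   line).
#' @param thresholds [default_thresholds()].
#' @param subgroups Subgroups to screen in addition to `"overall"`.
#' @param levels Screening levels (`"PT"`, `"SOC"`).
#' @param ic_mode,ebgm_mode Estimator variants.
#' @param seed Integer seed recorded in all outputs.
#' @return A validated `run_config`.
#' @export
run_config <- function(out_dir,
                       input = NULL,
                       synthetic = NULL,
                       synonyms = dtg_synonyms(),
                       dictionary_path = NULL,
                       dme_path = NULL, ime_path = NULL,
                       deleted_cases_path = NULL,
                       thresholds = default_thresholds(),
                       subgroups = c("M", "F", "<18", "18-45", "46-65", ">65"),
                       levels = c("PT", "SOC"),
                       ic_mode = "simplified", ebgm_mode = "simplified",
                       seed = 1) {
  if (is.null(input) && is.null(synthetic)) {
    abort("run_config needs either an input path or a synthetic_config")
  }
  for (p in c(input, dictionary_path, dme_path, ime_path, deleted_cases_path)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(paste0("configured path does not exist: ", p))
    }
  }
  stopifnot(all(subgroups %in% subgroup_levels), all(levels %in% c("PT", "SOC")))
  structure(list(
    out_dir = out_dir, input = input, synthetic = synthetic,
    synonyms = synonyms, dictionary_path = dictionary_path,
    dme_path = dme_path, ime_path = ime_path,
    deleted_cases_path = deleted_cases_path, thresholds = thresholds,
    subgroups = unique(c("overall", subgroups)), levels = levels,
    ic_mode = ic_mode, ebgm_mode = ebgm_mode, seed = as.integer(seed)
  ), class = "run_config")
}

#' Run the full screening pipeline
#'
#' Executes ingest (or synthesis) -> deduplication -> cohort selection and
#' description -> disproportionality screens (requested levels and
#' subgroups) -> clinical prioritisation -> time-to-onset analysis, and
#' writes a report bundle: CSV tables for the cohort summary, every
#' screen, the priority table and the onset records/curves, plus a JSON
#' manifest recording versions, seed, configuration hash and the record
#' counts at every stage. Any stage failure aborts with the stage name and
#' removes partial outputs. Reruns with the same configuration and seed
#' are byte-identical.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly; the bundle is written to
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  stage <- "setup"
  manifest <- list(
    package = "faersignal",
    version = as.character(utils::packageVersion("faersignal")),
    r_version = R.version.string,
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    counts = list()
  )
  emit <- function(x, name) {
    path <- file.path(config$out_dir, name)
    readr::write_lines(sprintf("# faersignal %s | seed %d | %s",
                               manifest$version, config$seed,
                               manifest$config_hash), path)
    readr::write_csv(x, path, append = TRUE, col_names = TRUE)
    written <<- c(written, path)
    path
  }

  result <- tryCatch({
    stage <- "ingest"
    if (!is.null(config$input)) {
      quarter <- read_faers_quarter(config$input)
      truth <- NULL
    } else {
      sim <- generate_faers(config$synthetic)
      quarter <- sim$quarter
      truth <- sim$truth
    }
    dictionary <- load_term_dictionary(config$dictionary_path)
    lists <- load_event_lists(config$dme_path, config$ime_path)
    deleted <- if (!is.null(config$deleted_cases_path)) {
      read_term_list(config$deleted_cases_path)
    } else character()
    manifest$counts$raw_demo <- nrow(quarter$demo)

    stage <- "deduplicate"
    cases <- case_reports(quarter, deleted)
    manifest$counts$deduplicated <- nrow(cases)
    inform(sprintf("deduplicate: %d raw demo records -> %d cases",
                   nrow(quarter$demo), nrow(cases)))

    stage <- "cohort"
    target_ids <- select_primary_suspect(quarter$drug, config$synonyms)
    target_ids <- intersect(target_ids, cases$primaryid)
    if (length(target_ids) == 0) abort("primary-suspect cohort is empty")
    cohort_cases <- filter(cases, .data$primaryid %in% target_ids)
    summary <- summarize_cohort(cohort_cases, quarter$drug, quarter$reac,
                                quarter$outc, quarter$indi)
    manifest$counts$cohort_cases <- summary$n_cases
    manifest$counts$cohort_events <- summary$n_events
    emit(generics::tidy(summary), "cohort_summary.csv")
    emit(summary$yearly, "report_trend.csv")
    emit(comedication_counts(cohort_cases, quarter$drug, config$synonyms),
         "comedications.csv")

    stage <- "screen"
    screens <- list()
    for (lv in config$levels) {
      for (sg in config$subgroups) {
        sc <- screen_signals(cases, quarter$reac, target_ids, dictionary,
                             level = lv, subgroup = sg,
                             thresholds = config$thresholds,
                             ic_mode = config$ic_mode,
                             ebgm_mode = config$ebgm_mode)
        screens[[paste(lv, sg, sep = ":")]] <- sc
        emit(as_tibble(sc),
             sprintf("signals_%s_%s.csv", lv, gsub("[<>]", "", sg)))
      }
    }
    n_pos <- sum(purrr::map_int(screens, ~ sum(.x$positive)))
    manifest$counts$screens <- length(screens)
    manifest$counts$positive_signals <- n_pos

    stage <- "prioritize"
    priorities <- purrr::imap_dfr(
      screens[grepl("^PT:", names(screens))],
      function(sc, key) {
        prioritize_signals(sc, quarter$reac, quarter$outc, target_ids,
                           lists, cases = cases)
      })
    manifest$counts$prioritized <- nrow(priorities)
    manifest$counts$high_priority <- sum(priorities$band == "high")
    manifest$counts$moderate_priority <- sum(priorities$band == "moderate")
    emit(as_tibble(priorities), "priorities.csv")

    stage <- "tto"
    onsets <- extract_tto(cohort_cases, quarter$ther, quarter$drug,
                          config$synonyms, outc = quarter$outc,
                          lists = lists, reac = quarter$reac)
    manifest$counts$tto_included <- nrow(onsets)
    manifest$counts$tto_excluded <- sum(attr(onsets, "exclusions")$n)
    emit(as_tibble(onsets), "tto_records.csv")
    emit(attr(onsets, "exclusions"), "tto_exclusions.csv")
    if (nrow(onsets) >= 30) {
      fit <- fit_weibull_tto(onsets$onset_days)
      emit(generics::glance(fit), "tto_weibull.csv")
      curve <- km_curve(onsets$onset_days)
      emit(as_tibble(curve), "tto_km_curve.csv")
      manifest$tto_classification <- fit$classification
    }

    stage <- "manifest"
    manifest$outputs <- basename(written)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest
  }, error = function(e) {
    unlink(written)
    abort(sprintf("pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)))
  })
  invisible(result)
}
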