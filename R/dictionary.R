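#' Load a preferred-term to system-organ-class dictionary
#'
#' The dictionary maps each event preferred term (PT) to its primary system
#' organ class (SOC), the two levels at which signal screening runs. MedDRA
#' itself is licensed and must be supplied by the user as a two-column CSV
#' (`pt,soc`); with `path = NULL` a small synthetic stand-in dictionary
#' shipped with the package (~57 PTs across 12 SOCs) is loaded, which is
#' what the synthetic generator and the test-suite use.
#'
#' @param path CSV file with columns `pt` and `soc`, or `NULL` for the
#'   bundled toy dictionary.
#' @return Tibble with columns `pt`, `soc`.
#' @export
load_term_dictionary <- function(path = NULL) {
  path <- path %||% system.file("extdata", "toy_meddra.csv", package = "faersignal")
  stopifnot(file.exists(path))
  dict <- readr::read_csv(path, col_types = "cc", progress = FALSE)
  if (!all(c("pt", "soc") %in% names(dict))) {
    abort("term dictionary must have columns 'pt' and 'soc'")
  }
  if (anyDuplicated(dict$pt)) abort("term dictionary maps some PT to more than one SOC")
  dict
}

#' Load designated/important medical event term lists
#'
#' Reads one-term-per-line files for the designated medical events (DME) and
#' important medical events (IME) used by the clinical-priority rubric. The
#' regulatory lists are licensed and user-supplied; `NULL` loads small
#' synthetic stand-in lists bundled for testing. A term on both lists is
#' treated as DME (the higher relevance).
#'
#' @param dme_path,ime_path Paths to plain-text term lists, or `NULL` for
#'   the bundled toy lists.
#' @return List with character vectors `dme` and `ime`.
#' @export
load_event_lists <- function(dme_path = NULL, ime_path = NULL) {
  dme_path <- dme_path %||% system.file("extdata", "toy_dme.txt", package = "faersignal")
  ime_path <- ime_path %||% system.file("extdata", "toy_ime.txt", package = "faersignal")
  list(dme = read_term_list(dme_path), ime = read_term_list(ime_path))
}

#' Read a one-term-per-line list file
#'
#' @param path Text file, one PT per line; blank lines and lines starting
#'   with `#` are ignored.
#' @return Character vector of terms.
#' @export
read_term_list <- function(path) {
  if (!file.exists(path)) abort(paste0("term list file not found: ", path))
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}
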