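# Hand-built miniature quarter used by IO and cohort tests. Three cases:
#  - C1: target drug PS, two events, death outcome, clean day-precision dates
#  - C2: target drug concomitant only (not cohort)
#  - C3: comparator drug PS
tiny_quarter <- function() {
  demo <- tibble::tibble(
    primaryid = c("112", "212", "312"),
    caseid = c("11", "21", "31"),
    caseversion = c("2", "2", "2"),
    fda_dt = c("20200401", "20200501", "20200601"),
    event_dt = c("20200315", "202003", ""),
    age = c("30", "5", "70"),
    age_cod = c("YR", "DEC", "YR"),
    sex = c("F", "M", ""),
    occr_country = c("US", "JP", ""),
    occp_cod = c("MD", "CN", "")
  )
  drug <- tibble::tibble(
    primaryid = c("112", "112", "212", "312"),
    caseid = c("11", "11", "21", "31"),
    drug_seq = c("1", "2", "1", "1"),
    role_cod = c("PS", "C", "C", "PS"),
    drugname = c("DOLUTEGRAVIR", "LAMIVUDINE", "dolutegravir sodium ", "EFAVIRENZ")
  )
  reac <- tibble::tibble(
    primaryid = c("112", "112", "212", "312"),
    caseid = c("11", "11", "21", "31"),
    pt = c("Nausea", "Hepatic necrosis", "Headache", "Nausea")
  )
  outc <- tibble::tibble(
    primaryid = c("112"), caseid = c("11"), outc_cod = c("DE")
  )
  rpsr <- tibble::tibble(
    primaryid = c("112", "212", "312"), caseid = c("11", "21", "31"),
    rpsr_cod = c("HP", "CSM", "FGN")
  )
  ther <- tibble::tibble(
    primaryid = c("112", "312"), caseid = c("11", "31"),
    dsg_drug_seq = c("1", "1"),
    start_dt = c("20200101", "20200520"), end_dt = c("", "")
  )
  indi <- tibble::tibble(
    primaryid = c("112", "312"), caseid = c("11", "31"),
    indi_drug_seq = c("1", "1"),
    indi_pt = c("HIV infection", "Hypertension")
  )
  faersignal:::new_faers_quarter(
    list(demo = demo, drug = drug, reac = reac, outc = outc,
         rpsr = rpsr, ther = ther, indi = indi),
    quarter = "2020Q2"
  )
}

# standard planted-signal configuration used by several suites: one
# drug-event pair at relative reporting ratio 10 with expected a near 40
planted_config <- function(seed, n_cases = 10000, rrr = 10) {
  rates <- faersignal:::default_background_rates(load_term_dictionary()$pt)
  rates["Hepatic necrosis"] <- 0.004
  synthetic_config(
    n_cases = n_cases, seed = seed, background_rate = rates,
    planted_signals = tibble::tibble(
      pt = "Hepatic necrosis", rrr = rrr, fatal_prob = 0.4,
      shape = 0.6, scale = 100
    )
  )
}

null_config <- function(seed, n_cases = 10000) {
  synthetic_config(n_cases = n_cases, seed = seed)
}

run_screen <- function(sim, level = "PT", subgroup = "overall", ...) {
  cases <- case_reports(sim$quarter)
  ids <- select_primary_suspect(sim$quarter$drug, dtg_synonyms())
  screen_signals(cases, sim$quarter$reac, ids, load_term_dictionary(),
                 level = level, subgroup = subgroup, ...)
}
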