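all_pos <- function() list(ror = TRUE, prr = TRUE, ic = TRUE, ebgm = TRUE)

score_row <- function(a, fatal, denom, dme = TRUE, ime = FALSE) {
  priority_components(a, fatal, denom, TRUE, TRUE, TRUE, TRUE,
                      dme = dme, ime = ime)
}

test_that("the rubric reproduces designated-medical-event scores from row inputs", {
  # overall analysis: denominator is the drug-level adverse-event total
  pml <- score_row(24, 10, 32383)
  expect_equal(unlist(pml[1, 1:4], use.names = FALSE), c(0, 2, 1, 2))
  expect_equal(pml$total, 5); expect_equal(as.character(pml$band), "moderate")
  expect_equal(score_row(174, 15, 32383)$total, 4)   # fatal 8.62% < 25%
  expect_equal(score_row(72, 7, 32383)$total, 4)
  expect_equal(score_row(65, 3, 32383)$total, 4)
  expect_equal(score_row(11, 3, 32383)$total, 5)     # fatal 27.27% in [25,50]
  # subgroup rows with fatal proportion above 50% reach high priority
  for (row in list(c(9, 5), c(3, 2), c(4, 3))) {
    s <- score_row(row[1], row[2], 10000)
    expect_equal(s$total, 6)
    expect_equal(as.character(s$band), "high")
  }
  # subgroup renal failure: reporting rate in (1, 10] adds the extra point
  rf <- score_row(61, 5, 5000)
  expect_equal(rf$rate_points, 1)
  expect_equal(rf$total, 5)
})

test_that("a non-listed, non-fatal, rare term scores low", {
  s <- priority_components(5, 0, 1000, TRUE, TRUE, TRUE, TRUE,
                           dme = FALSE, ime = FALSE)
  expect_equal(s$total, 2)
  expect_equal(as.character(s$band), "low")
})

test_that("boundary conventions: 25%/50% fatality score 1, 1%/10% rate score 0/1", {
  expect_equal(score_row(4, 1, 100000)$fatality_points, 1)   # exactly 25%
  expect_equal(score_row(4, 2, 100000)$fatality_points, 1)   # exactly 50%
  expect_equal(score_row(4, 3, 100000)$fatality_points, 2)   # 75%
  expect_equal(score_row(10, 0, 1000)$rate_points, 0)        # exactly 1%
  expect_equal(score_row(100, 0, 1000)$rate_points, 1)       # exactly 10%
  expect_equal(score_row(101, 0, 1000)$rate_points, 2)
})

test_that("stability maps the four flags onto three analysis families", {
  base <- function(...) priority_components(50, 0, 100000, ..., dme = FALSE,
                                            ime = FALSE)$stability_points
  expect_equal(base(TRUE, TRUE, TRUE, TRUE), 2)    # 3 of 3
  expect_equal(base(TRUE, TRUE, TRUE, FALSE), 1)   # Bayesian family broken
  expect_equal(base(TRUE, TRUE, FALSE, FALSE), 1)  # 2 of 3
  expect_equal(base(TRUE, FALSE, FALSE, FALSE), 0) # 1 of 3
  expect_equal(base(FALSE, FALSE, FALSE, FALSE), 0)
})

test_that("band boundaries hold over all component combinations", {
  g <- expand.grid(r = 0:2, s = 0:2, f = 0:2, c = 0:2)
  total <- g$r + g$s + g$f + g$c
  band <- priority_band(total)
  expect_equal(as.character(band[total <= 2]),
               rep("low", sum(total <= 2)))
  expect_equal(as.character(band[total >= 3 & total <= 5]),
               rep("moderate", sum(total >= 3 & total <= 5)))
  expect_equal(as.character(band[total >= 6]),
               rep("high", sum(total >= 6)))
})

test_that("total score is monotone in fatal count and report count", {
  t_by_fatal <- sapply(0:10, function(f) score_row(10, f, 10000)$total)
  expect_true(all(diff(t_by_fatal) >= 0))
  t_by_a <- sapply(c(5, 50, 500, 5000), function(a)
    priority_components(a, 0, 10000, TRUE, TRUE, TRUE, TRUE,
                        dme = TRUE, ime = FALSE)$total)
  expect_true(all(diff(t_by_a) >= 0))
})

test_that("impossible inputs are rejected", {
  expect_error(score_row(5, 6, 1000), "exceed")
  expect_error(score_row(5, 1, 0), "positive")
})

test_that("prioritize annotates positive signals and orders by band then score", {
  sim <- generate_faers(planted_config(seed = 21, n_cases = 8000))
  q <- sim$quarter
  cases <- case_reports(q)
  ids <- select_primary_suspect(q$drug, dtg_synonyms())
  sc <- screen_signals(cases, q$reac, ids, load_term_dictionary())
  pr <- prioritize_signals(sc, q$reac, q$outc, ids, load_event_lists(),
                           cases = cases)
  expect_true(all(pr$positive))
  expect_true("Hepatic necrosis" %in% pr$term)
  hn <- pr[pr$term == "Hepatic necrosis", ]
  expect_equal(hn$relevance_points, 2)    # on the DME list
  expect_equal(hn$stability_points, 2)    # all four methods positive
  expect_lte(hn$fatal_count, hn$a)
  # ordering: high before moderate before low, then descending totals
  expect_true(!is.unsorted(rev(as.integer(pr$band))))
  # empty input stays empty but typed
  none <- prioritize_signals(dplyr::filter(sc, FALSE), q$reac, q$outc, ids,
                             load_event_lists(), cases = cases)
  expect_equal(nrow(none), 0)
  expect_true(all(c("total", "band") %in% names(none)))
})
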