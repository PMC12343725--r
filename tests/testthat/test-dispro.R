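test_that("the four estimators reproduce hand-computed values on (10,20,30,240)", {
  # ROR = 10*240/(20*30) = 4; CI = exp(log 4 +/- 1.96*sqrt(1/10+1/20+1/30+1/240))
  r <- compute_ror(10, 20, 30, 240)
  expect_equal(r$ror, 4)
  se <- sqrt(1 / 10 + 1 / 20 + 1 / 30 + 1 / 240) # = sqrt(0.1875)
  expect_equal(r$ror_low, exp(log(4) - qnorm(0.975) * se), tolerance = 1e-12)
  expect_equal(r$ror_high, exp(log(4) + qnorm(0.975) * se), tolerance = 1e-12)
  expect_equal(round(c(r$ror_low, r$ror_high), 2), c(1.71, 9.35))
  # PRR = (10/30)/(30/270) = 3; chi2 must match the textbook Yates statistic
  p <- compute_prr(10, 20, 30, 240)
  expect_equal(p$prr, 3)
  oracle <- suppressWarnings(
    stats::chisq.test(matrix(c(10, 20, 30, 240), 2), correct = TRUE))
  expect_equal(p$chi2, unname(oracle$statistic), tolerance = 1e-12)
  # RRR = 10*300/(30*40) = 2.5 drives both Bayesian point estimates
  expect_equal(compute_ic(10, 20, 30, 240)$ic, log2(2.5), tolerance = 1e-12)
  e <- compute_ebgm(10, 20, 30, 240)
  expect_equal(e$ebgm, 2.5)
  expect_equal(e$ebgm05, 2.5 * exp(-1.645 / sqrt(10)), tolerance = 1e-12)
})

test_that("Yates chi-squared agrees with chisq.test across a table grid", {
  set.seed(1)
  for (i in 1:25) {
    t <- sample(1:400, 4)
    got <- compute_prr(t[1], t[2], t[3], t[4])$chi2
    ref <- suppressWarnings(
      stats::chisq.test(matrix(t, 2), correct = TRUE)$statistic)
    expect_equal(got, unname(ref), tolerance = 1e-10)
  }
})

test_that("balanced and independent tables sit at the null", {
  for (k in c(1, 3, 10, 50)) {
    expect_equal(compute_ror(k, k, k, k)$ror, 1)
    expect_equal(compute_prr(k, k, k, k)$prr, 1)
    expect_equal(compute_ic(k, k, k, k)$ic, 0)
    expect_equal(compute_ebgm(k, k, k, k)$ebgm, 1)
  }
  # independence without symmetry: a*N = (a+b)(a+c)
  expect_equal(compute_ic(6, 6, 2, 2)$ic, 0)
  expect_equal(compute_ebgm(6, 6, 2, 2)$ebgm, 1)
})

test_that("zero cells yield flagged-undefined RORs unless corrected", {
  r <- compute_ror(5, 0, 3, 10)
  expect_true(is.na(r$ror))
  rc <- compute_ror(5, 0, 3, 10, continuity = TRUE)
  expect_equal(rc$ror, (5.5 * 10.5) / (0.5 * 3.5))
})

test_that("the Bate posterior ('full') mode tracks the closed form at large counts", {
  s <- compute_ic(500, 12000, 1500, 300000, mode = "simplified")
  f <- compute_ic(500, 12000, 1500, 300000, mode = "full")
  expect_equal(f$ic, s$ic, tolerance = 0.02)
  expect_equal(f$ic025, s$ic025, tolerance = 0.05)
})

test_that("contingency counting is report-level with subgroup filters on all cells", {
  q <- tiny_quarter()
  cases <- case_reports(q)
  ids <- select_primary_suspect(q$drug, dtg_synonyms())
  dict <- load_term_dictionary()
  t1 <- build_contingency(cases, q$reac, ids, dict, term = "Nausea")
  expect_equal(t1[, c("a", "b", "c", "d")],
               tibble::tibble(a = 1L, b = 0L, c = 1L, d = 1L))
  # two PTs of one SOC in a single report count once at SOC level
  reac2 <- tibble::tibble(primaryid = c("112", "112", "312"),
                          pt = c("Nausea", "Vomiting", "Headache"))
  t2 <- build_contingency(cases, reac2, ids, dict,
                          term = "Gastrointestinal disorders", level = "SOC")
  expect_equal(t2$a, 1L)
  # female subgroup drops the male/unknown reports from every cell
  t3 <- build_contingency(cases, q$reac, ids, dict, term = "Nausea",
                          subgroup = "F")
  expect_equal(t3$N, 1L)
  expect_equal(t3$a, 1L)
  expect_error(build_contingency(cases, q$reac, ids, dict, term = "Nonsense"),
               "unknown term")
  expect_warning(z <- build_contingency(cases, q$reac, ids, dict,
                                        term = "Nausea", subgroup = "<18"),
                 "no reports")
  expect_equal(z$N, 0L)
})

test_that("monotonicity: more co-reports with fixed margins raises every estimator", {
  m1 <- 40; m2 <- 60; N <- 1000
  a <- 1:30
  b <- m1 - a; c <- m2 - a; d <- N - m1 - m2 + a
  ror <- compute_ror(a, b, c, d)$ror
  prr <- compute_prr(a, b, c, d)$prr
  ic <- compute_ic(a, b, c, d)$ic
  ebgm <- compute_ebgm(a, b, c, d)$ebgm
  for (v in list(ror, prr, ic, ebgm)) expect_true(all(diff(v) > 0))
})

test_that("the conjunction rule demands all four methods", {
  th <- default_thresholds()
  # a below the minimum-case threshold can never flag ROR/PRR
  low <- evaluate_signals(tibble::tibble(a = 2L, b = 8L, c = 10L, d = 980L), th)
  expect_false(low$ror_flag); expect_false(low$positive)
  # zero co-reports: nothing positive
  zero <- evaluate_signals(tibble::tibble(a = 0L, b = 50L, c = 100L, d = 850L), th)
  expect_false(any(zero$ror_flag, zero$prr_flag, zero$ic_flag,
                   zero$ebgm_flag, zero$positive))
  # RRR 2.2 at a = 100: ROR, PRR and IC pass but EBGM05 < 2 blocks the signal
  mid <- evaluate_signals(
    tibble::tibble(a = 100L, b = 900L, c = 900L, d = 20200L), th)
  expect_true(mid$ror_flag && mid$prr_flag && mid$ic_flag)
  expect_lt(mid$ebgm05, 2)
  expect_false(mid$positive)
})

test_that("screens are deterministic and bounded by the dictionary", {
  sim <- generate_faers(planted_config(seed = 3, n_cases = 2000))
  s1 <- run_screen(sim)
  s2 <- run_screen(sim)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_equal(s1$term, sort(s1$term))
  soc <- run_screen(sim, level = "SOC")
  expect_lte(nrow(soc), length(unique(load_term_dictionary()$soc)))
})

test_that("MGPS posterior means match numerical integration", {
  prior <- structure(list(alpha1 = 0.5, beta1 = 0.6, alpha2 = 2, beta2 = 2,
                          P = 0.3, logLik = NA, n_tables = 20, convergence = 0),
                     class = "mgps_prior")
  set.seed(4)
  a <- sample(0:30, 20, replace = TRUE)
  E <- runif(20, 0.5, 20)
  got <- mgps_posterior_mean(a, E, prior)
  for (i in seq_along(a)) {
    post <- function(l) {
      (prior$P * stats::dgamma(l, prior$alpha1, rate = prior$beta1) +
       (1 - prior$P) * stats::dgamma(l, prior$alpha2, rate = prior$beta2)) *
        stats::dpois(a[i], l * E[i])
    }
    # split at the likelihood peak: the integrand is sharply spiked when E
    # is small, which defeats a single adaptive pass
    peak <- max(a[i] / E[i], 1); upper <- (a[i] + 100) / E[i]
    iv <- function(f) {
      stats::integrate(f, 0, peak, rel.tol = 1e-10)$value +
        stats::integrate(f, peak, upper, rel.tol = 1e-10)$value
    }
    z <- iv(post)
    m <- iv(function(l) l * post(l))
    expect_equal(got[i], m / z, tolerance = 1e-6)
  }
})

test_that("the gamma-Poisson shrinker pulls null tables toward 1", {
  set.seed(7)
  n <- 300; m1 <- 200; N <- 20000
  m2 <- sample(50:2000, n, replace = TRUE)
  a <- rbinom(n, m2, m1 / N) # independence: E[a] = m1*m2/N
  tabs <- tibble::tibble(a = a, b = m1 - a, c = m2 - a, d = N - m1 - m2 + a)
  prior <- fit_mgps(tabs)
  E <- (tabs$a + tabs$b) * (tabs$a + tabs$c) / N
  scores <- mgps_scores(tabs$a, E, prior)
  rrr <- tabs$a / E
  expect_lt(mean(abs(scores$ebgm - 1)), mean(abs(rrr - 1)))
  # posterior 5th percentile sits below the geometric mean
  expect_true(all(scores$ebgm05 < scores$ebgm))
})

test_that("mgps mode on too few tables falls back with a warning", {
  tabs <- tibble::tibble(a = c(5L, 8L), b = c(95L, 92L),
                         c = c(50L, 80L), d = c(850L, 820L))
  expect_warning(out <- evaluate_signals(tabs, ebgm_mode = "mgps"),
                 "falling back")
  expect_equal(out$ebgm, with(tabs, a * (a + b + c + d) / ((a + b) * (a + c))))
  expect_error(fit_mgps(tabs), "at least 50")
})
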