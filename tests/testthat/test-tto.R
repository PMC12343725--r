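test_that("onset extraction does day arithmetic and excludes unusable dates", {
  q <- tiny_quarter()
  cases <- case_reports(q)
  ids <- select_primary_suspect(q$drug, c("DOLUTEGRAVIR", "EFAVIRENZ"))
  cohort <- dplyr::filter(cases, primaryid %in% ids)
  out <- extract_tto(cohort, q$ther, q$drug, c("DOLUTEGRAVIR", "EFAVIRENZ"),
                     outc = q$outc, lists = load_event_lists(), reac = q$reac)
  # case 11: start 2020-01-01, event 2020-03-15 -> 74 days, fatal, DME PT
  expect_equal(out$onset_days[out$primaryid == "112"], 74L)
  expect_true(out$fatal[out$primaryid == "112"])
  expect_equal(out$event_category[out$primaryid == "112"], "DME")
  # case 31 has no event date -> excluded with reason
  expect_false("312" %in% out$primaryid)
  excl <- attr(out, "exclusions")
  expect_equal(excl$n[excl$reason == "missing event date"], 1)
})

test_that("negative intervals and partial-precision dates are excluded", {
  cases <- tibble::tibble(
    primaryid = c("1", "2", "3"),
    event_dt = c("20200101", "20200315", "202003"),
    sex = "M", age_band = "18-45"
  )
  ther <- tibble::tibble(primaryid = c("1", "2", "3"),
                         dsg_drug_seq = "1",
                         start_dt = c("20200301", "202001", "20200101"))
  drug <- tibble::tibble(primaryid = c("1", "2", "3"), drug_seq = "1",
                         drugname = "DOLUTEGRAVIR")
  out <- extract_tto(cases, ther, drug, "DOLUTEGRAVIR")
  expect_equal(nrow(out), 0)
  reasons <- attr(out, "exclusions")$reason
  expect_setequal(reasons, c("negative interval", "partial start date",
                             "partial event date"))
})

test_that("the earliest target-drug start date anchors the interval", {
  cases <- tibble::tibble(primaryid = "1", event_dt = "20200410",
                          sex = "M", age_band = "18-45")
  ther <- tibble::tibble(primaryid = c("1", "1"), dsg_drug_seq = c("1", "2"),
                         start_dt = c("20200401", "20200101"))
  drug <- tibble::tibble(primaryid = c("1", "1"), drug_seq = c("1", "2"),
                         drugname = "DOLUTEGRAVIR")
  out <- extract_tto(cases, ther, drug, "DOLUTEGRAVIR")
  expect_equal(out$onset_days, 100L)
})

test_that("Weibull fit recovers planted parameters and classifies failure type", {
  x <- withr::with_seed(101, rweibull(5000, 0.6, 100))
  fit <- fit_weibull_tto(x)
  expect_gt(fit$shape, 0.57); expect_lt(fit$shape, 0.63)
  expect_lt(fit$shape_ci[2], 1)
  expect_equal(fit$classification, "early-failure")
  expect_equal(fit$scale, 100, tolerance = 0.1)
  # exponential data (shape 1) must classify as random
  y <- withr::with_seed(202, rweibull(5000, 1, 150))
  expect_equal(fit_weibull_tto(y)$classification, "random")
  z <- withr::with_seed(303, rweibull(5000, 2.5, 150))
  expect_equal(fit_weibull_tto(z)$classification, "wear-out")
})

test_that("Weibull estimates are nearly unbiased across seeds", {
  fits <- lapply(1:20, function(s) {
    fit_weibull_tto(withr::with_seed(1000 + s, rweibull(2000, 0.6, 100)))
  })
  shape_bias <- mean(sapply(fits, `[[`, "shape") - 0.6) / 0.6
  scale_bias <- mean(sapply(fits, `[[`, "scale") - 100) / 100
  expect_lt(abs(shape_bias), 0.03)
  expect_lt(abs(scale_bias), 0.03)
})

test_that("the MLE agrees with an independent fitting routine", {
  skip_if_not_installed("fitdistrplus")
  x <- withr::with_seed(7, rweibull(800, 0.8, 60))
  fit <- fit_weibull_tto(x)
  ref <- fitdistrplus::fitdist(x, "weibull")
  expect_equal(fit$shape, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(fit$scale, unname(ref$estimate["scale"]), tolerance = 1e-3)
})

test_that("fit refuses tiny or degenerate samples", {
  expect_error(fit_weibull_tto(rweibull(10, 1, 10)), "at least 30")
  expect_error(fit_weibull_tto(rep(5, 100)), "degenerate")
})

test_that("the free-location variant stays below the smallest onset", {
  x <- withr::with_seed(9, 20 + rweibull(500, 1.2, 80))
  fit <- fit_weibull_tto(x, location = "free")
  expect_gt(fit$location, 0)
  expect_lt(fit$location, min(x))
})

test_that("the KM curve is the empirical CDF when nothing is censored", {
  k <- km_curve(c(5, 10, 20))
  expect_equal(k$cuminc, c(1, 2, 3) / 3)
  expect_equal(km_at(k, c(0, 5, 12, 20, 99)), c(0, 1 / 3, 2 / 3, 1, 1))
  single <- km_curve(7)
  expect_equal(km_at(single, c(6.9, 7)), c(0, 1))
  # property: matches a direct sort-and-count empirical CDF
  x <- withr::with_seed(5, round(rweibull(400, 0.7, 120)))
  x <- x[x > 0]
  k2 <- km_curve(x)
  grid <- seq(0, max(x) + 10, by = 3)
  expect_equal(km_at(k2, grid), stats::ecdf(x)(grid), tolerance = 1e-12)
})

test_that("group comparison: symmetry, identity, and detection of a shift", {
  id <- tibble::tibble(onset_days = rep(c(1, 2, 3), 2),
                       grp = rep(c("a", "b"), each = 3))
  cmp <- compare_onset_groups(id, "grp")
  expect_gt(glance(cmp)$p.value, 0.99)
  expect_equal(cmp$median[1], cmp$median[2])
  expect_equal(cmp$q1[1], cmp$q1[2]); expect_equal(cmp$q3[1], cmp$q3[2])

  a <- withr::with_seed(31, rweibull(500, 0.6, 100))
  df <- tibble::tibble(onset_days = c(a, a + 200),
                       grp = rep(c("a", "b"), each = 500))
  expect_lt(glance(compare_onset_groups(df, "grp"))$p.value, 0.001)
  # swapping the group labels leaves the p-value unchanged
  df2 <- dplyr::mutate(df, grp = ifelse(grp == "a", "b", "a"))
  expect_equal(glance(compare_onset_groups(df, "grp"))$p.value,
               glance(compare_onset_groups(df2, "grp"))$p.value)
})

test_that("more than two groups switch to Kruskal-Wallis", {
  df <- tibble::tibble(
    onset_days = withr::with_seed(8, rweibull(300, 0.8, 100)),
    grp = rep(c("<18", "18-45", "46-65"), each = 100))
  cmp <- compare_onset_groups(df, "grp")
  expect_match(glance(cmp)$method, "Kruskal")
  expect_equal(nrow(cmp), 3)
  expect_error(compare_onset_groups(df[df$grp == "<18", ], "grp"),
               "two nonempty groups")
})
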