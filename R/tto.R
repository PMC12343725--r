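#' Extract time-to-onset records
#'
#' Time to onset is the interval in days from the earliest therapy start
#' date of the target drug to the report's event date, both required at day
#' precision. Reports are excluded — with per-reason accounting attached as
#' the `"exclusions"` attribute — when either date is missing, either date
#' has only year or month precision, or the interval is negative. Partial
#' dates are never imputed: imputation would bias the onset distribution.
#'
#' @param cases Cohort case tibble ([case_reports()] rows; supplies the
#'   event date, sex and age band).
#' @param ther Therapy records (`primaryid`, `dsg_drug_seq`, `start_dt`).
#' @param drug Drug records, used to restrict therapy rows to the target
#'   drug's sequence numbers.
#' @param target_variants Synonym tibble or character vector naming the
#'   target drug.
#' @param outc Outcome records, for the per-report fatal flag.
#' @param lists DME/IME lists ([load_event_lists()]) for the event
#'   category; with `reac` supplied each report is categorised `DME` if any
#'   of its PTs is a DME, else `IME`, else `other`.
#' @param reac Reaction records (optional, for event categories).
#' @return Tibble `(primaryid, onset_days, sex, age_band, event_category,
#'   fatal)`; attribute `"exclusions"` counts the dropped reports by
#'   reason.
#' @export
extract_tto <- function(cases, ther, drug, target_variants,
                        outc = NULL, lists = NULL, reac = NULL) {
  if (is.data.frame(target_variants)) {
    target_variants <- target_variants$variant[target_variants$enabled]
  }
  target_variants <- normalize_drug_name(target_variants)
  target_seq <- drug |>
    filter(normalize_drug_name(.data$drugname) %in% target_variants) |>
    distinct(.data$primaryid, .data$drug_seq)
  starts <- ther |>
    inner_join(target_seq, by = c("primaryid", dsg_drug_seq = "drug_seq")) |>
    mutate(start_date = fda_date_as_date(.data$start_dt),
           start_prec = parse_fda_date(.data$start_dt)$precision)

  per_report <- cases |>
    select("primaryid", "event_dt", "sex", "age_band") |>
    left_join(
      starts |>
        group_by(.data$primaryid) |>
        summarise(
          start_date = if (all(is.na(.data$start_date))) as.Date(NA)
                       else min(.data$start_date, na.rm = TRUE),
          start_partial = any(!is.na(.data$start_prec) & .data$start_prec != "day"),
          .groups = "drop"
        ),
      by = "primaryid"
    ) |>
    mutate(
      event_prec = parse_fda_date(.data$event_dt)$precision,
      event_date = fda_date_as_date(.data$event_dt),
      reason = dplyr::case_when(
        is.na(.data$event_prec) ~ "missing event date",
        .data$event_prec != "day" ~ "partial event date",
        is.na(.data$start_date) & .data$start_partial ~ "partial start date",
        is.na(.data$start_date) ~ "missing start date",
        as.integer(.data$event_date - .data$start_date) < 0 ~ "negative interval",
        TRUE ~ NA_character_
      )
    )

  excl <- per_report |> filter(!is.na(.data$reason)) |> count(.data$reason)
  kept <- per_report |>
    filter(is.na(.data$reason)) |>
    mutate(onset_days = as.integer(.data$event_date - .data$start_date))

  fatal_ids <- if (!is.null(outc)) unique(outc$primaryid[outc$outc_cod == "DE"]) else character()
  category <- rep("other", nrow(kept))
  if (!is.null(lists) && !is.null(reac)) {
    by_report <- reac |>
      filter(.data$primaryid %in% kept$primaryid) |>
      group_by(.data$primaryid) |>
      summarise(cat = if (any(.data$pt %in% lists$dme)) "DME"
                      else if (any(.data$pt %in% lists$ime)) "IME"
                      else "other", .groups = "drop")
    category <- coalesce(by_report$cat[match(kept$primaryid, by_report$primaryid)],
                         "other")
  }
  out <- kept |>
    transmute(.data$primaryid, .data$onset_days, .data$sex, .data$age_band,
              event_category = category,
              fatal = .data$primaryid %in% fatal_ids)
  attr(out, "exclusions") <- excl
  out
}

#' Fit a Weibull onset model with failure-type classification
#'
#' Maximum-likelihood fit of the Weibull distribution to positive onset
#' intervals, with a 95% confidence interval for the shape from the
#' observed information (delta method on the log scale). The hazard-based
#' failure type follows the shape CI: *early failure* when the upper bound
#' is below 1 (hazard falls over time — events cluster soon after therapy
#' start), *wear-out* when the lower bound exceeds 1, otherwise *random*.
#' By default the location is fixed at 0 (onset intervals start at zero by
#' construction; a free location is weakly identified when day-0/1 onsets
#' are present); `location = "free"` fits the three-parameter variant with
#' a threshold below the smallest observation.
#'
#' @param onset_days Numeric vector of onset intervals (days); values
#'   `<= 0` are dropped before fitting (a continuous model carries no
#'   information at exactly zero days).
#' @param location `"fixed"` (default, at 0) or `"free"`.
#' @param conf_level Confidence level for the shape interval.
#' @return A `weibull_tto` object with `shape`, `scale`, `location`,
#'   `shape_ci`, `classification`, `logLik`, `n`; methods
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' fit <- fit_weibull_tto(rweibull(200, 0.7, 120))
#' generics::glance(fit)
#' @export
fit_weibull_tto <- function(onset_days, location = c("fixed", "free"),
                            conf_level = 0.95) {
  location <- match.arg(location)
  x <- onset_days[!is.na(onset_days) & onset_days > 0]
  if (length(x) < 30) {
    abort(sprintf("need at least 30 positive onset values to fit (got %d)",
                  length(x)))
  }
  if (length(unique(x)) == 1) abort("degenerate fit: all onset values identical")

  z <- qnorm(1 - (1 - conf_level) / 2)
  if (location == "fixed") {
    nll <- function(th) {
      v <- suppressWarnings(-sum(dweibull(x, exp(th[1]), exp(th[2]), log = TRUE)))
      if (!is.finite(v)) 1e10 else v # guard the optimizer's wild steps
    }
    fit <- optim(c(0, log(mean(x))), nll, method = "BFGS", hessian = TRUE)
    shape <- exp(fit$par[1]); scale <- exp(fit$par[2]); gamma0 <- 0
    se_log_shape <- sqrt(diag(solve(fit$hessian)))[1]
  } else {
    # threshold parameterised as min(x) * plogis(th3): stays in (0, min x)
    nll <- function(th) {
      g <- min(x) * stats::plogis(th[3])
      v <- suppressWarnings(-sum(dweibull(x - g, exp(th[1]), exp(th[2]), log = TRUE)))
      if (!is.finite(v)) 1e10 else v
    }
    fit <- optim(c(0, log(mean(x)), 0), nll, method = "Nelder-Mead",
                 control = list(maxit = 2000))
    h <- stats::optimHess(fit$par, nll)
    shape <- exp(fit$par[1]); scale <- exp(fit$par[2])
    gamma0 <- min(x) * stats::plogis(fit$par[3])
    se_log_shape <- sqrt(diag(solve(h)))[1]
  }
  ci <- shape * exp(c(-1, 1) * z * se_log_shape)
  classification <- if (ci[2] < 1) "early-failure"
                    else if (ci[1] > 1) "wear-out" else "random"
  structure(list(
    shape = shape, scale = scale, location = gamma0,
    shape_ci = ci, conf_level = conf_level,
    classification = classification,
    logLik = -fit$value, n = length(x),
    n_dropped_nonpositive = sum(!is.na(onset_days) & onset_days <= 0),
    data = x
  ), class = "weibull_tto")
}

#' @export
print.weibull_tto <- function(x, ...) {
  cat(sprintf(
    "<weibull_tto> shape %.3f (95%% CI %.3f-%.3f), scale %.1f d%s; n = %d\n  failure type: %s\n",
    x$shape, x$shape_ci[1], x$shape_ci[2], x$scale,
    if (x$location > 0) sprintf(", location %.1f d", x$location) else "",
    x$n, x$classification))
  invisible(x)
}

#' @rdname fit_weibull_tto
#' @param x A `weibull_tto` fit.
#' @param ... Unused.
#' @method tidy weibull_tto
#' @export
tidy.weibull_tto <- function(x, ...) {
  tibble(term = c("shape", "scale", "location"),
         estimate = c(x$shape, x$scale, x$location),
         conf.low = c(x$shape_ci[1], NA, NA),
         conf.high = c(x$shape_ci[2], NA, NA))
}

#' @rdname fit_weibull_tto
#' @method glance weibull_tto
#' @export
glance.weibull_tto <- function(x, ...) {
  tibble(shape = x$shape, shape_low = x$shape_ci[1],
         shape_high = x$shape_ci[2], scale = x$scale,
         classification = x$classification, logLik = x$logLik, n = x$n)
}

#' Kaplan-Meier cumulative onset curve
#'
#' Cumulative incidence `1 - S(t)` of the onset distribution via
#' `survival::survfit`. Spontaneous reports carry no follow-up, so nothing
#' is censored and the curve equals the empirical CDF: a nondecreasing step
#' function reaching 1 at the largest observed onset.
#'
#' @param onset_days Numeric onset intervals (days).
#' @return A `km_curve`: tibble `(time, n_event, cuminc)` with a step
#'   evaluator attached; use [km_at()] to evaluate it at arbitrary days.
#' @export
km_curve <- function(onset_days) {
  stopifnot(length(onset_days) > 0)
  sf <- survival::survfit(survival::Surv(onset_days, rep(1, length(onset_days))) ~ 1)
  out <- tibble(time = sf$time, n_event = sf$n.event, cuminc = 1 - sf$surv)
  attr(out, "step_fn") <- stats::stepfun(out$time, c(0, out$cuminc), right = FALSE)
  class(out) <- c("km_curve", class(out))
  out
}

#' @rdname km_curve
#' @param curve A `km_curve`.
#' @param t Days at which to evaluate the cumulative incidence.
#' @export
km_at <- function(curve, t) {
  attr(curve, "step_fn")(t)
}

#' Compare onset distributions between groups
#'
#' Per-group medians and interquartile ranges (linear-interpolation
#' quantiles) with a two-sided Wilcoxon rank-sum test (normal
#' approximation with tie correction) for two groups, or a Kruskal-Wallis
#' test for more.
#'
#' @param onsets Tibble of onset records (e.g. from [extract_tto()]).
#' @param group Name of the grouping column in `onsets`.
#' @param value Name of the onset column (default `"onset_days"`).
#' @return An `onset_comparison`: per-group summary tibble with the test's
#'   `p.value` and `method` as attributes; [generics::glance()] returns
#'   them as a one-row tibble.
#' @export
compare_onset_groups <- function(onsets, group, value = "onset_days") {
  g <- onsets[[group]]
  x <- onsets[[value]]
  keep <- !is.na(g) & !is.na(x)
  g <- factor(g[keep]); x <- x[keep]
  if (nlevels(g) < 2) abort("need at least two nonempty groups")
  summary <- tibble(group = levels(g)) |>
    mutate(
      n = as.integer(table(g)[.data$group]),
      median = purrr::map_dbl(.data$group, ~ median(x[g == .x])),
      q1 = purrr::map_dbl(.data$group, ~ unname(quantile(x[g == .x], 0.25))),
      q3 = purrr::map_dbl(.data$group, ~ unname(quantile(x[g == .x], 0.75)))
    )
  if (nlevels(g) == 2) {
    ht <- suppressWarnings(
      wilcox.test(x[g == levels(g)[1]], x[g == levels(g)[2]],
                  exact = FALSE, correct = TRUE))
    method <- "Wilcoxon rank-sum (normal approximation)"
  } else {
    ht <- kruskal.test(x, g)
    method <- "Kruskal-Wallis"
  }
  attr(summary, "p.value") <- unname(ht$p.value)
  attr(summary, "method") <- method
  class(summary) <- c("onset_comparison", class(summary))
  summary
}

#' @rdname compare_onset_groups
#' @param x An `onset_comparison`.
#' @param ... Unused.
#' @method glance onset_comparison
#' @export
glance.onset_comparison <- function(x, ...) {
  tibble(p.value = attr(x, "p.value"), method = attr(x, "method"),
         n_groups = nrow(x))
}

#' @export
print.onset_comparison <- function(x, ...) {
  NextMethod()
  cat(sprintf("%s: p = %.4g\n", attr(x, "method"), attr(x, "p.value")))
  invisible(x)
}
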