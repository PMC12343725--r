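#' Fit the DuMouchel gamma-Poisson shrinker prior
#'
#' The multi-item gamma-Poisson shrinker (MGPS) models each table's count
#' as `a ~ Poisson(lambda * E)` with baseline `E = (a+b)(a+c)/N`, and puts
#' a two-component gamma mixture prior on the relative reporting ratio
#' `lambda`:
#' `f(lambda) = P * Gamma(alpha1, beta1) + (1-P) * Gamma(alpha2, beta2)`
#' (shape/rate). The five prior parameters are estimated by maximising the
#' marginal likelihood — a mixture of negative binomials — over all tables
#' of a screen. Fewer than 50 tables leaves the mixture unidentifiable and
#' is refused.
#'
#' @param tables Tibble with columns `a`, `b`, `c`, `d` (one row per
#'   drug-event table).
#' @param init Optional starting values
#'   `c(alpha1, beta1, alpha2, beta2, P)`.
#' @return An `mgps_prior` object (parameters, log-likelihood, n).
#' @references DuMouchel W (1999) Bayesian data mining in large frequency
#'   tables, with an application to the FDA spontaneous reporting system.
#'   The American Statistician 53(3):177-190.
#' @export
fit_mgps <- function(tables, init = c(0.2, 0.1, 2, 4, 1 / 3)) {
  if (nrow(tables) < 50) {
    abort("mgps prior fit needs at least 50 tables (prior unidentifiable)")
  }
  a <- tables$a
  E <- with(tables, (a + b) * (a + c) / (a + b + c + d))
  negll <- function(theta) {
    al1 <- exp(theta[1]); be1 <- exp(theta[2])
    al2 <- exp(theta[3]); be2 <- exp(theta[4])
    P <- stats::plogis(theta[5])
    ll <- log(P * dnbinom(a, size = al1, prob = be1 / (be1 + E)) +
              (1 - P) * dnbinom(a, size = al2, prob = be2 / (be2 + E)))
    -sum(ll)
  }
  theta0 <- c(log(init[1:4]), stats::qlogis(init[5]))
  fit <- optim(theta0, negll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-10))
  structure(list(
    alpha1 = exp(fit$par[1]), beta1 = exp(fit$par[2]),
    alpha2 = exp(fit$par[3]), beta2 = exp(fit$par[4]),
    P = stats::plogis(fit$par[5]),
    logLik = -fit$value, n_tables = nrow(tables),
    convergence = fit$convergence
  ), class = "mgps_prior")
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat(sprintf(paste0("<mgps_prior> %.3f * Gamma(%.3g, %.3g) + %.3f * ",
                     "Gamma(%.3g, %.3g)  [n = %d tables]\n"),
              x$P, x$alpha1, x$beta1, 1 - x$P, x$alpha2, x$beta2, x$n_tables))
  invisible(x)
}

#' @rdname fit_mgps
#' @param x An `mgps_prior`.
#' @param ... Unused.
#' @method tidy mgps_prior
#' @export
tidy.mgps_prior <- function(x, ...) {
  tibble(term = c("alpha1", "beta1", "alpha2", "beta2", "P"),
         estimate = c(x$alpha1, x$beta1, x$alpha2, x$beta2, x$P))
}

#' @rdname fit_mgps
#' @method glance mgps_prior
#' @export
glance.mgps_prior <- function(x, ...) {
  tibble(logLik = x$logLik, n_tables = x$n_tables,
         converged = x$convergence == 0)
}

# posterior mixture weight of component 1 given a, E
mgps_post_weight <- function(a, E, prior) {
  w1 <- prior$P * dnbinom(a, size = prior$alpha1,
                          prob = prior$beta1 / (prior$beta1 + E))
  w2 <- (1 - prior$P) * dnbinom(a, size = prior$alpha2,
                                prob = prior$beta2 / (prior$beta2 + E))
  w1 / (w1 + w2)
}

#' MGPS posterior summaries
#'
#' Given a fitted prior, the posterior of `lambda` for a table with count
#' `a` and baseline `E` is again a two-component gamma mixture with
#' components `Gamma(alpha_j + a, beta_j + E)`. `mgps_scores()` returns the
#' posterior geometric mean `EBGM = 2^{E[log2 lambda]}` and the exact
#' posterior 5th percentile `EBGM05` (root of the mixture CDF);
#' `mgps_posterior_mean()` returns the posterior arithmetic mean `E[lambda]`
#' (used for cross-checks against numerical integration).
#'
#' @param a Observed counts (vectorised).
#' @param E Baseline expected counts.
#' @param prior An `mgps_prior`.
#' @return `mgps_scores()`: tibble `(ebgm, ebgm05)`;
#'   `mgps_posterior_mean()`: numeric vector.
#' @export
mgps_scores <- function(a, E, prior) {
  Q <- mgps_post_weight(a, E, prior)
  s1 <- prior$alpha1 + a; r1 <- prior$beta1 + E
  s2 <- prior$alpha2 + a; r2 <- prior$beta2 + E
  elog <- Q * (digamma(s1) - log(r1)) + (1 - Q) * (digamma(s2) - log(r2))
  ebgm <- exp(elog)
  ebgm05 <- purrr::map_dbl(seq_along(a), function(i) {
    cdf <- function(x) {
      Q[i] * pgamma(x, s1[i], rate = r1[i]) +
        (1 - Q[i]) * pgamma(x, s2[i], rate = r2[i]) - 0.05
    }
    upper <- max(qgamma(0.05, s1[i], rate = r1[i]),
                 qgamma(0.05, s2[i], rate = r2[i]), 1e-8)
    lower <- min(qgamma(0.05, s1[i], rate = r1[i]),
                 qgamma(0.05, s2[i], rate = r2[i]), upper / 2)
    uniroot(cdf, lower = lower * 0.5, upper = upper * 2, extendInt = "yes",
            tol = 1e-10)$root
  })
  tibble(ebgm = ebgm, ebgm05 = ebgm05)
}

#' @rdname mgps_scores
#' @export
mgps_posterior_mean <- function(a, E, prior) {
  Q <- mgps_post_weight(a, E, prior)
  Q * (prior$alpha1 + a) / (prior$beta1 + E) +
    (1 - Q) * (prior$alpha2 + a) / (prior$beta2 + E)
}
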