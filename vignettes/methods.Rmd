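---
title: "Methods: disproportionality screening, priority scoring and onset modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality screening, priority scoring and onset modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

This vignette is the package's own account of the statistics it implements:
the models, their assumptions, the defaults and why they were chosen, and
what the synthetic test bed does and does not establish about real
spontaneous-report data.

## The data model and its assumptions

A spontaneous reporting database is a collection of case reports, each
carrying demographics, one or more suspect/concomitant drugs with role
codes, one or more adverse events coded as MedDRA preferred terms (PTs),
outcome codes, and partially complete dates. Three assumptions shape the
pipeline:

* **One case, one row.** Cases are resubmitted as new versions;
  `deduplicate_cases()` keeps, per case identifier, the record with the
  latest receipt date, breaking ties by the highest primary key, and drops
  cases on deleted-case lists. This matches the deduplication practice
  recommended for the quarterly files. The operation is idempotent by
  construction.
* **Report-level counting.** A report contributes at most once to the `a`
  cell of any term, even if it lists the same PT twice or several PTs of
  one SOC. This keeps the case/event distinction coherent: a cohort has
  fewer cases than adverse events.
* **Partial dates are information about precision, not values to fill
  in.** FAERS dates arrive as 4, 6 or 8 digit strings. `parse_fda_date()`
  records the populated components and a precision label; nothing is ever
  imputed. Onset analysis simply excludes reports without day-precision
  dates — imputation (e.g. mid-month) would bias the onset distribution
  toward artificial spikes.

## The four estimators and the conjunction rule

All four methods are functions of the 2×2 table `(a, b, c, d)` with
`N = a+b+c+d`, where the comparator is the rest of the deduplicated
extract ("rest of database"). Writing `E = (a+b)(a+c)/N` for the expected
co-report count under independence and `RRR = a/E`:

* **ROR** `= ad/(bc)`, 95 % interval
  `exp(log ROR ± z₀.₉₇₅ √(1/a+1/b+1/c+1/d))`. Undefined with a zero cell;
  by default the result is flagged undefined and the method counts as
  negative. An optional Haldane–Anscombe `+0.5` correction (interval
  computation only) can be enabled.
* **PRR** `= [a/(a+b)]/[c/(c+d)]` with the Yates-corrected Pearson χ²
  (identical to `chisq.test(correct = TRUE)`, which the test suite uses as
  an independent oracle). The continuity correction is the convention in
  this literature and can be switched off.
* **BCPNN IC.** The default ("simplified") mode uses the closed form
  `IC = log2(RRR)` with `IC025 = IC − 2s`, where `s²` is the Bate et al.
  (1998) variance approximation of the information-component posterior
  with priors `α₁ = β₁ = γ₁₁ = 1`, `α = β = 2` and `γ` chosen so the
  prior sits at independence. A "full" mode computes the exact
  Beta/Dirichlet posterior moments of `log p₁₁ − log p₁. − log p.₁` via
  digamma/trigamma functions and reports `E[IC] − 2·sd[IC]`.
* **EBGM.** The default mode reports `RRR` itself with a lognormal lower
  bound `EBGM05 = RRR·exp(−1.645/√a)`, the leading-order Poisson variance
  of `log RRR`. The "mgps" mode is a complete DuMouchel gamma-Poisson
  shrinker: a five-parameter two-component gamma mixture prior on the
  reporting ratio, fitted by maximising the negative-binomial marginal
  likelihood over all tables of the screen, with the posterior geometric
  mean and exact posterior 5th percentile per table. The posterior is
  conjugate (a reweighted two-component gamma mixture), so the geometric
  mean uses digamma moments and the 5th percentile is found by root
  search on the mixture CDF (`uniroot`, tolerance 1e-10). The prior fit
  refuses fewer than 50 tables — a two-component mixture is not usefully
  identifiable below that — and the screen then falls back to the
  simplified mode with a warning.

**Why the simplified family is the default.** Published FAERS analyses in
this style print IC and EBGM values satisfying `IC = log2(EBGM)` to the
printed precision, which is exactly the simplified closed-form
relationship (the shrinkage variants break it). The package therefore
defaults to the closed forms — the estimators most screening studies
actually compute — and offers the full-posterior and MGPS variants behind
mode flags, with the mode recorded in the result metadata.

A drug–event pair is a *signal* only when **all four** methods pass:
`a ≥ 3` and ROR CI lower bound > 1; `a ≥ 3`, PRR ≥ 2 and χ² ≥ 4;
IC025 > 0; EBGM05 > 2. Strict inequalities are used where the customary
threshold statements are ambiguous ("> 2" rather than "≥ 2"); all
thresholds are configurable in `default_thresholds()`. No multiple-testing
adjustment is applied — the conjunction rule itself is the (heuristic)
false-positive control used in this literature — and the output metadata
says so.

## Clinical-priority rubric

Each positive signal is scored on four 0–2 components: reporting rate
(`>10 %` → 2, `(1, 10] %` → 1, `≤ 1 %` → 0, with the drug's total
adverse-event count as denominator — the subgroup's own total in subgroup
screens), signal stability, fatal report proportion (`> 50 %` → 2,
`[25, 50] %` → 1, `< 25 %` → 0) and clinical relevance (DME 2, IME 1,
else 0; DME wins when a term is on both lists). Totals band as low (0–2),
moderate (3–5), high (6–8).

Two conventions required a decision:

* **Stability with four methods against a three-analysis rubric.** The
  rubric counts agreement among three analyses. The four flags are mapped
  onto three families — ROR-type, PRR-type, and the Bayesian pair (IC and
  EBGM jointly) — so "3 of 3" means all four methods agree. Any signal
  passing the conjunction rule necessarily scores 2 here; the mapping only
  matters for partially positive pairs scored outside the screen.
* **Boundary conventions.** Fatality at exactly 25 % or 50 % scores 1
  (the rubric prints an inclusive 25–50 % band); a reporting rate of
  exactly 1 % scores 0 and exactly 10 % scores 1. No published worked
  example sits on a boundary, so these conventions cannot contradict the
  printed scores they reproduce.

The DME/IME lists themselves are licensed regulatory artefacts and are
user-supplied as one-term-per-line files; the package ships small
synthetic stand-in lists (`toy_dme.txt`, `toy_ime.txt`) aligned with its
toy dictionary for testing.

## Time to onset

Onset is `event date − earliest target-drug therapy start`, in days, both
at day precision. The Weibull model is fitted by maximum likelihood on the
log-parameter scale (BFGS, analytic-free Hessian from `optim`), with the
shape's 95 % CI from the observed information via the delta method. The
failure taxonomy is hazard-based: shape CI entirely below 1 ⇒ early
failure (declining hazard, events cluster after initiation); entirely
above 1 ⇒ wear-out; otherwise random.

Numerical decisions:

* Zero-day onsets are dropped before fitting (`n` reported accordingly): a
  continuous positive model has no density at 0, and with shape < 1 the
  likelihood diverges there. They remain in the KM curve and the rank
  tests, which are discrete-friendly.
* Fits are refused below 30 positive values (the shape CI is useless
  below that) and for degenerate constant samples.
* The "3-parameter" Weibull variant is available (`location = "free"`,
  threshold parameterised inside `(0, min x)` via a logistic transform),
  but the default fixes the location at 0: onset intervals start at zero
  by construction and a free threshold is weakly identified whenever
  day-0/1 onsets are present.
* The KM curve uses `survival::survfit`; with no censoring (spontaneous
  reports have no follow-up) it equals the empirical CDF exactly, which
  the tests assert against a direct sort-and-count oracle.
* Two-group comparisons use the Wilcoxon rank-sum test with normal
  approximation and tie correction (onset days are heavily tied); more
  than two groups use Kruskal–Wallis. Medians and quartiles are type-7
  (linear interpolation) quantiles.

## The synthetic generator as study conditions

`synthetic_config()` defines the population every simulation-based test
runs on. Defaults were chosen once, to mimic the structure of a
single-drug FAERS cohort at desk scale, and are not tuned per test:

* 5 % of reports carry the target drug as primary suspect; the remainder
  spread over 15 comparator drugs.
* ~57 PTs across 12 SOCs (the toy dictionary), background per-PT report
  probabilities cycling through 0.2–5 %.
* Onset intervals Weibull with shape 0.9, scale 150 days for background
  events — mildly early-skewed, as spontaneous reports typically are.
* 30 % of event dates missing and 10 % month-precision; 20 % of therapy
  start dates missing; 35 % of ages missing; 20 % of sexes unknown —
  missingness rates of the order seen in the public quarterly files.
* 5 % of cases carry an extra earlier version record, and 2 % a
  background death outcome.

A planted signal `(pt, rrr, fatal_prob, shape, scale)` tilts the per-case
event probability for target-exposed cases to
`p₁ = rrr(1−f)·bg/(1 − rrr·f)` (target share `f`, background rate `bg`),
which makes the *report-level* relative reporting ratio equal `rrr` in
expectation — the naive `rrr·bg` tilt overshoots because the exposed cases
inflate the event margin. Configurations implying `p₁ > 1` or `rrr·f ≥ 1`
abort before generation.

What the generator deliberately does **not** emulate: reporting-trend
seasonality, drug–drug interaction structure, correlated events within a
report (background PTs are independent), verbatim-term noise requiring
MedDRA coding, and country/occupation effects on reporting. Passing tests
therefore demonstrate that the *methods* behave correctly under a
controlled spontaneous-reporting mechanism — not that any particular
real-world signal is or is not genuine, which additionally depends on the
biases of real reporting (under-reporting, stimulated reporting, missing
exposure denominators).

## Problem sizes and tolerances in the test suite

The suite exercises: planted-signal recovery at a tenfold reporting ratio
over 20 seeds of 10,000 cases each (expected `a ≈ 40`), with matched null
datasets expected to produce essentially no all-four-method positives;
empirical attainment of the planted ratio within ±10 % at 50,000 cases;
Weibull parameter recovery at 5,000 samples (single seed) and mean
relative bias below 3 % over 20 seeds of 2,000; MGPS posterior means
against split-range numerical integration to 1e-6; and exact reproduction
of the published rubric worked examples. These sizes were chosen as the
smallest at which the respective stochastic properties are stable, keeping
the default test run in the tens of seconds.

## Known limitations

* Drug-name normalisation is purely lexical plus a user-supplied synonym
  table; there is no WHO-Drug/RxNorm resolution, so misspelled verbatim
  names fall outside the cohort.
* The comparator is always the rest of the extract; active-comparator or
  drug-class-restricted designs are not implemented.
* No likelihood-ratio-test or tree-based scan statistics.
* Disproportionality quantifies reporting association, not risk; the
  package computes no incidence and none of its outputs should be read as
  causal.
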