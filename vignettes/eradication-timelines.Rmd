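---
title: "Methods: eradication records, success rates, and spline timeline analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eradication records, success rates, and spline timeline analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(islerad)
```

This vignette is the package's account of its methods: the data model and
filtering conventions, the success-rate arithmetic, the spline scatter
model and its bootstrap bands, what the synthetic generator does and does
not emulate, and the numerical and design choices made where more than one
convention was defensible.

## Event records and inclusion filters

An eradication event is one attempt to remove one invasive vertebrate
population from one entire island; several species on the same island are
separate events. Each record carries the island (id, country, area in
hectares, ordinal human-habitation bin), the target (scientific name,
mapped to one of 13 groups), the eradication status (seven categories, of
which successful / reinvaded / failed / to-be-confirmed count as
*completed*), the end year (last year a method was applied), the primary
method (toxicant, trapping, hunting, other), and the record-keeping fields
the inclusion rules check.

`apply_inclusion_filters()` applies five rules — quality, whole island,
feral (semi-feral counts as feral; domestic does not), purpose, recognised
status — and attributes each exclusion to the *first* failing rule in that
fixed order. The order is a bookkeeping convention: the kept set is the
same under any order, but first-failure attribution makes the per-rule
counts well defined and additive (`n_input = n_kept + Σ exclusions`).

Status strings are matched case- and punctuation-insensitively against a
documented alias table ("Successful and subsequently reinvaded" →
`reinvaded`, and so on). Anything outside the table is a hard error by
default (`strict = TRUE`), or a row-level issue with the row dropped
(`strict = FALSE`); a raw status is never silently coerced, because a
miscoded status corrupts success-rate denominators invisibly. The same
philosophy applies to areas and years: invalid values produce row-level
issues that name the row and field, never silent drops.

The species→group dictionary is a packaged, user-extensible CSV. Rats
contain only *Rattus* species and mice only *Mus musculus*; birds are
routed to flying/non-flying by a flight-capability column, since
eradication feasibility differs fundamentally by that trait.

## Success rates and group summaries

The success rate is `100 · s / (s + f)` over successful (`s`) and failed
(`f`) events only. Reinvaded events — operations that succeeded but whose
target later re-established — are excluded from both numerator and
denominator: reinvasion is a restoration failure, not an operational one.
Rates are undefined (`NA`, deliberately neither 0 nor 100) when both
counts are zero, reported for groups only with at least 10 success-or-fail
records, and for years only with at least 5 such events. The annual-rate
threshold is interpreted on the rate's own denominator (completed
success-or-fail events), since only those enter the formula.

Printed percentages round half away from zero to one decimal (so 72.857
prints as 72.9); percentiles use the linear-interpolation convention
(`quantile(type = 7)`); interval shading for annual rates uses the Wilson
score interval, which stays inside [0, 1] and is non-degenerate at 0 or
`n` successes.

In the packaged count fixture and in `group_summary()` output, the
species, events, and outcome columns are additive over groups, but the
islands column is not: an island targeted for several groups counts once
in the totals row (which is a distinct count), so the per-group column
over-counts it. The fixture carries counts and success rates only; area
and habitation cells of the published table are typographically ambiguous
in circulating copies and are left to be computed from data.

Events with a missing end year and a non-final status (in progress,
to-be-confirmed, planned) are assigned the final window year (default
2019) by `assign_end_years()`, as a deliberate measure of contemporary
activity; undated events with any other status are reported as issues and
excluded from time series, never guessed. Note the side effect: the
fallback concentrates those events into the final year and can create a
real end-of-window spike in the annual series.

## The spline scatter model

For an annual metric $y_t \ge 0$ on a year window, the trend model is

$$\log(y_t + c) = s(t) + \varepsilon_t, \qquad
  \varepsilon_t \sim N(0, \sigma^2_{r(t)}),$$

where $s$ is a cubic spline with $k$ equidistant interior knots (cubic
B-spline basis, boundary knots at the window ends, $p = k + 4$ columns,
fitted by ordinary least squares), and $r(t)$ indexes one or two variance
regimes. The lognormal scatter reflects the data: annual counts and areas
span orders of magnitude and their spread scales with level.

Parameters that matter:

* **`offset_c`** (default 0.5, in the metric's units): added before the
  log so zero-count years are usable; reported with every fit, and all
  natural-scale output subtracts it back. Results for well-populated
  series are insensitive to it; for sparse early decades it acts as a mild
  shrinkage of log-zero years.
* **knot range** (default $k \in [0, \min(35, n/3 - 4)]$): wide enough for
  decadal structure on a 120-year series while capping $p \le n/3$. The
  knot count is chosen by $\mathrm{GCV}(k) = n\,\mathrm{RSS}_k/(n-p_k)^2$
  on the log scale, ties broken toward the smaller (smoother) $k$.
* **`variance_changepoint`** (default `NULL`; 1985 is the package's
  suggested setting for the treated-area metric, whose spread contracts
  sharply in the mid-1980s): splits the residual variance into two
  regimes. It is a user setting, not estimated from data. Regime $r$ uses
  divisor $n_r - p\,n_r/n$, apportioning the $p$ model degrees of freedom
  by sample share so the divisors sum to $n - p$.

Derivatives are analytic from the piecewise-cubic coefficients. On the log
scale they are $s'$ and $s''$; on the natural scale of the metric,
$m = e^s - c$, $m' = e^s s'$, and $m'' = e^s (s'' + s'^2)$. The default
reporting scale is natural (the figures of interest plot counts and
hectares); gradient *sign* conclusions are identical on both scales
because $e^s > 0$, while curvature signs can differ — an exponential has
positive curvature on the natural scale and zero on the log scale — so the
scale is always recorded with the output. No extrapolation outside the
fitted window is permitted; boundary behaviour is whatever the B-spline
basis implies (no natural-spline end conditions).

## Bootstrap bands and significance periods

Uncertainty comes from a parametric bootstrap of the scatter model:
replicate $b$ draws $z^*_t = \hat s(t) + \varepsilon^*_t$ with
$\varepsilon^*_t \sim N(0, \hat\sigma^2_{r(t)})$, refits the spline, and
evaluates curve, gradient, and curvature on an annual grid. Pointwise
bands are empirical type-7 quantiles over (default) 1000 replicates at
confidence 0.95. A derivative is significant in a year when its band
excludes zero; maximal runs of at least `min_run = 5` consecutive
significant years with constant sign are the reported periods. No
multiplicity correction is applied beyond the run rule; the bands are
pointwise by construction and are interpreted as such.

Random numbers flow from a single seed, with the replicate noise matrix
filled column-major so replicate $b$ always consumes the same draws:
enlarging `n_bootstrap` never reshuffles earlier replicates.

**Propagating knot selection.** `refit_knots` controls whether each
replicate re-runs the GCV knot search (`TRUE`) or inherits the original
$k$ (`FALSE`, the default, which stabilises replicate curves and is
cheapest). The package's own calibration experiments (in the test suite)
show the difference matters: with $k$ held fixed, pointwise derivative
bands are so strongly correlated across years that the 5-year run rule
adds almost no protection on null data — a flat lognormal series produces
a spurious ≥5-year gradient period in roughly half of runs, partly because
GCV occasionally chases a chance wiggle and the conditioned-on fit then
certifies it. Re-selecting $k$ inside every replicate propagates the
model-selection uncertainty into the bands and restores calibration
(period-free rate ≈ 95% or better on flat noise at `n_bootstrap = 1000`)
while retaining full power to recover an injected 25-year growth segment.
The calibration and recovery experiments therefore run with
`refit_knots = TRUE`, and analyses whose $k$ was chosen by GCV should do
the same; the refit path shares the per-$k$ design decompositions across
replicates, so its cost stays low.

Degenerate inputs: a noiseless series gives $\hat\sigma \approx 0$ and the
bands collapse onto the point estimates with a warning (flagged, not
fatal). Singular designs and over-parameterised fits ($p > n$) are errors.

## The synthetic generator

`scenario()` defines yearly event counts as Poisson draws from a piecewise
log-linear intensity — the minimal count process consistent with fitting a
smooth lognormal trend — plus multinomial group assignment, per-group
lognormal island areas, a rank-skewed (Zipf-like) country distribution to
mimic the concentration of effort in a handful of nations, non-final
statuses confined to the closing reporting-lag years, and a configurable
fraction of undated non-final events. Outcomes are drawn so that the
*computed* success rate (reinvaded events out of the denominator) has
expectation equal to the scenario's per-group target rates, which requires
inverting the reinvasion thinning: an event succeeds with probability
$p' = \theta / (\theta + (1-\theta)(1-r))$ so that the post-exclusion rate
is the target $\theta$ under reinvasion probability $r$.

The defaults emulate the global record as published: a slow start in the
early 1900s, sustained growth from 1950, a strong wave over 1980–2004, a
gentle decline after 2005 (≈1550 events in expectation over 1900–2019), a
group mix and success rates matching the published group table (pooled
rate ≈ 88%), reinvasion probability 0.134, 38 countries, and a reporting
lag leaving on the order of 90 recent events undated.

What it does **not** emulate — and therefore what passing tests cannot
attest about real data: islands are not persistent entities (areas are
drawn per event, so repeat attempts on one island do not share an area),
method choice is a per-group modal draw rather than an era-dependent
technology model, statuses carry no duration structure, and no spatial or
jurisdictional structure beyond the country code exists. The generator
validates the machinery, not the history.

`tableone_seeded_events()` is different in kind: a deterministic table
whose per-group status counts exactly equal the packaged count fixture, so
that `group_summary()` must reproduce every published group success rate
and the outcome totals arithmetically.

## Problem sizes used by the test suite

The suite's simulation experiments use sizes chosen to give the relevant
binomial checks resolving power at modest cost: 500 simulated series
(bootstrap 100 each) for pointwise gradient coverage of a known curve at
interior years; 200 seeded runs each (bootstrap 1000, knot range 0–10,
knot re-selection propagated) for the flat-series false-period rate and
for recovery of an injected log-slope-0.08 growth segment; 20 seeds at
$n \approx 10^5$ events for the group-mix goodness of fit. The full suite
runs in a couple of minutes on one CPU.

## Known limitations

* Unpenalised regression splines with GCV-selected equidistant knots can
  be locally unstable compared to penalised smoothers; the bootstrap (with
  `refit_knots = TRUE`) prices that in, but a penalised variant is
  deliberately out of scope.
* Significance is pointwise; the 5-year run rule is a heuristic guard, not
  a family-wise error control.
* Running the success-rate series through the lognormal machinery treats a
  bounded proportion as a positive unbounded quantity; it is serviceable
  because annual rates here sit well inside (0, 1], but a logit-scale
  treatment would be more principled for rates near the boundaries.
* The islands column of group summaries over-counts islands shared between
  groups by construction; only the totals row is a distinct count.
* Country annotations (Small Island Developing States, income class) are
  an optional user-supplied join; the packaged lookup is synthetic
  illustration data, not an authoritative classification.
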