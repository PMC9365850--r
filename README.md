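# islerad

Analysis of island invasive-vertebrate eradication records: event-table
validation and filtering, group success-rate summaries, annual activity
series, and a spline-based timeline analysis that finds multi-year periods
of significant growth, acceleration, or deceleration in eradication
activity.

## The problem

Eradicating an invasive vertebrate population from an entire island is one
of conservation's most effective interventions, and a century of attempts
has been compiled into databases such as the Database of Island Invasive
Species Eradications (DIISE). Synthesising those records raises three
recurring tasks, and `islerad` packages all three for anyone working with
DIISE-style event exports:

1. **Record hygiene.** One row per target-species-on-island attempt, with
   five inclusion rules (data quality good/satisfactory; whole island
   treated; feral or semi-feral population; purpose was eradication, not a
   trial; status among the seven recognised categories) applied in a fixed
   order with per-rule exclusion accounting.
2. **Outcome accounting.** Success rates computed as
   `success / (success + failure)` — reinvasions after a successful
   operation are a restoration failure, not an operational one, and leave
   the denominator — with group summaries (13 taxon groups: *Rattus*-only
   rats, *Mus musculus*-only mice, birds split by flight capability, ...)
   and annual series of events, treated area, active countries, and taxa
   targeted.
3. **Trend shape.** For each annual metric `y_t`, a cubic regression spline
   is fitted to `log(y_t + c)` with equidistant interior knots, the knot
   count chosen by generalised cross-validation,
   `GCV(k) = n·RSS_k / (n − p_k)²` with `p_k = k + 4`. A parametric
   bootstrap from the fitted lognormal scatter model (optionally piecewise,
   for series whose variance shifts mid-window) yields pointwise 95%
   confidence bands for the curve, its gradient `m′(t)` (change per year),
   and curvature `m″(t)` (change in gradient per year). Years where a
   derivative's band excludes zero, for at least 5 consecutive years with
   constant sign, form the reported significance periods.

A synthetic event generator (piecewise log-linear Poisson intensity,
group/outcome/area models with closed-form ground truth) makes every stage —
including the timeline machinery's false-positive and recovery rates —
testable offline.

## Worked example

Filter a raw export, then summarise:

```r
library(islerad)
ev <- parse_events(system.file("extdata", "demo_events.csv", package = "islerad"))$events
apply_inclusion_filters(ev)
#> Inclusion filter report
#>   input events: 12
#>   kept events:  9
#>   excluded by quality:     1
#>   excluded by whole_island: 1
#>   excluded by feral:       0
#>   excluded by purpose:     1
#>   excluded by status:      0
```

One row was rejected per violated rule: a poor-quality record, a
partial-island treatment, and a trial operation. Group summaries on the
packaged count fixture reproduce the published outcome table:

```r
gs <- group_summary(tableone_seeded_events())
gs[c(1:4, 14), c("group", "n_events", "n_successful", "n_reinvaded", "n_failed", "success_rate_pct")]
#>      group n_events n_successful n_reinvaded n_failed success_rate_pct
#>       rats      820          545         135       74             88.0
#>  ungulates      185          150           4       13             92.0
#>       cats      117           80           5       12             87.0
#>       mice       91           51           7       19             72.9
#>      total     1550         1081         167      146             88.1
```

So rats are the dominant target (820 of 1550 events, 53%), and 88.1% of the
1227 completed success-or-fail operations succeeded. The timeline analysis
on a synthetic scenario with growth waves starting in 1950 and 1980:

```r
sim   <- simulate_events(scenario(seed = 42))
kept  <- apply_inclusion_filters(sim$events)$kept
dated <- assign_end_years(kept)$events
s     <- annual_series(dated, "events", "all")
run_timeline(s, spline_options = list(k_max = 12),
             config = timeline_config(seed = 43, refit_knots = TRUE))
#> Timeline analysis [events]: k = 5 knots, sigma = 0.561, seed = 43
#> Significant periods (>= 5 consecutive years):
#>   positive gradient: 1942-1960 (19 years)
#>   positive gradient: 1976-1998 (23 years)
#>   positive curvature: 1940-1947 (8 years)
#>   positive curvature: 1975-1988 (14 years)
```

Both injected growth waves are recovered as significant positive-gradient
periods, each preceded by a period of significant acceleration.

There is also a thin command-line wrapper
(`system.file("exec", "islerad", package = "islerad")`) with subcommands
`filter`, `summarize`, `series`, `timeline`, and `simulate`.

## See also

The methods vignette (`vignettes/eradication-timelines.Rmd`) documents the
scatter model, the GCV/bootstrap machinery and its calibration, the
synthetic generator's assumptions, and known limitations.
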