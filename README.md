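# ortegar

Time-geographic interaction analysis of animal GPS telemetry in R.

`ortegar` detects and quantifies dyadic interactions between tracked animals
using the ORTEGA approach from time geography, for movement ecologists who
want to go beyond fixed spatial-buffer contact rules. Instead of asking
whether two fixes fall within a buffer at (nearly) the same instant, it asks
whether the *regions the two animals could have occupied between fixes*
overlap — which keeps working when collars are desynchronised, sampling is
coarse, or animals respond to each other with a delay of hours to weeks.

## The method

For each pair of consecutive fixes of one animal, the potential path area
(PPA) is the ellipse with the two fixes at its foci and major axis
`2a = v_max * Δt` — the planar projection of the space–time prism of all
points reachable in the time budget `Δt` at speed at most `v_max`. The speed
budget is an exponentially weighted moving average of recent observed
segment speeds,

    s_i = v_i                                  if λ = 1
    s_i = Σ_{k=0}^{n-1} λ (1 − λ)^k v_{i−k}    if 0 < λ < 1
    v_max = ε s_i

with smoothing constant `λ` (default 0.5), window `n` (default 10) and a
multiplicative error term `ε = 1.25` that lets the budget exceed the
smoothed average by 25%. PPAs inflated by sampling gaps (interval above
`mean + 3·sd` of the individual's sampling intervals) are removed.

Two animals' PPAs that intersect in space form an interaction event. Events
are **concurrent** when the start-time lag is at or below the concurrency
threshold (by default the data's sampling interval), otherwise **delayed**
and assigned a lag bin (1 day, 1/2/3 weeks). Maximal runs of temporally
continuous events are traced into interaction segments whose duration is
`max end − min start`; segments and events are summarised per calendar
month, per dyad, and aggregated into an interaction network. The package
also provides 95%-convex-hull home ranges with directed overlap
proportions, heading/speed-difference descriptors with kernel-density
profiles, the classical proximity buffer + time-window baseline with a
Mann–Whitney comparison harness, and a correlated-random-walk simulator
with scripted regimes (co-movement, lagged revisit, avoidance,
independence) that emits ground-truth interaction intervals.

## Worked example

```r
library(ortegar)

# a 10-day follower dyad at 1-h sampling: B shadows A with 400 m jitter
sim <- simulate_dyad("co_movement", days = 10, jitter_m = 400, seed = 42)
fit <- ortega(sim$tracks)
fit
#> Time-geographic interaction analysis: 1 dyad(s), 480 PPAs (0 gap-removed)
#>   concurrency threshold 1.00 h; lag bins 24/168/336/504 h
#>   A-B: 471 concurrent event(s) in 5 segment(s) (231.0 h total), 2146 delayed event(s)

summary(fit)
#>   id_a id_b n_concurrent n_delayed n_segments total_duration_h median_duration_h
#> 1    A    B          471      2146          5              231                22

coverage_fraction(sim$truth, fit$dyads[[1]]$segments)
#> [1] 0.9626736

# the proximity baseline at its narrowest setting misses most of this
cmp <- compare_methods(fit$dyads[[1]]$segments$duration_h,
                       proximity_sweep(sim$tracks, "A", "B", 200, 0)$duration_h)
cmp
#> Mann-Whitney comparison of interaction durations
#>   n = 5 vs 13; medians 22 vs 0 h
#>   U = 65.0, p = 0.0003304
```

The fit reports 480 PPA ellipses (one per consecutive fix pair per animal),
471 intersecting PPA pairs with lag ≤ 1 h chained into 5 continuous
segments totalling 231 h of concurrent interaction — 96% of the scripted
co-movement time — while the 200 m / 0 min proximity rule fragments the same
association into 13 runs with median duration 0 h; the Mann–Whitney test
confirms the duration distributions differ.

`run_interaction(config)` and `run_compare(config)` orchestrate full runs
(events, segments, monthly summaries, home ranges, descriptors, network
CSV/GEXF, resolved config, manifest) into an output directory, and
`inst/cli/ortega.R` wraps them for shell use:

```sh
Rscript inst/cli/ortega.R simulate --regime co_movement --days 30 --seed 1 --out sim
Rscript inst/cli/ortega.R interact --config config.json
```

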