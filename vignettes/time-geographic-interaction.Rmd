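---
title: "Time-geographic interaction analysis: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-geographic interaction analysis: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ortegar)
```

## The model

A GPS collar observes an animal at discrete fixes; between two consecutive
fixes the animal could have been anywhere it can reach within the time
budget at a bounded speed. Time geography formalises this as the space–time
prism; its planar projection, the potential path area (PPA), is an ellipse
with the two fixes at its foci and major axis `2a = v_max * Δt`. The
semi-focal distance is `c = dist/2`, the minor semi-axis
`b = sqrt(a² − c²)`, so the ellipse degenerates to the straight segment
exactly when the animal would have had to move at its speed budget the
whole time.

The speed budget is not a biological constant but an adaptive bound
estimated from the recent past by an exponentially weighted moving average
(EWMA) of observed segment speeds, scaled by a multiplicative error term
`ε`:

* `s_i = v_i` when `λ = 1`, else `s_i = Σ_{k=0}^{n−1} λ(1−λ)^k v_{i−k}`,
* `v_max,i = ε · s_i`.

Two assumptions follow from this construction and should be kept in mind:
positions are treated as exact (no collar-error model — the prism absorbs
only *between-fix* uncertainty), and every point of the PPA is treated as
equally reachable (the method is deterministic; no within-prism visit
probability is modelled).

Interaction is then defined pairwise: every spatial intersection of one
animal's PPA with another's is an *event*; the absolute difference of the
two PPAs' start times is its *lag*. Events with lag at or below the
concurrency threshold are concurrent, the rest delayed. Maximal runs of
temporally continuous events form *interaction segments*; a segment's
duration is the difference between the latest PPA end time and the
earliest PPA start time over the run — deliberately the envelope, not the
sum, of the member intervals.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `lambda` | 0.5 | — | EWMA decay; 0.5 halves a speed's influence per step. Any value in (0, 1]. |
| `n` | 10 | fixes | EWMA window; at 1-h sampling, 10 h of history. |
| `epsilon` | 1.25 | — | Error term: budget may exceed the smoothed speed by 25%, absorbing natural variability. |
| `concurrent_threshold_h` | sampling interval | h | Concurrency is only meaningful at the data's temporal resolution; 1-h data gives a 1-h threshold. |
| `lag_bins_h` | 24, 168, 336, 504 | h | Delayed lags binned at 1 day and 1–3 weeks, the range over which scent-marking responses are plausible. |
| `gap_k` | 3 | — | A PPA is removed when its interval exceeds `mean + 3·sd` of the individual's sampling intervals. |
| `vertices` | 100 | — | Ellipse boundary discretisation (see below). |
| `retain` | 0.95 | — | Home-range hull keeps the 95% of fixes closest to the mean centre. |
| proximity grid | 200/500/1000/2000 m × 0/30/60 min | | The standard baseline grid for the comparison harness. |

`ε = 1.25` is the conventional setting; `λ` and `n` are not fixed by
convention and are therefore configurable and echoed into every run's
resolved configuration.

## Numerical choices

**Validity floor.** The EWMA can fall below the observed segment speed (for
constant speeds the truncated weights sum to less than one), which would
make `v_max·Δt < dist` and the ellipse impossible. The budget is therefore
floored at the observed segment speed, `v_max = max(ε·s_i, v_i)`, and
floored segments are flagged. This guarantees geometric feasibility while
leaving the EWMA untouched elsewhere.

**Head-of-track truncation.** For `i < n` the EWMA sums over the available
history only, without renormalising the weights (a renormalising variant is
available via `ewma_params(renormalize = TRUE)`). The non-renormalised sum
underestimates early budgets slightly; the validity floor prevents any
infeasibility this could cause.

**Gap rule.** The removal rule is stated as "larger than three times the
standard deviation of the sampling intervals", which is degenerate under
near-constant sampling (sd ≈ 0 would reject almost every interval, or
none, depending on the reading). The default here is
`dt > mean + 3·sd`, which reduces to "anything longer than the nominal
interval" for constant sampling and to the familiar 3-sigma rule
otherwise; the literal `k·sd` reading is selectable (`gap_rule = "k_sd"`).

**Ellipse discretisation and exact convex clipping.** All shapes the
method manipulates — PPA ellipses and convex hulls — are convex, so
intersection tests, overlap areas and point membership are computed by
exact convex-polygon geometry (Sutherland–Hodgman clipping, shoelace
areas). Ellipses are discretised at 100 equal parametric angles, which
keeps the polygon-vs-`πab` area error below 0.1%, far below telemetry
noise; degenerate (segment-shaped) ellipses are given a hair-width minor
axis (1e-6 m) so the same machinery applies. A shared boundary point
counts as intersecting.

**Candidate filtering.** Before any polygon work, pairs are pruned by an
exact necessary condition: intersecting ellipses must have centroid
distance at most `a₁ + a₂`, and events beyond the largest lag bin are not
of interest. The pruned set is a guaranteed superset of the intersecting
set (verified against a brute-force all-pairs oracle in the tests), so the
filter affects speed only, never results.

**Continuity rule.** The original description traces "continuous
subsequences" without formalising continuity. Here two successive events
are continuous when their time intervals (the union of both members' PPA
intervals) overlap or abut within one sampling interval. The tolerance
makes tracing robust to interleaved fix times between the two animals.

**Tie-breaks.** A lag exactly on the concurrency threshold is concurrent
("equal to or shorter than"); a lag exactly on a bin boundary is assigned
to that bin (closed lower bound); fixes tied on trimming distance in the
percentage hull retain the earlier timestamp; duplicate timestamps keep
the first occurrence. A delayed lag below the smallest bin is reported
with bin `NA` in events and under bin 0 in monthly summaries.

**Months and timezones.** Timestamps are parsed as UTC; calendar-month
binning follows the track set's configured `tz`. A segment spanning a
month boundary contributes its duration split exactly at the boundary, and
its frequency count to the month it starts in, so monthly durations always
sum to segment totals.

**Projection.** Geographic input is projected to the UTM zone of the data
centroid (WGS84, standard transverse Mercator series) so that all geometry
is Euclidean in metres; the tests verify local isometry against an
independent geodesic computation to 0.1% below 1 km. Planar input is
accepted as-is.

**Directed home-range overlap.** `overlap_proportion(hx, hy)` divides the
intersection area by the area of `hy` — the fraction of *y*'s range shared
with *x* — and is deliberately asymmetric. The "95% of points" hull is
implemented as trimming the 5% of fixes farthest from the mean centre;
which 5% to exclude is not canonical, and a median-centre variant would be
a straightforward extension. Trimming is per time window when windowed
ranges are requested.

## The synthetic generator

`simulate_dyad()` produces correlated random walks with home-range
attraction: Gamma step lengths (mean 500 m per hourly step, shape 1.5),
wrapped-normal turning (SD 40°), and a heading bias toward a range centre
(weight 0.15) — the simplest motion model that yields stable home ranges of
realistic extent (tens of km²) for a large territorial carnivore at 1-h
sampling. On top of the walk, scripted regimes provide ground truth:
`co_movement` (follower copies the leader plus 50 m Gaussian jitter, with
an optional collar time offset), `lagged_revisit` (the follower traverses
the leader's path 24 h later), `avoidance` (repulsion within 2 km), and
`independent` (range centres 50 km apart). `stage_scenario()` chains three
phases — full co-movement, partial accompaniment, separate ranges with
occasional 1-day-lag revisits — emulating a dispersal timeline.

What the generator does *not* emulate: positional error, behavioural-state
switching (resting/hunting), habitat structure, irregular duty-cycling
beyond scheduled gaps, and attraction/avoidance that depends on past
encounters. Passing the recovery tests therefore shows the pipeline is
correct *given its model of movement*, not that the detected interactions
of any real dyad are behaviourally meaningful; on real data the
concurrent/delayed counts remain *potential* interactions.

## Behavioural-pattern labels are heuristic

The four qualitative patterns — following, encounter, latency, avoidance —
have no canonical numeric thresholds. `segment_signature()` always emits
the quantitative record (mean heading difference, mean speed difference,
duration, lag) and only optionally attaches labels: following = concurrent
segment with mean heading difference < 45° lasting ≥ 3 sampling intervals;
encounter = shorter concurrent segment; latency = any delayed event;
avoidance = a dyad-level flag for dyads in the lowest quartile of
concurrent frequency. The thresholds are exposed and the output is marked
heuristic. One caveat worth knowing: event pairs at lag ± one sampling
interval compare *adjacent* movement steps, so their heading difference
includes one turning angle even for a perfect follower; simultaneous pairs
are the clean signal.

## Problem sizes and verification

The test-suite simulations use 10–30-day dyads at 1-h sampling (up to
~1,400 fixes per scenario), 200-PPA-per-side instances for the brute-force
equivalence check, 500 random ellipse pairs against a 10⁵-sample
Monte-Carlo membership oracle built on the focal-distance definition
(independent of the polygon machinery), and 1,000 random parameter draws
against a direct-summation EWMA oracle at 1e-12 relative tolerance. The
acceptance script (`scripts/acceptance.R`) recomputes recovery coverage,
false-positive duration, lag recovery, the desynchronisation contrast,
stage-wise durations and the method comparison from a single seed at these
sizes.

## Known limitations

* Deterministic prisms: every point of a PPA counts equally; probabilistic
  weightings (Brownian bridges, random walks within the prism) are out of
  scope.
* Dyadic only: three-way simultaneous intersections are not modelled;
  multi-animal structure enters through the per-dyad network aggregation.
* The intersection *area* is a diagnostic, not a probability; decisions
  near zero overlap depend on the 100-vertex discretisation (below 0.1% of
  the smaller ellipse, decisions are not guaranteed stable).
* Coarser sampling inflates PPAs and can over-connect dyads; the method is
  best at sampling intervals of roughly 20 min – 1 h for animals of this
  movement scale.
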