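---
title: "Constructing person-specific smoking-risk geofences from EMA streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing person-specific smoking-risk geofences from EMA streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 6)
library(smokefence)
```

## The problem

Smoking is strongly place-conditioned: many people smoke repeatedly at the
same handful of locations (home, a bar, outside work) at characteristic
times of day. A smartphone that knows where those personal high-risk
locations are can deliver a cessation message exactly when its owner walks
into one — a *geofence*-triggered just-in-time intervention. The package
turns a participant's 30-day ecological momentary assessment (EMA) record —
GPS- and time-stamped self-reports of smoking and nonsmoking moments — into
a set of per-3-hour-interval geofence polygons around that person's
high-risk smoking areas, and quantifies how well those polygons would have
captured the recorded smoking events.

All coordinates are consumed already projected to a planar system in US
feet (e.g. NAD83 California Zone 3); the package is agnostic to which
planar feet system is used and performs no geographic reprojection. One
meter is taken as 3.28083333 US survey feet, the convention matching state
plane feet; the international-foot alternative differs by 0.0006% and is
available through the `ft_per_m` configuration constant.

## The procedure

For one participant, `fit_geofences()` runs five stages.

**1. Cleaning and binning.** Smoking reports closer than 5 minutes to the
most recently retained smoking report are dropped — bursts of
near-simultaneous reports are app glitches or double taps, not separate
cigarettes. The scan is greedy and keep-first in chronological order, so a
burst at 0, 3 and 6 minutes keeps 0 and 6: each dropped report is within
the window of a *retained* one, which matches the double-reporting
rationale (a chain rule that compared against the last *raw* report would
silently swallow a long slow burst). Keep-first is the deterministic
choice; a keep-last variant is available (`dedup_keep = "last"`) for
sensitivity checks, and the whole rule commutes with timezone conversion.
Timestamps arrive in UTC and are converted to local time by a fixed
configured offset (default −8 h, Pacific Standard Time). A fixed offset
rather than a tz database keeps runs reproducible; daylight-saving
handling, if wanted, is the caller's responsibility. The local day is then
cut into eight half-open 3-hour bins [0,3), [3,6), …, [21,24) — half-open
because events carry seconds, so "midnight to 2:59" phrased at minute
resolution would leave gaps.

**2. Density estimation.** The cleaned smoking events are smoothed into a
continuous risk surface with a compact-support quartic (biweight) kernel,

$$\lambda(g) \;=\; \sum_{i\,:\,d_{ig}<\tau} \frac{3}{\pi\tau^2}
\Bigl(1-\frac{d_{ig}^2}{\tau^2}\Bigr)^2,$$

evaluated at the centers of square raster cells, where $d_{ig}$ is the
Euclidean distance from cell center $g$ to event $i$. The bandwidth
$\tau$ defaults to 1320 ft (a quarter mile, a proxy for comfortable
walking distance) and the cell side to 150 ft. The kernel's weight is
exactly zero at distance $\tau$ and beyond, and the quartic form is the
standard hotspot-mapping kernel in GIS toolchains. Each kernel integrates
to one, so the surface integrates to the number of events (the mass test
asserts this to 2% on a fine grid); absolute units are irrelevant
downstream because zonal means are min-max normalized, but the raster is
written in events/ft² for clarity. The evaluation grid covers the events'
bounding box padded by $\tau$ on all sides — every kernel's support lies
inside — with the origin snapped down to a cell multiple so that
translated inputs give rigidly translated grids. Evaluation is a plain
event-by-event loop over each event's reachable sub-grid: with EMA-scale
inputs (tens to a few hundred events) nothing faster is warranted.

**3. Zonal risk.** The surface is averaged within each zone of a chosen
partition — irregular blocks read from GeoJSON, or fishnet grids of 500-ft
or 1000-ft square cells (`make_fishnet()`). The "500 ft" / "1000 ft"
figures are cell side lengths, not areas: a 22-ft cell would be
implausible next to the 150-ft density cell. A zone's mean is the
arithmetic mean of the raster values at the cell centers falling inside
it; a center on a shared edge belongs to the zone whose interior lies
up-and-right, so every center counts exactly once. Zones that catch no
center — blocks narrower than the cell size, typically roadway slivers —
"fail to rasterize": they get a missing mean, are excluded from
normalization, terciles and geofences, and are counted and logged, since
such a zone might well be a smoking location the method then cannot fence.
Zones extending beyond the participant's padded surface are also missing
but are tallied separately (`n_outside`): they are outside the analysis
extent, not rasterization failures. Non-missing means are min-max
normalized to [0,1] and rounded to 6 decimals; rounding is part of the
contract because a threshold sweep that includes 1.0 interacts with it (a
raw 0.9999984 becomes 0.999998 and is excluded at threshold 1.0). When
all means are equal the normalized value is defined as 1 for every zone.
Zones at or above the retention threshold — comparison is inclusive, as
"greater than or equal to" — are split into low/medium/high risk
terciles by rank: sorted ascending and cut into three groups as equal as
possible, remainders to the lower groups (7 retained zones split 3/2/2),
with value ties always taking the lower tercile so the classification is
deterministic. A value-range tercile mode (`tercile_mode = "range"`)
exists for choropleth-style maps.

**4. Geofence construction.** Risk is computed once from all of a
participant's smoking events, so a zone's normalized mean is the same at
every hour; the time stratification enters through a second condition.
For each 3-hour bin, a zone is selected iff its normalized mean is at or
above the threshold (default 0.3) *and* at least one of the bin's smoking
events falls inside it. The selected zones are unioned — zones sharing an
edge or a corner merge into one group without any queen/rook adjacency
parameter — and buffered outward by 100 m. The buffer is computed as the
exact Euclidean offset: the set of points within the buffer distance of
the zone union. Joins are therefore perfectly round, and buffers of
nearby groups that overlap dissolve into a single polygon automatically.
Output outlines are extracted by marching-squares contouring of the
distance field on a 20-ft grid (`contour_cell_ft`); with linear
interpolation the outline is accurate to well under 0.1% in area against
the closed form for a buffered square. Whether a point is *captured*
never depends on that resolution: capture uses the exact distance test
(within buffer distance of the zone union), with the perimeter counting
as inside — an intervention triggers on entering the fence.

**5. Evaluation.** Performance is the percent of smoking events falling
inside their own bin's geofence, evaluated in-sample on the same events
that built the fences, as the design intends (the fences summarize a
participant's past month; a held-out mode is a possible extension, not
part of this version). Above 80% is considered good, above 50% adequate.
Per-bin percentages use 1 decimal; bins with no smoking events report
`NA` and are excluded from the across-bin mean. Because the weighting of
an "average across 3-hour periods" is ambiguous, both the unweighted
across-bin mean and the event-weighted pooled percentage are reported.
`threshold_sweep()` repeats construction time-independently (condition
(2) checked against all events) over thresholds 0.1–0.9: retention is
monotone, so capture is non-increasing, and threshold 0 captures every
event lying in a zone with a non-missing mean. `compare_partitions()`
ranks partitions per bin and overall, with ties reported as ties, and
also reports total fenced area — block and fishnet fences can capture the
same events with very different footprints, which matters for alert
burden.

## What the synthetic generator emulates

The study's raw GPS traces are not deposited, so `gen_case_suite()`
builds a four-case synthetic study with the statistical structure the
method assumes. Each participant is an anchors-plus-background mixture:
events cluster isotropically (Gaussian scatter, truncated to the study
extent) around a few anchor locations with time-of-day profiles —
`bin_weights` gives the marginal probability of each 3-hour bin, and each
anchor's 8-vector gives the conditional probability of that anchor given
the bin — while with probability `dispersion` an event instead lands
uniformly anywhere in the 20,000 × 20,000 ft extent. Daily smoking counts
are Poisson at the case's rate; nonsmoking surveys are Poisson capped at
3 per day (the survey burden cap); and a small duplicate rate (4%)
injects double reports under 5 minutes apart to exercise deduplication.
The four cases take their 30-day totals from the study's compliance
quartiles — 16/8, 12/47, 31/67 and 177/61 smoking/nonsmoking events — as
daily rates, and a stream is redrawn on a deterministic sub-seed sequence
until realized totals fall within the observed ranges (12–177 smoking,
8–67 nonsmoking). Three cases are anchor-concentrated (dispersion
0–0.1); the heaviest smoker is dispersed (dispersion 0.58), so that
roughly two zones hold about 42% of its events and the rest scatter —
the regime in which zone-level risk thresholds necessarily miss most
events, the method's known failure mode. The suite also emits the three
partitions: 500-ft and 1000-ft fishnets and a Voronoi pseudo-block
tessellation of 40 uniformly placed seeds, 20% of which are split by a
20-ft corridor whose middle strip becomes its own sliver zone — the
stand-in for roadway blocks that fail to rasterize. Real census blocks
follow street grids and administrative lines, not Voronoi geometry, and
real movement follows road networks; the generator reproduces the
*spatial statistics* the pipeline is sensitive to (clustering scale,
dispersion share, sliver widths, time-of-day structure), not urban form.
Passing tests on it show the machinery is correct under those structures,
not that any particular capture percentage will be attained on real
traces.

## Numerical choices and degenerate inputs

* Normalization with all means equal gives 1 everywhere (so a
  single-hotspot surface still retains its zone); all means missing is an
  error.
* Tercile tie groups move down, never up; an empty retained set is a
  valid, empty classification.
* Zone membership for both cell centers and events nudges the query point
  by +10⁻⁶ ft in x and y, realizing the up-and-right half-open rule
  without boundary ambiguity in floating point.
* Partition overlap validation uses exact convex clipping when both zones
  are convex (shared edges give area exactly 0) and a
  crossing/containment heuristic with a grid area estimate otherwise;
  overlaps above 10⁻⁶ of the smaller zone's area are an error.
* The distance field for buffering is computed exactly within
  `r + 4·contour_cell_ft` of each zone's bounding box and bounded below
  elsewhere, which leaves the contoured outline unchanged while skipping
  far cells.
* Empty selections produce empty multipolygons and zero areas, never
  errors; a participant with no smoking events after deduplication is an
  error instructing the caller to skip them.
* Determinism: all generator randomness flows through one seed per
  participant (sub-seeds derived arithmetically below 2³¹), and geofence
  construction is vertex-identical for identical inputs at a fixed
  contouring resolution.

## Worked example

```{r example}
suite <- gen_case_suite(seed = 7)
fit <- fit_geofences(suite$participants$q25, suite$partitions$fishnet_1000)
summary(fit)
```

```{r plot}
plot(fit)
```

The sweep reproduces the threshold analysis; on the dispersed case it
drops steeply, on concentrated cases it is flat:

```{r sweep}
fit100 <- fit_geofences(suite$participants$q100,
                        suite$partitions$fishnet_1000)
summary(fit100, sweep = TRUE)$sweep
```

## Problem sizes used in the test-suite

The shipped tests run the full four-case suite (30 days, 12–177 smoking
events per case) against all three partitions, kernel grids up to about
110 × 110 cells for oracle comparisons, a τ/50 grid for mass
conservation, and ten suite seeds for the clustered-versus-dispersed
ordering — sizes chosen to exercise every code path at desk scale while
the whole suite stays fast.

## Known limitations

* A fixed isotropic bandwidth smooths all of a person's places equally;
  adaptive and space–time kernels are natural extensions and are
  deliberately out of scope here.
* Risk is purely spatial; the time stratification only gates *where*
  fences appear by bin, it does not estimate a spatio-temporal density.
* Evaluation is in-sample; capture percentages are summaries of fit, not
  out-of-sample predictions.
* The spatially dispersed profile is a structural failure mode: when most
  events occur in low-density zones, no threshold choice fences them
  without fencing everywhere.
* No road networks, dwellings or lat/lon handling; inputs must already be
  planar feet.
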