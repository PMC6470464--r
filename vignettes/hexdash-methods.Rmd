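---
title: "hexdash: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hexdash: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexdash)
```

This vignette records how the package computes what it computes, which
knobs matter, and where the genuinely open design choices were settled.

## The problem and the data model

Surveillance sites hold participant-level records that must be made
explorable to a broad audience without disclosing individuals. `hexdash`
models one dashboard as a pipeline:

```
participants.csv + region.geojson
  -> validated DatasetBundle
  -> hex grid over the region           (uniform hexagons, planar meters)
  -> per-cell aggregates                (counts, indicator num/den, tallies)
  -> suppression                        (privacy floor)
  -> indicator values + chart payloads  (JSON; the package's boundary)
```

A participant record carries a location, four nested cascade flags
(`virally_suppressed` ⊆ `on_art` ⊆ `knows_status` ⊆ `hiv_positive`), sex,
age and three categorical demographics. Nesting violations are *rejected*
at load rather than coerced: a surveillance record whose flags contradict
each other is evidence of an upstream fault, and silently repairing it
would corrupt every downstream ratio. The loader conserves rows —
accepted plus rejected always equals rows read — and reports each
rejection with its reason.

## Geometry: one planar projection for everything

Hexagons must be uniform in ground distance, which degrees of
longitude/latitude are not. All geometry therefore runs in a local
azimuthal equal-area projection (spherical Lambert) centered on the
region's bounding-box center; coordinates enter and leave the package as
WGS84 lon/lat but are projected exactly once. Over a typical HDSS
catchment (tens of km) the projection's distortion is far below one part
per thousand, i.e. centimeters on a 1 km hexagon.

A consequence worth stating: polygon containment (validation, rejection
sampling in the generator) is evaluated on the *projected* boundary, so a
single geometric convention governs the whole package. Testing
containment in raw degrees instead would flip points within a few meters
of the boundary, because straight planar edges curve slightly in degrees.

## The hex grid

Cells are regular hexagons addressed by axial coordinates $(q, r)$,
default orientation flat-top, tiling the region's bounding box plus one
ring of margin. Point assignment converts a planar point to fractional
axial coordinates and applies cube rounding — an $O(1)$ analytic
operation equivalent to choosing the nearest cell center. The test suite
keeps an independent brute-force nearest-center search as the oracle for
this equivalence.

Numerical choices:

- **Tie-break.** Points exactly on a shared edge or corner are
  equidistant from 2–3 centers. Assignment compares the rounded cell
  against its six neighbors with a tolerance of $10^{-9} R$ and resolves
  ties toward the lexicographically smallest $(q, r)$. Determinism here
  is required for reproducible aggregation, not correctness.
- **Cell size.** The default (`circumradius_m: auto` in the config) aims
  for a few hundred populated cells — enough spatial resolution to show
  variation, few enough that cells hold meaningful denominators. A
  bounded fixed-point iteration on the radius targets 150–400 populated
  cells and falls back to the closest achievable count for sparse data.
- **Clipping.** Cells are not clipped to the region boundary; clipping is
  cosmetic and belongs to the renderer, while counts only ever come from
  points inside the boundary anyway.

## Privacy model

Participants are aggregated to cells before anything is exposed; every
payload key is either global or a cell key $(q, r)$, and the only
coordinates that appear downstream are hex vertices and hex centroids.
Suppression removes cells below the floor `max(1, min_count)` *entirely*
(absent, not zeroed — an explicit zero would still reveal "nobody lives
here" at hex precision, and an explicit small count would reveal more).
The default floor of 1 hides only empty cells; a stricter floor is
config-overridable, and the suppression summary (hidden cells, hidden
participants) is returned for audit. Empty cells are counted as "never
shown" rather than "suppressed" in that summary, so the audit numbers
reflect information actually withheld.

## Indicators

The five built-in KPIs follow the 90/90/90 cascade; each ratio's
denominator predicate *is* the previous ratio's numerator predicate, so
cascade linkage (each denominator equals the prior numerator) holds by
construction rather than by arithmetic accident. All values are ratios of
exact integer counts. Two deliberate conventions:

- A ratio with a zero denominator is **undefined** (serialized as null
  with a reason), never 0% or 100%. Small cells would otherwise fabricate
  extreme performance — a 1-resident cell should not display a perfect or
  catastrophic cascade.
- Percentages are rounded to two decimals only at the payload boundary;
  everything internal keeps full precision.

Custom indicators can be declared in the config as field-comparison
expressions (e.g. `on_art & sex == 'female'`); the parser accepts only
participant fields, literals, comparison and boolean operators, so a
config file cannot execute arbitrary code.

Categorical breakdowns support two normalization modes: proportions over
the full base population, or over the subpopulation matching an
indicator's numerator (e.g. education levels among HIV-positive
residents). Switching modes changes bases and proportions, never label
sets; labels missing in the data remain as an explicit `"unknown"` so
counts always conserve.

## Choropleth classification

Default: quantile breaks with 5 classes (config: `equal_interval`
available). Quantile breaks use type-7 quantiles; for distinct values the
class occupancies balance within ±1. Cells whose indicator value is
undefined are excluded and counted, not classified. Two degenerate cases
are flags, not errors: an all-equal vector collapses to a single class,
and heavy ties that produce duplicate break values merge the affected
classes.

## Chart payloads

Payloads are plain structured data ending at class indices and counts —
no colors, no rendering. Fixed choices: population pyramid in 5-year age
bins (0–4 … 85+); the HIV-by-age stacked chart in 10-year bins to limit
sparse cells at hex scale; treemap tiles ordered by descending count with
alphabetical tie-break so layouts are deterministic; donuts carry a
target ring when the indicator has a target; the scatter chart plots one
indicator against another *across displayable cells* — the only
interpretation of a scatter plot consistent with the hex being the finest
unit of analysis. Every payload's totals equal its declared base
population, which the tests verify as a conservation property.

The envelope is `{page, sections[], generated_at, data_version}`.
`generated_at` is the instance's materialization time, not the request
time: the serving contract is that identical `(data_version, params)`
yield byte-identical payloads.

## The dashboard shell

A dashboard folder holds `dashboard.yml` (title, data paths, grid,
indicator list, chart menu, classification, targets) plus the two data
files. Discovery scans the root; a folder with a broken config becomes a
diagnostic, never a failure of its siblings. Refresh hashes the data
files (`tools::md5sum`); unchanged content is a strict no-op, changed
content re-runs the whole pipeline into a fresh instance — the swap is
atomic because the old instance object is untouched until the new one is
complete, and a refresh that fails validation keeps the old state serving
with the error surfaced in the status page.

Serving is a pure function from `(instance, page, params)` to a payload;
invalid requests return structured `4xx`-style error payloads. The
shipped CLI (`exec/hexdash`) wraps this as `synth`, `validate`, `build`
and a polling file-based `serve`; an HTTP transport would be a thin layer
over `serve_page()` and is intentionally outside the tested contract.

## The synthetic generator

`synth_generate()` emulates the data structure of a TasP-like trial
population. Its defaults are the study conditions used throughout the
tests:

- 10,000 participants in 12 isotropic Gaussian homestead clusters
  (σ = 800 m) around uniform centers, rejection-sampled into the region —
  mimicking the settlement clustering that makes equal-area hexes
  population-skewed;
- a young-skewed discrete age pyramid (5-year bins), sex drawn
  Bernoulli(0.5);
- HIV prevalence by age band and sex (peaking in mid-adult women at 0.40,
  ~0.02 in children), the shape of a severe generalized epidemic;
- cascade progression `p_diagnosed = p_art = p_suppressed = 0.9`, i.e.
  the 90/90/90 targets met exactly in expectation;
- education / relationship / employment drawn from fixed categorical
  distributions including an explicit `unknown` mass.

One seed drives a single RNG stream (restored afterwards, so the
generator never perturbs a caller's RNG), and the bundle's `as_of` date
is fixed rather than wall-clock: equal seeds give bit-identical bundles.

What the generator does *not* emulate: measurement error and missingness
mechanisms, household structure (records are independent given their
cluster), migration/longitudinal change, and the real trial's actual
parameter values, which are not public. Passing tests therefore
demonstrate correctness of the machinery — conservation, nesting,
assignment, suppression, parameter recovery at known generating values —
not fidelity to any real population.

## Problem sizes and runtime

The test suite runs bundles of 250–10,000 participants and grids of a few
hundred cells; the pairwise cell-overlap check runs on a deliberately
small 3 km region where an exhaustive convex-clipping comparison is
cheap. Parameter recovery is checked at n = 10,000, where a binomial
standard error of ~0.8 points on a 90% ratio makes the ±2-point
acceptance band comfortably non-trivial. The full suite completes in
well under a minute on one CPU.

## Known limitations

- The projection is spherical, not ellipsoidal; adequate at HDSS scale,
  not for continental regions.
- Unclipped cells mean a hex can visually overhang the boundary.
- No time series: the dashboard shows the current refreshed state only.
- No uncertainty intervals on KPIs; cell-level ratios on small
  denominators are exact but noisy, which the undefined-ratio and
  privacy-floor rules only partially mitigate.
- `mgcv::in.out` treats points exactly on a polygon edge as an
  implementation-defined side; the generator's rejection sampling makes
  such points measure-zero, but hand-built data placed exactly on the
  boundary may validate either way.
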