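# hexdash

Config-driven, privacy-preserving dashboards for population health
surveillance data.

Health and Demographic Surveillance System (HDSS) sites produce
participant-level datasets — in the motivating case, an HIV
Treatment-as-Prevention (TasP) trial population — that are hard to share
with the mixed audience working at such a site: community members, nurses,
field staff and scientists. `hexdash` is the data backend for a two-page
dashboard that makes those datasets explorable without ever exposing an
individual:

- **Overview page** — a choropleth map of the study region binned into
  *uniform hexagons*, colored by a selected key performance indicator
  (KPI), next to global KPI donut charts. Participants are aggregated to
  hex cells; the hex is the finest spatial granularity that ever leaves
  the package, and cells with no (or too few) participants are suppressed
  outright.
- **Analysis page** — a drill-down into one selected hex: population
  pyramid, HIV-by-age stacked bars, treemaps of education / relationship /
  employment, compared side by side with the global indicators, with
  breakdowns normalizable by total population or by an indicator
  population (e.g. HIV-positive residents only).

The shipped indicators follow the UNAIDS 90/90/90 treatment-cascade
targets. For a participant set \(P\) with nested cascade flags
(suppressed ⊆ on ART ⊆ diagnosed ⊆ HIV-positive):

| indicator | definition |
|---|---|
| `trial_participants` | \|P\| |
| `hiv_prevalence` | 100 · \|positive\| / \|P\| |
| `diagnosed_of_positive` | 100 · \|diagnosed\| / \|positive\| (target 90) |
| `art_of_diagnosed` | 100 · \|on ART\| / \|diagnosed\| (target 90) |
| `suppressed_of_art` | 100 · \|suppressed\| / \|on ART\| (target 90) |

All values are ratios of exact integer counts; a zero denominator yields
an explicitly undefined value, never 0 or 100.

A *dashboard* is simply a folder containing a `dashboard.yml` config plus
the two standard data files (`participants.csv`, `region.geojson`).
Dropping a new folder under the served root creates a new dashboard;
content-hash refresh re-runs the pipeline only when data actually changed,
and data that fail validation can never replace a healthy served state.
Pages are served as renderer-agnostic JSON payloads
(`{page, sections[], generated_at, data_version}`).

Because real trial data cannot be redistributed, the package includes a
synthetic generator (`synth_generate()`) that emulates a TasP-like
population: clustered homesteads inside the region polygon, a young-skewed
age pyramid, age/sex-dependent HIV prevalence, and cascade stages drawn so
the nesting holds by construction.

## Worked example

```r
library(hexdash)

params  <- synth_params(n_participants = 5000, seed = 42)
bundle  <- synth_generate(params)
grid    <- build_grid(bundle$region, cell_circumradius = 1000)
agg     <- aggregate_bundle(grid, bundle)
display <- suppress_cells(agg, min_count = 1)
nrow(display$cells)
#> [1] 89

vals <- compute_cascade(cascade_indicators(), bundle$participants)
for (v in vals)
  cat(sprintf("%-22s %.2f%% (%d / %d)\n", v$indicator, v$value,
              v$numerator, v$denominator))
#> hiv_prevalence         13.18% (659 / 5000)
#> diagnosed_of_positive  87.10% (574 / 659)
#> art_of_diagnosed       88.68% (509 / 574)
#> suppressed_of_art      91.36% (465 / 509)
```

5,000 simulated participants land in 89 populated hexes; globally 13.18%
are HIV-positive, and each cascade stage sits near its 90% target (the
generator's default progression probabilities are 0.9). Drilling into the
busiest hex compares it with the global picture:

```r
top  <- which.max(display$cells$participant_count)
cell <- c(display$cells$q[top], display$cells$r[top])
compare_local_global(cascade_indicators(),
                     hexdash:::cell_cascade_values(display, cascade_indicators(), cell),
                     vals)
#>               indicator  local  global difference target
#> 2        hiv_prevalence  12.82   13.18    -0.3595     NA
#> 3 diagnosed_of_positive  80.00   87.10    -7.1017     90
#> 4      art_of_diagnosed  84.09   88.68    -4.5850     90
#> 5     suppressed_of_art  91.89   91.36     0.5363     90
```

This 429-resident hex is 7.1 percentage points behind the global
diagnosis rate — exactly the kind of local shortfall the map is meant to
surface.

The same pipeline is available as a shell tool
(`exec/hexdash synth|validate|build|serve`), which emits, checks and
serves complete dashboard folders.

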