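Package: hexdash
Title: Config-Driven Hex-Binned Dashboards for Population Health Surveillance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable framework that turns participant-level population
    health surveillance data into a two-page dashboard data model: a global
    overview (privacy-preserving hexagonal map plus HIV treatment-cascade
    key performance indicators aligned with the UNAIDS 90/90/90 targets)
    and a per-region analysis page (demographic explanatory charts).
    Participants are aggregated onto a uniform hexagonal grid so that the
    hex cell is the finest spatial granularity ever exposed; empty or
    below-floor cells are suppressed. Dashboards are declared as folders
    holding a config file plus delimited data, discovered and refreshed on
    content change, and served as renderer-agnostic JSON chart payloads.
    Includes a synthetic generator for TasP-like trial populations with
    clustered homesteads and nested cascade stages, so every component is
    testable without access to real surveillance data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mgcv,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
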