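Package: sociospat
Title: Socio-Spatial Trajectory Analytics for Group-Living Central-Place Foragers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the socio-spatial structure of animal and human
    communities from synchronized high-frequency GPS trajectories. Reads Movebank
    and generic fix tables, projects to a planar (UTM) frame, resamples tracks to a
    uniform 5-second epoch grid, and computes dyadic inter-individual proximity
    series with pooled and hourly summaries, per-individual-day travel metrics
    (day range, start-end displacement, radial time profiles), rasterized
    landscape-visitation overlap statistics (dyadic shared/different fractions,
    cumulative group exploration curves, sex-partitioned landscape use), and an
    end-to-end comparison pipeline. Includes a seeded central-place-forager
    simulator with two community archetypes (a cohesive troop and a
    fission-fusion band) for testing and method exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table (>= 1.14.0),
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    geosphere,
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
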