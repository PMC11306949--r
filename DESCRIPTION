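Package: aagraph
Title: Attribute Association Graphs for Case-Control Cohort Exploration
Version: 0.1.0
Authors@R:
    person("AAG", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Builds attribute association graphs (AAGs) from disease/control
    cohort tables. Metric variables are discretized into low/normal/high bands
    around data-driven reference ranges (mean +/- SD, optionally overridden by
    clinical intervals), categorical variables are expanded into one attribute
    per value, and every attribute becomes a graph node carrying absolute
    counts, missing-value-adjusted shares, and frequency/distinction labels for
    both cohorts. Directed edges carry conditional co-occurrence statistics
    classified into high/medium/low conditional difference types. Includes
    configurable graph filtering, export to property-graph bulk-import CSV,
    GraphML and JSON, dashboard-ready binned distributions and conditional bin
    averages, Pearson correlation confidence intervals via the Fisher
    transformation, a synthetic cohort simulator with known ground truth, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
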