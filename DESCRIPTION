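Package: sqlnscea
Title: Cost and Cost-Effectiveness Modelling of Small-Quantity
    Lipid-Based Nutrient Supplements in Rural Uganda
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic cohort model of the cost, cost-efficiency and
    cost-effectiveness of providing daily small-quantity lipid-based nutrient
    supplements (SQ-LNS) to children 6-18 months of age in rural Uganda.
    Combines an activity-based cost model (product and supply chain priced per
    kilogram, village-health-team incentives, and base-district programmatic
    costs extrapolated to all rural districts via spatial and population
    indices) with an effectiveness model (deaths and cases of anaemia,
    developmental disability, stunting and wasting averted as baseline
    prevalence x relative reduction x population), converts health effects to
    disability-adjusted life years with optional discounting, and supports
    scenario sensitivity analyses and mortality-based geographic targeting.
    Includes a seeded synthetic-data generator for the unpublished district
    and activity-cost inputs, calibrated to the published national aggregates.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
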