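#!/usr/bin/env Rscript
# Generate the synthetic rural-Uganda inputs: the district table (areas,
# eligible children, VHT counts, sub-regions), the calibrated Namutumba-like
# base-district activity-cost table, and the cohort projection. The district
# data behind the published national aggregates are not public, so these
# seeded stand-ins carry the structure the model assumes and are calibrated
# to the published cost composition.

library(sqlnscea)

config <- default_uganda_config()
spec <- fixture_spec() # n = 120 districts, seed = 7
fixture <- simulate_fixture(spec, config)

dir.create("results/fixture", recursive = TRUE, showWarnings = FALSE)
write_fixture(fixture, "results/fixture")
write_model_config(config, "results/fixture/uganda_2020.config")

cat(sprintf("districts: %d, eligible children: %s (target %s)\n",
            nrow(fixture$districts),
            format(sum(fixture$districts$eligible_children), big.mark = ","),
            format(spec$national_cohort_target, big.mark = ",")))
in_t <- fixture$districts$sub_region %in% targeting_sub_regions()
cat(sprintf("children in the five targeting sub-regions: %s\n",
            format(sum(fixture$districts$eligible_children[in_t]),
                   big.mark = ",")))
cat(sprintf("activity-cost items: %d rows\n", nrow(fixture$items)))
cat("wrote results/fixture/{districts,activity_costs,cohorts}.csv\n")
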