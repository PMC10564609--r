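#!/usr/bin/env Rscript
# Sensitivity analysis: six single-parameter scenarios (18 % mortality
# reduction, customs elimination, -10 % price, $0.09/sachet price, $0.29 and
# $0.87 VHT incentives) plus simultaneous best and worst cases.

library(sqlnscea)

config <- read_model_config("results/fixture/uganda_2020.config")
districts <- read_districts("results/fixture/districts.csv")
items <- read_activity_costs("results/fixture/activity_costs.csv")
cohorts <- read_cohort_projection("results/fixture/cohorts.csv")

sens <- run_sensitivity(config, default_scenarios(config),
                        districts, items, cohorts)
utils::write.csv(sens$table, "results/sensitivity.csv", row.names = FALSE)

print(sens$table[, c("scenario", "cost_per_child", "cost_per_daly",
                     "cost_per_death")], digits = 5)
rng_daly <- range(sens$table$cost_per_daly)
rng_death <- range(sens$table$cost_per_death)
cat(sprintf("cost per DALY averted ranges $%.0f-$%.0f across scenarios\n",
            rng_daly[1], rng_daly[2]))
cat(sprintf("cost per death averted ranges $%.0f-$%.0f across scenarios\n",
            rng_death[1], rng_death[2]))
cat("wrote results/sensitivity.csv\n")
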