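#!/usr/bin/env Rscript
# Mortality-based geographic targeting: restrict the programme to rural
# districts in the five sub-regions with the worst under-five mortality
# (West Nile, Busoga, Tooro, Ankole, Karamoja) and recompute the model on
# the subset.

library(sqlnscea)

config <- read_model_config("results/fixture/uganda_2020.config")
districts <- read_districts("results/fixture/districts.csv")
items <- read_activity_costs("results/fixture/activity_costs.csv")
cohorts <- read_cohort_projection("results/fixture/cohorts.csv")

tg <- apply_targeting(config, districts, items, cohorts)
full <- run_model(config, districts, items, cohorts)

cat(sprintf("targeted districts: %d of %d\n", nrow(tg$districts),
            nrow(districts)))
cat(sprintf("targeted children: %s per year (%.1f%% of the cohort)\n",
            format(sum(tg$districts$eligible_children), big.mark = ","),
            100 * tg$cohort_share))
cat(sprintf("annual cost: $%.1f M targeted vs $%.1f M untargeted (%.0f%% lower)\n",
            tg$result$average_annual_cost / 1e6,
            full$average_annual_cost / 1e6, 100 * (1 - tg$cost_ratio)))
cat(sprintf("cost per child: $%.2f targeted vs $%.2f untargeted\n",
            tg$result$cost_per_child, full$cost_per_child))

utils::write.csv(data.frame(
  quantity = c("targeted_children", "cohort_share", "targeted_annual_cost_usd",
               "untargeted_annual_cost_usd", "targeted_cost_per_child_usd"),
  value = c(sum(tg$districts$eligible_children), tg$cohort_share,
            tg$result$average_annual_cost, full$average_annual_cost,
            tg$result$cost_per_child)
), "results/targeting.csv", row.names = FALSE)
cat("wrote results/targeting.csv\n")
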