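#!/usr/bin/env Rscript
# Build the 2021-2031 programme cost ledger: product and supply chain priced
# per kilogram, VHT delivery incentives, and base-district activity costs
# extrapolated to every rural district via spatial/population indices, with
# start-up costs annualised over the 10 intervention years.

library(sqlnscea)

config <- read_model_config("results/fixture/uganda_2020.config")
districts <- read_districts("results/fixture/districts.csv")
items <- read_activity_costs("results/fixture/activity_costs.csv")
cohorts <- read_cohort_projection("results/fixture/cohorts.csv")

ledger <- build_cost_ledger(config, districts, items, cohorts)
write_cost_ledger(ledger, "results/cost_ledger.csv")
utils::write.csv(ledger$total_by_year, "results/cost_by_year.csv",
                 row.names = FALSE)

print(ledger)
pc <- ledger$per_child_components
cat(sprintf("per child: product $%.2f, supply chain $%.2f, non-product $%.2f\n",
            pc["product"], pc["supply_chain"], pc["nonproduct_programmatic"]))
cat("activity shares of average annual cost:\n")
print(round(sort(ledger$activity_shares, decreasing = TRUE), 4))
cat("wrote results/cost_ledger.csv, results/cost_by_year.csv\n")
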