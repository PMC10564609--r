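#!/usr/bin/env Rscript
# Base-case cost-effectiveness: cost per child, per DALY averted, per death
# averted and per case averted, on 10-year totals, undiscounted and at 3 %.

library(sqlnscea)

config <- read_model_config("results/fixture/uganda_2020.config")
districts <- read_districts("results/fixture/districts.csv")
items <- read_activity_costs("results/fixture/activity_costs.csv")
cohorts <- read_cohort_projection("results/fixture/cohorts.csv")

res <- run_model(config, districts, items, cohorts)
print(res)

summary_rows <- data.frame(
  quantity = c("cost_per_child_usd", "average_annual_cost_usd",
               "dalys_averted_per_year", "cost_per_daly_usd",
               "cost_per_daly_discounted_usd", "cost_per_death_usd",
               "cost_per_death_discounted_usd"),
  value = c(res$cost_per_child, res$average_annual_cost,
            res$average_annual_dalys, res$undiscounted$cost_per_daly,
            res$discounted$cost_per_daly, res$undiscounted$cost_per_death,
            res$discounted$cost_per_death)
)
per_case <- data.frame(quantity = paste0("cost_per_case_",
                                         names(res$undiscounted$cost_per_case)),
                       value = unname(res$undiscounted$cost_per_case))
utils::write.csv(rbind(summary_rows, per_case), "results/cea_summary.csv",
                 row.names = FALSE)
cat("undiscounted cost per case averted:\n")
print(round(res$undiscounted$cost_per_case))
cat("wrote results/cea_summary.csv\n")
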