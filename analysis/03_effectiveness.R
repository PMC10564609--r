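#!/usr/bin/env Rscript
# Annual deaths and cases averted per outcome (baseline prevalence x relative
# reduction x relevant population) and their conversion to DALYs averted,
# undiscounted and discounted at 3 %.

library(sqlnscea)

config <- read_model_config("results/fixture/uganda_2020.config")
cohorts <- read_cohort_projection("results/fixture/cohorts.csv")

effects <- annual_effect_table(config, cohorts)
write_effect_table(effects, "results/effects.csv")

daly0 <- dalys_averted(effects, config, r = 0)
dalyr <- dalys_averted(effects, config, r = config$discount$rate)
write_daly_table(daly0, "results/dalys_undiscounted.csv")
write_daly_table(dalyr, "results/dalys_discounted.csv")

avg <- sapply(split(effects, effects$outcome), function(d) mean(d$cases_averted))
cat("average annual effects (cases/deaths averted):\n")
print(round(avg))
cat(sprintf("average annual DALYs averted (undiscounted): %.0f\n",
            mean(daly0$total_dalys_averted)))
cat("assumed unpublished parameters:\n")
str(attr(daly0, "assumed_parameters"))
cat("wrote results/effects.csv, results/dalys_*.csv\n")
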