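test_that("cost-effectiveness ratios reproduce the published headline identities", {
  expect_equal(cer(58.7e6, 242292), 58.7e6 / 242292)
  expect_equal(round(cer(58.7e6, 242292), 1), 242.3)
  expect_equal(round(cer(58.7e6, 3689)), 15912) # printed as 15 914
  expect_equal(cer(0, 100), 0)
  expect_true(is.na(cer(100, 0)))
  expect_error(cer(-1, 10), "non-negative")
})

test_that("scenario overrides are applied functionally and validated", {
  spec <- scenario_spec("none", list())
  cfg <- apply_scenario(base_config, spec)
  cfg$scenario_name <- base_config$scenario_name
  expect_equal(cfg, base_config)

  best <- default_scenarios(base_config)[[7]]
  cfgb <- apply_scenario(base_config, best)
  expect_equal(cfgb$costs$customs_usd_per_kg, 0)
  expect_equal(cfgb$costs$price_per_carton_usd, 33.30 * 0.9)
  expect_equal(cfgb$costs$vht_incentive_usd_per_delivery, 0.29)
  # original untouched, application idempotent
  expect_equal(base_config$costs$customs_usd_per_kg, 1.01)
  expect_equal(apply_scenario(cfgb, best), cfgb)

  worst <- default_scenarios(base_config)[[8]]
  cfgw <- apply_scenario(base_config, worst)
  expect_equal(cfgw$outcomes$mortality$relative_reduction, 0.18)
  expect_equal(cfgw$costs$price_per_carton_usd, 0.09 * 546)
  expect_equal(cfgw$costs$vht_incentive_usd_per_delivery, 0.87)

  expect_error(apply_scenario(base_config,
                              scenario_spec("bad", list("costs.nope" = 1))),
               "costs.nope")
  expect_error(apply_scenario(base_config, scenario_spec(
    "invalid", list("outcomes.mortality.relative_reduction" = 1.5))),
    "invalid configuration")
})

test_that("run_model ties every ratio to its cost and effect totals", {
  fx <- default_fixture
  res <- run_model(base_config, fx$districts, fx$items, fx$cohorts)
  u <- res$undiscounted
  expect_equal(u$cost_per_daly, u$total_cost / u$dalys_averted,
               tolerance = 1e-9)
  expect_equal(u$cost_per_death,
               u$total_cost / sum(res$effects$cases_averted[
                 res$effects$outcome == "mortality"]), tolerance = 1e-9)
  expect_equal(res$cost_per_child,
               res$average_annual_cost / res$ledger$average_annual_cohort,
               tolerance = 1e-9)
  # determinism: identical inputs give identical outputs
  res2 <- run_model(base_config, fx$districts, fx$items, fx$cohorts)
  expect_identical(res$undiscounted, res2$undiscounted)
})

test_that("the sensitivity table behaves like the published scenario analysis", {
  fx <- default_fixture
  sens <- run_sensitivity(base_config, default_scenarios(base_config),
                          fx$districts, fx$items, fx$cohorts)
  expect_equal(nrow(sens$table), 9) # base + six single + best + worst
  expect_equal(sens$table$scenario[1], "base")

  tab <- sens$table
  pick <- function(s, col) tab[tab$scenario == s, col]
  base_daly <- pick("base", "cost_per_daly")
  base_death <- pick("base", "cost_per_death")

  # removing a cost component cannot raise the ratio
  expect_lt(pick("customs_eliminated", "cost_per_daly"), base_daly)
  # pure-effect rescaling: costs fixed, deaths scale by 18/27
  expect_equal(pick("mortality_rr_18", "cost_per_death"),
               base_death * 27 / 18, tolerance = 1e-9)
  # bracketing
  expect_lt(pick("best_case", "cost_per_daly"), base_daly)
  expect_gt(pick("worst_case", "cost_per_daly"), base_daly)
  expect_lt(pick("best_case", "cost_per_death"), base_death)
  expect_gt(pick("worst_case", "cost_per_death"), base_death)

  dup <- list(scenario_spec("x", list()), scenario_spec("x", list()))
  expect_error(run_sensitivity(base_config, dup, fx$districts, fx$items,
                               fx$cohorts), "duplicate")
  expect_error(run_sensitivity(base_config, list(), fx$districts, fx$items,
                               fx$cohorts), "at least one")
})

test_that("geographic targeting filters districts and preserves per-child components", {
  fx <- default_fixture
  tg <- apply_targeting(base_config, fx$districts, fx$items, fx$cohorts)
  expect_true(all(tg$districts$sub_region %in% targeting_sub_regions()))
  expect_equal(tg$cohort_share,
               sum(tg$districts$eligible_children) /
                 sum(fx$districts$eligible_children))

  full <- run_model(base_config, fx$districts, fx$items, fx$cohorts)
  pc_t <- tg$result$ledger$per_child_components
  pc_f <- full$ledger$per_child_components
  for (comp in c("product", "supply_chain", "vht_incentives"))
    expect_equal(unname(pc_t[comp]), unname(pc_f[comp]))

  # selecting every sub-region reproduces the untargeted run
  all_tg <- apply_targeting(base_config, fx$districts, fx$items, fx$cohorts,
                            sub_regions = unique(fx$districts$sub_region))
  expect_equal(all_tg$cohort_share, 1)
  expect_equal(all_tg$result$average_annual_cost, full$average_annual_cost)

  expect_error(apply_targeting(base_config, fx$districts, fx$items,
                               fx$cohorts, sub_regions = character()),
               "at least one")
  expect_error(apply_targeting(base_config, fx$districts, fx$items,
                               fx$cohorts, sub_regions = "Atlantis"),
               "Atlantis")
})
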