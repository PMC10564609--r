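test_that("product-chain unit arithmetic matches the published rates", {
  cst <- cost_parameters()
  d <- intervention_design()
  expect_equal(cost_per_sachet(cst), 33.30 / 546)
  expect_equal(round(cost_per_sachet(cst), 3), 0.061)
  expect_equal(cost_per_sachet(cost_parameters(price_per_carton_usd = 546)), 1)
  expect_equal(cost_per_sachet(cost_parameters(price_per_carton_usd = 0)), 0)
  expect_error(cost_per_sachet(cost_parameters(sachets_per_carton = 0)),
               "positive")

  expect_equal(product_cost_per_child(cst, d), 365 * 33.30 / 546)
  expect_equal(product_cost_per_child(cst, intervention_design(sachets_per_day = 0)), 0)
  # linearity in the carton price
  expect_equal(
    product_cost_per_child(cost_parameters(price_per_carton_usd = 66.60), d),
    2 * product_cost_per_child(cst, d))

  expect_equal(annual_mass_kg_per_child(d), 7.3)
  expect_equal(supply_chain_cost_per_child(cst, d), (0.31 + 1.01 + 0.17) * 7.3)
  expect_equal(round(supply_chain_cost_per_child(cst, d)), 11)
  expect_equal(
    supply_chain_cost_per_child(cost_parameters(customs_usd_per_kg = 0), d),
    (0.31 + 0.17) * 7.3)
  expect_equal(
    supply_chain_cost_per_child(cst, intervention_design(sachet_mass_g = 1e-12)),
    (0.31 + 1.01 + 0.17) * 365 * 1e-15)

  expect_equal(incentive_cost_per_child(cst, d), 0.44 * 4)
  expect_equal(
    incentive_cost_per_child(cost_parameters(vht_incentive_usd_per_delivery = 0.87), d),
    3.48)
  expect_equal(
    incentive_cost_per_child(cst, intervention_design(deliveries_per_year = 1e-9)),
    0.44e-9)
})

test_that("extrapolation indices reproduce the worked area example and self-index to 1", {
  base <- list(area_km2 = 820, eligible_children = 10000, vht_count = 1000)
  bigger <- list(area_km2 = 1585, eligible_children = 20000, vht_count = 2000)
  expect_equal(round(extrapolation_index(bigger, base, "spatial"), 2), 1.93)
  for (k in index_kinds())
    expect_equal(extrapolation_index(base, base, k), 1)
  expect_equal(extrapolation_index(bigger, base, "child_pop"), 2)
  expect_equal(extrapolation_index(bigger, base, "vht_pop"), 2)
  # doubled children and doubled VHTs leave the ratio-of-ratios at 1
  expect_equal(extrapolation_index(bigger, base, "vht_child_ratio"), 1)
  expect_error(extrapolation_index(bigger, list(area_km2 = 0), "spatial"),
               "positive")
  expect_error(extrapolation_index(bigger, base, "made_up"))
})

test_that("activity costs scale by the district index and sum across districts", {
  dd <- toy_districts()
  items <- data.frame(activity = "capacity_building",
                      input_category = "transport", phase = "recurring",
                      base_cost_usd = 1000, index_kind = "spatial",
                      stringsAsFactors = FALSE)
  scaled <- scale_activity_costs(items, dd, dd[1, ])
  expect_equal(scaled$cost_usd[scaled$district == "Base"], 1000)
  expect_equal(scaled$cost_usd[scaled$district == "Twice"], 2000)
  expect_equal(scaled$cost_usd[scaled$district == "Same"], 1000)
  # two districts identical to the base double the national total
  expect_equal(sum(scaled$cost_usd[scaled$district != "Twice"]), 2 * 1000)
  expect_error(scale_activity_costs(items, dd, list(name = "Elsewhere")),
               "present")
  bad <- items; bad$index_kind <- "bogus"
  expect_error(scale_activity_costs(bad, dd, dd[1, ]), "index_kind")
})

test_that("the cost ledger is linear in unit prices and additive over districts", {
  fx <- default_fixture
  led <- build_cost_ledger(base_config, fx$districts, fx$items, fx$cohorts)

  # district sums equal national activity totals
  nat <- stats::aggregate(cost_usd ~ activity, data = led$costs, FUN = sum)
  by_d <- stats::aggregate(cost_usd ~ activity + district, data = led$costs,
                           FUN = sum)
  re <- stats::aggregate(cost_usd ~ activity, data = by_d, FUN = sum)
  expect_equal(re$cost_usd, nat$cost_usd, tolerance = 1e-6)

  # grand total equals sum of yearly totals
  expect_equal(sum(led$total_by_year$cost_usd), sum(led$costs$cost_usd),
               tolerance = 1e-9)

  # doubling the carton price exactly doubles the product line, nothing else
  cfg2 <- base_config
  cfg2$costs$price_per_carton_usd <- 2 * cfg2$costs$price_per_carton_usd
  led2 <- build_cost_ledger(cfg2, fx$districts, fx$items, fx$cohorts)
  tot <- function(l, a) sum(l$costs$cost_usd[l$costs$activity == a])
  expect_equal(tot(led2, "product"), 2 * tot(led, "product"))
  expect_equal(tot(led2, "capacity_building"), tot(led, "capacity_building"))
  expect_equal(tot(led2, "vht_incentives"), tot(led, "vht_incentives"))

  expect_error(build_cost_ledger(base_config, fx$districts[0, ], fx$items,
                                 fx$cohorts), "empty")
})

test_that("per-child components on the default fixture match the published breakdown", {
  led <- build_cost_ledger(base_config, default_fixture$districts,
                           default_fixture$items, default_fixture$cohorts)
  pc <- led$per_child_components
  expect_equal(unname(pc["product"]), 22.26, tolerance = 1e-3)
  expect_equal(unname(pc["supply_chain"]), 10.88, tolerance = 1e-3)
  expect_equal(unname(pc["vht_incentives"]), 1.76)
  expect_equal(unname(pc["nonproduct_programmatic"]), 19, tolerance = 0.5 / 19)
  expect_gt(led$cost_per_child, 51.5)
  expect_lt(led$cost_per_child, 53.5)
})

test_that("zero programmatic and incentive costs reduce per-child cost to product + supply chain", {
  cfg <- base_config
  cfg$costs$vht_incentive_usd_per_delivery <- 0
  dd <- toy_districts()
  no_items <- data.frame(activity = character(), input_category = character(),
                         phase = character(), base_cost_usd = numeric(),
                         index_kind = character(), stringsAsFactors = FALSE)
  cp <- cohort_projection(2022:2031, rep(40000, 10))
  led <- build_cost_ledger(cfg, dd, no_items, cp)
  expect_equal(led$cost_per_child,
               product_cost_per_child(cfg$costs, cfg$design) +
                 supply_chain_cost_per_child(cfg$costs, cfg$design))
})

test_that("district and activity tables round-trip and reject malformed input", {
  fx <- default_fixture
  dpath <- withr::local_tempfile(fileext = ".csv")
  write_districts(fx$districts, dpath)
  expect_equal(read_districts(dpath), fx$districts)
  apath <- withr::local_tempfile(fileext = ".csv")
  write_activity_costs(fx$items, apath)
  got <- read_activity_costs(apath)
  rownames(got) <- rownames(fx$items) <- NULL
  expect_equal(got, fx$items)

  bad <- fx$districts[, -2]
  write_districts(bad, dpath)
  expect_error(read_districts(dpath), "missing column")
})
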