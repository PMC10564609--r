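test_that("district generation is seed-deterministic and hits the national total exactly", {
  spec <- fixture_spec()
  d1 <- gen_districts(spec)
  d2 <- gen_districts(spec)
  expect_identical(d1, d2)
  expect_equal(sum(d1$eligible_children), 1118340)
  expect_equal(d1$name[1], "Namutumba")
  expect_equal(d1$area_km2[1], 820)
  expect_true(all(d1$area_km2 > 0 & d1$eligible_children > 0 & d1$vht_count > 0))

  other <- gen_districts(fixture_spec(seed = 8))
  expect_false(identical(d1$area_km2, other$area_km2))
})

test_that("the five targeting sub-regions hold the study's share of children", {
  d <- gen_districts(fixture_spec())
  in_t <- d$sub_region %in% targeting_sub_regions()
  expect_equal(sum(d$eligible_children[in_t]), 396808)
})

test_that("a single-district fixture degenerates to the base district with the full cohort", {
  d <- gen_districts(fixture_spec(n_districts = 1))
  expect_equal(nrow(d), 1)
  expect_equal(d$eligible_children, 1118340)
  expect_equal(d$name, "Namutumba")
})

test_that("calibration meets the share and per-child targets on the default fixture", {
  fx <- default_fixture
  led <- build_cost_ledger(base_config, fx$districts, fx$items, fx$cohorts)
  shares <- led$activity_shares
  targets <- fx$spec$activity_share_targets
  for (a in names(targets)) {
    expect_lt(abs(shares[[a]] - targets[[a]]), 0.005,
              label = sprintf("share of %s (%.4f vs %.4f)", a, shares[[a]],
                              targets[[a]]))
  }
  expect_lt(abs(led$per_child_components[["nonproduct_programmatic"]] - 19),
            0.50)
  expect_gt(led$cost_per_child, 51.5)
  expect_lt(led$cost_per_child, 53.5)
})

test_that("a zero non-product target emits no activity items", {
  spec0 <- fixture_spec(nonproduct_per_child_target = 0)
  d <- gen_districts(spec0)
  items <- gen_base_activity_costs(spec0, d, base_config)
  expect_equal(nrow(items), 0)
  led <- build_cost_ledger(base_config, d, items,
                           gen_cohort_projection(spec0, base_config$design))
  expect_equal(led$cost_per_child,
               product_cost_per_child(base_config$costs, base_config$design) +
                 supply_chain_cost_per_child(base_config$costs, base_config$design) +
                 incentive_cost_per_child(base_config$costs, base_config$design),
               tolerance = 1e-9)
})

test_that("infeasible share targets are rejected", {
  expect_error(fixture_spec(activity_share_targets = c(product = 0.7,
                                                       product_supply_chain = 0.2,
                                                       capacity_building = 0.2,
                                                       logistics = 0.2)),
               "at most 1")
})

test_that("fixture tables written twice from the same seed are byte-identical", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_fixture(simulate_fixture(fixture_spec(seed = 123)), dir1)
  write_fixture(simulate_fixture(fixture_spec(seed = 123)), dir2)
  for (f in c("districts.csv", "activity_costs.csv", "cohorts.csv")) {
    expect_identical(readBin(file.path(dir1, f), "raw", 1e6),
                     readBin(file.path(dir2, f), "raw", 1e6),
                     label = f)
  }
})
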