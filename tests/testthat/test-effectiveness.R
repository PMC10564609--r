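test_that("cases averted are baseline x relative reduction x population", {
  expect_equal(round(averted(0.468, 0.30, 1118340)), 157015)
  expect_equal(round(averted(0.2028, 0.30, 1118340)), 68040)
  expect_equal(averted(0.5, 0, 1e6), 0)
  expect_error(averted(1.2, 0.3, 100), "\\[0, 1\\]")
  expect_error(averted(0.5, -0.1, 100), "\\[0, 1\\]")
  expect_error(averted(0.5, 0.3, -100), "non-negative")
})

test_that("longitudinal wasting prevalence applies the correction factor", {
  expect_equal(longitudinal_prevalence(0.078, 2.6), 0.2028)
  expect_equal(longitudinal_prevalence(0.078, 6), 0.468)
  expect_equal(longitudinal_prevalence(0.3, 1), 0.3)
  expect_error(longitudinal_prevalence(0.3, 4), "exceeds 1")
})

test_that("deaths averted reproduce the published count and rescale with the RR", {
  expect_equal(deaths_averted(base_config, 1118340),
               0.0122 * 0.27 * 1118340)
  # printed 3689; the closed form lands within 0.2 % (rounding of 1.22 %)
  expect_lt(abs(deaths_averted(base_config, 1118340) - 3689) / 3689, 0.002)

  cfg18 <- apply_scenario(base_config, scenario_spec(
    "rr18", list("outcomes.mortality.relative_reduction" = 0.18)))
  expect_equal(deaths_averted(cfg18, 1118340),
               deaths_averted(base_config, 1118340) * 18 / 27)
  expect_equal(deaths_averted(base_config, 0), 0)
})

test_that("the annual effect table matches closed-form products per outcome", {
  cp <- cohort_projection(2022, 1118340)
  eff <- annual_effect_table(base_config, cp)
  get <- function(o) eff$cases_averted[eff$outcome == o]

  expect_equal(get("stunting"), 0.42 * 0.12 * 1118340)
  expect_equal(get("wasting_cross_sectional"), 0.078 * 0.14 * 1118340)
  expect_equal(get("mortality"), 0.0122 * 0.27 * 1118340)
  expect_equal(round(get("developmental_disability")),
               round(559170 * 0.0656 * 0.16)) # ~5869, "almost 6000"
  expect_equal(round(get("wasting_longitudinal_lower")), 68040)
  expect_equal(round(get("wasting_longitudinal_upper")), 157015)

  # anaemia: 9-18 and 18-24 bands at steady-state occupancy; 6-9 outside window
  slice <- 1118340 / 12
  expected_anaemia <- 0.41 * 0.28 * 9 * slice + 0.31 * 0.28 * 6 * slice
  expect_equal(get("anaemia_mod_sev"), expected_anaemia)

  # full-cohort-per-band convention uses the whole cohort in both bands
  eff2 <- annual_effect_table(base_config, cp,
                              anaemia_person_base = "full_cohort_per_band")
  expect_equal(eff2$cases_averted[eff2$outcome == "anaemia_mod_sev"],
               (0.41 + 0.31) * 0.28 * 1118340)
})

test_that("effect counts are linear in RR and cohort and bounded by baseline cases", {
  set.seed(11)
  for (i in 1:10) {
    n <- stats::runif(1, 1e4, 2e6)
    eff <- annual_effect_table(base_config, cohort_projection(2022, n))
    eff2 <- annual_effect_table(base_config, cohort_projection(2022, 2 * n))
    expect_equal(eff2$cases_averted, 2 * eff$cases_averted)
    # RR <= 1 bounds averted cases by baseline cases in the same population
    for (o in names(base_config$outcomes)) {
      spec <- base_config$outcomes[[o]]
      if (is.data.frame(spec$baseline)) next
      row <- eff$outcome == o
      if (!any(row)) next
      expect_lte(eff$cases_averted[row],
                 spec$baseline * eff$population_base[row])
    }
  }

  cfg0 <- base_config
  for (o in names(cfg0$outcomes)) cfg0$outcomes[[o]]$relative_reduction <- 0
  eff0 <- annual_effect_table(cfg0, cohort_projection(2022, 1118340))
  expect_true(all(eff0$cases_averted == 0))
})

test_that("month-slice enumeration reproduces every closed-form population base", {
  d <- base_config$design
  cp <- cohort_projection(2022, 1118340)
  eff <- annual_effect_table(base_config, cp)
  windows <- list(mortality = c(6, 18), developmental_disability = c(18, 24))
  for (o in names(windows)) {
    expect_identical(eff$population_base[eff$outcome == o],
                     brute_band_count(1118340, windows[[o]], d))
  }
  # anaemia base is the sum of the two in-window band enumerations
  expect_identical(eff$population_base[eff$outcome == "anaemia_mod_sev"],
                   brute_band_count(1118340, c(9, 18), d) +
                     brute_band_count(1118340, c(18, 24), d))
})
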