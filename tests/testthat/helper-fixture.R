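# Shared objects for the suite: the base configuration and the default
# calibrated synthetic fixture (seeded, so identical in every run).
base_config <- default_uganda_config()
default_fixture <- simulate_fixture(fixture_spec(), base_config)

# A tiny three-district table for hand-checkable cost arithmetic.
toy_districts <- function() {
  data.frame(
    name = c("Base", "Twice", "Same"),
    area_km2 = c(820, 1640, 820),
    eligible_children = c(10000, 20000, 10000),
    vht_count = c(1000, 2000, 1000),
    sub_region = c("Busoga", "West Nile", "Tooro"),
    stringsAsFactors = FALSE
  )
}

# Brute-force oracle: sum steady-state one-month slices over integer months.
brute_band_count <- function(annual_cohort, band, design) {
  slice <- annual_cohort / design$duration_months
  sum(rep(slice, band[2] - band[1]))
}
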