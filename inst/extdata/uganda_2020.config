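scenario_name: base
design:
  start_age_months: 6.0
  duration_months: 12.0
  sachets_per_day: 1.0
  sachet_mass_g: 20.0
  deliveries_per_year: 4.0
  start_year: 2021.0
  horizon_years: 10.0
  startup_years: 1.0
outcomes:
  mortality:
    name: mortality
    baseline: 0.0122
    relative_reduction: 0.27
    effect_window:
    - 6.0
    - 18.0
    counted_in_dalys: yes
    disability_weight: 1.0
    disability_duration_years: remaining_life_expectancy
  anaemia_mod_sev:
    name: anaemia_mod_sev
    baseline:
    - start_month: 6.0
      end_month: 9.0
      prevalence: 0.59
    - start_month: 9.0
      end_month: 18.0
      prevalence: 0.41
    - start_month: 18.0
      end_month: 24.0
      prevalence: 0.31
    relative_reduction: 0.28
    effect_window:
    - 9.0
    - 24.0
    counted_in_dalys: yes
    disability_weight: .na.real
    disability_duration_years: 1.25
  developmental_disability:
    name: developmental_disability
    baseline: 0.0656
    relative_reduction: 0.16
    effect_window:
    - 18.0
    - 24.0
    counted_in_dalys: yes
    disability_weight: 0.011
    disability_duration_years: remaining_life_expectancy
  stunting:
    name: stunting
    baseline: 0.42
    relative_reduction: 0.12
    effect_window:
    - 6.0
    - 18.0
    counted_in_dalys: no
  wasting_cross_sectional:
    name: wasting_cross_sectional
    baseline: 0.078
    relative_reduction: 0.14
    effect_window:
    - 6.0
    - 18.0
    counted_in_dalys: no
  wasting_longitudinal:
    name: wasting_longitudinal
    baseline: 0.078
    relative_reduction: 0.3
    effect_window:
    - 6.0
    - 18.0
    counted_in_dalys: no
    correction_factors:
      lower: 2.6
      upper: 6.0
costs:
  price_per_carton_usd: 33.299999999999997
  sachets_per_carton: 546.0
  intl_shipping_usd_per_kg: 0.31
  customs_usd_per_kg: 1.01
  domestic_usd_per_kg: 0.17
  vht_incentive_usd_per_delivery: 0.44
  deflator_table: []
discount:
  rate: 0.03
  reference_year: 2021.0
life_table:
  remaining_life_expectancy_years: 62.5
anaemia_severity_split:
  moderate: 0.9
  severe: 0.1

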