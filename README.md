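# sqlnscea

Cost, cost-efficiency and cost-effectiveness modelling of daily
small-quantity lipid-based nutrient supplements (SQ-LNS) for children 6–18
months of age in rural Uganda.

SQ-LNS is a 20 g/day fortified food product with strong trial evidence of
reducing child mortality, stunting, wasting, anaemia and developmental
delay. Policy uptake needs cost numbers next to the effect sizes. This
package implements a deterministic modelling framework for a national
programme delivered through Uganda's Village Health Team (VHT) volunteer
network over 2021–2031 (one start-up year, ten intervention years), from a
societal perspective in 2020 US dollars. It is aimed at nutrition
economists and modellers who want to reproduce, stress-test or re-parameterise
the analysis (e.g. for another setting).

## The model

Three chained components:

- **Cost model** — product priced per carton ($33.30 / 546 sachets ≈
  $0.061/sachet), supply chain per kg (shipping $0.31 + customs $1.01 +
  domestic $0.17, at 7.3 kg/child-year), VHT incentives ($0.44 × 4
  deliveries/year), plus activity-based programmatic costs extrapolated
  from a base district to all rural districts by spatial, child-population,
  VHT-population and VHT-to-child-ratio indices.
- **Effectiveness model** — for each outcome *o*, annual cases averted are

  `averted_o = baseline_o × relative_reduction_o × population_o`

  with age-windowed populations from a steady-state cohort model
  (mortality/stunting/wasting 6–18 mo, anaemia 9–24 mo, developmental
  disability 18–24 mo).
- **DALY model and CEA** — DALYs averted = YLL + YLD with optional
  continuous discounting (no age weighting); cost-effectiveness ratios are
  10-year cost totals over 10-year effect totals, undiscounted and at 3 %.

A seeded synthetic-data generator supplies the non-public inputs (district
table, base-district activity costs), calibrated in closed form so the
default fixture reproduces the published national cost composition. A
scenario engine covers the six published sensitivity analyses plus best and
worst cases, and a targeting routine restricts the programme to the five
highest-mortality sub-regions.

## Worked example

```r
library(sqlnscea)

config  <- default_uganda_config()
fixture <- simulate_fixture(fixture_spec(), config)  # 120 districts, seed 7
res     <- run_model(config, fixture$districts, fixture$items, fixture$cohorts)
res
#> <cea_result> base
#>   average annual cost: $58.3 M; cost per child: $52.14
#>   deaths averted/yr: 3684; DALYs averted/yr: 245443
#>   cost per DALY: $238 (undiscounted), $501 (discounted 3%)
#>   cost per death: $15828 (undiscounted)
```

Reading the output: reaching ~1.12 million children a year costs ~$58 M
(2020 USD), $52.14 per child — $22.26 product, $10.88 supply chain, $19.00
non-product programmatic. The programme averts ~3,684 deaths, ~145,000
moderate/severe anaemia cases and ~5,869 developmental-disability cases per
year, totalling ~245,000 DALYs; dividing 10-year costs by 10-year DALYs
gives $238 per DALY averted (discounting both streams at 3 % raises it,
since a death averted loses a long discounted life-year stream). Scenario
and targeting analyses:

```r
sens <- run_sensitivity(config, default_scenarios(config),
                        fixture$districts, fixture$items, fixture$cohorts)
range(sens$table$cost_per_daly)   # ~191 (best case) to ~427 (worst case)

tg <- apply_targeting(config, fixture$districts, fixture$items, fixture$cohorts)
tg$result$average_annual_cost / 1e6   # ~20.5: -65% by targeting 5 sub-regions
```

## Analysis workflow

The `analysis/` scripts run the full study end to end, writing tables under
`results/`:

```sh
Rscript analysis/01_simulate.R      # synthetic districts, costs, cohorts
Rscript analysis/02_costs.R         # cost ledger and composition
Rscript analysis/03_effectiveness.R # effects and DALYs averted
Rscript analysis/04_cea.R           # cost-effectiveness ratios
Rscript analysis/05_sensitivity.R   # scenario table
Rscript analysis/06_targeting.R     # geographic targeting
```

A bundled configuration file (`inst/extdata/uganda_2020.config`, YAML;
unknown keys are rejected) encodes the default parameterisation and can be
edited for other settings.

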