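---
title: "Modelling the cost-effectiveness of SQ-LNS in rural Uganda: methods and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost-effectiveness of SQ-LNS in rural Uganda: methods and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sqlnscea)
```

## The model

`sqlnscea` estimates what it would cost, and what health it would buy, to
give every child in rural Uganda a daily 20 g sachet of small-quantity
lipid-based nutrient supplement (SQ-LNS) from 6 to 18 months of age,
delivered quarterly to households by the existing Village Health Team (VHT)
volunteer network. The programme runs 2021–2031: one start-up year followed
by ten intervention years. Costs are societal (they include opportunity
costs such as caregiver time), in 2020 US dollars.

The model is deterministic throughout. Three components are chained:

1. **Costs.** The product is priced per carton ($33.30 for 546 sachets,
   ≈ $0.061/sachet); the supply chain per kilogram of product (international
   shipping and handling $0.31/kg, customs clearance $1.01/kg, domestic
   transport/storage/handling $0.17/kg; a child consumes 7.3 kg/year); VHT
   incentives per delivery ($0.44 × 4 deliveries/year). All other
   programmatic costs are activity-based: each activity × input-category
   item has a base cost in a Namutumba-like reference district and is
   extrapolated to every other rural district by an index — district area
   for transport, eligible-child population for per-child inputs, VHT
   population for per-worker inputs, or the VHT-to-child ratio. A district
   of 1585 km² against a base of 820 km² carries index 1585/820 = 1.93 on
   spatial items. Start-up items occur once and are annualised (divided
   evenly across the ten intervention years) in all "average annual"
   figures.

2. **Effectiveness.** For each outcome, cases averted per year equal
   baseline prevalence × relative reduction × relevant population. Relative
   reductions come from meta-analyses of randomised trials: mortality 27 %,
   moderate/severe anaemia 28 %, language-domain developmental disability
   16 %, stunting 12 %, cross-sectional wasting 14 %, longitudinal wasting
   30 %. Effects are windowed by age: mortality, stunting and wasting over
   the full 6–18-month supplementation window; anaemia from 9 to 24 months
   (effects emerge after ~3 months and persist ~6 months after
   supplementation ends) with age-banded baselines (41 % at 9–18 months,
   31 % at 18–24 months); developmental disability in the 18–24-month band.

3. **DALYs and ratios.** DALYs averted are years of life lost (deaths ×
   remaining life expectancy) plus years lived with disability (cases ×
   duration × disability weight) for anaemia and developmental disability.
   Stunting and wasting carry no disability weight and contribute zero.
   Cost-effectiveness ratios divide 10-year cost totals by 10-year effect
   totals (not means of annual ratios), undiscounted and discounted at 3 %.

## Demographic convention

The annual eligible cohort is assumed uniformly distributed over the twelve
supplementation months, so each one-month age slice holds `cohort / 12`
children at steady state. Age bands outside 6–18 months reuse the same slice
size — the 18–24-month band holds `6 × cohort/12` children who have aged out
of supplementation. This closed form equals a month-by-month enumeration
exactly (a property the test suite asserts) and is what produces the
published magnitude of ~5,900 developmental-disability cases averted
(559,170 × 0.066 × 0.16).

For anaemia, the person base for the 9–24-month window is ambiguous in the
source material: steady-state band occupancy (the default,
`anaemia_person_base = "band_occupancy"`) yields ≈ 145,000 cases averted per
year, while exposing the full cohort in each band
(`"full_cohort_per_band"`) yields ≈ 225,000; the published count
(> 160,000) lies between the two. The switch is exposed rather than silently
fixed; all headline cost-per-DALY results here use the default.

## Parameters without published values

Four inputs the DALY total depends on have no published value. They are
package defaults, configurable, and echoed in every result's
`assumed_parameters` metadata:

| parameter | default | units | rationale |
|---|---|---|---|
| remaining life expectancy `L` | 62.5 | years | approximate Ugandan remaining life expectancy in early childhood |
| anaemia YLD duration | 1.25 | years | the 9–24-month effect window |
| anaemia moderate/severe split | 0.9 / 0.1 | fractions | severe anaemia is a small minority of moderate-or-severe cases in survey data; gives weighted weight 0.9 × 0.052 + 0.1 × 0.149 = 0.0617 |
| developmental-disability weight | 0.011 | — | GBD weight for borderline intellectual disability |

Because these are assumptions, the published total of 242,292 DALYs averted
per year is treated as a ±5 % plausibility band, not an exact target; the
default configuration lands at ≈ 245,400 (+1.3 %). Likewise the published
discounted $413/DALY is not exactly reproducible; the model asserts the
direction (discounting raises cost per DALY, here to ≈ $500) rather than the
value.

## Discounting

With rate $r$, a burden of duration $d$ starting in year $t$ contributes
$(1+r)^{-(t - t_0)} \cdot \tfrac{1}{r}\left(1 - e^{-r d}\right)$ discounted
years per case-year of weight 1 — an annual stream factor to the reference
year $t_0 = 2021$ times continuous within-case discounting, with no age
weighting. The $r \to 0^+$ limit recovers the undiscounted product to
machine precision (implemented with `expm1`). All of a year's effects share
that year's single stream factor; the model has annual granularity and does
not lag onset within a year. Start-up costs sit in the start-up year of the
discounted cost stream.

## The synthetic fixture

The district table and the base-district activity costs behind the published
aggregates are not public, so the `fixture_spec()` / `simulate_fixture()`
generator produces seeded stand-ins with the structure the model assumes:

- **Districts** (default n = 120, seed = 7): areas log-normal with median at
  the 820 km² base area and log-SD 0.56 (central 95 % ≈ 0.3×–3× the base, a
  plausible spread for Ugandan districts); eligible children drawn
  proportional to area with multiplicative noise and rescaled so the
  national sum is exactly 1,118,340 and the five mortality-targeting
  sub-regions (West Nile, Busoga, Tooro, Ankole, Karamoja) hold exactly
  396,808 children — both study conditions, not free parameters; VHT counts
  proportional to children with 15 % log-normal noise around 1,400 in the
  base district; sub-regions cycled through the fifteen survey sub-region
  names.
- **Cohorts**: constant at the national figure in each intervention year.
  The published "average of 1,118,340 children per year" is the only
  projection information available, and a constant projection makes the
  yearly district table self-consistent; `cohort_projection()` accepts any
  year-varying series.
- **Activity costs**: a fixed template of activity × input × phase × index
  items (transport items spatial, per-child items child-population-indexed,
  VHT-facing items VHT-indexed; start-up concentrated in social and
  behaviour change communication and capacity building) is scaled in closed
  form — no iterative fitting — so that, combined with the analytic product,
  supply-chain and incentive costs, capacity building is 15.3 % and
  logistics 6 % of the average annual total and non-product programmatic
  cost is $19.00 per child. The calibration anchor is total per-child cost
  `T = product + supply chain + 19 = $52.14`.

One bookkeeping choice matters for the cost composition: the published
18.7 % "shipping and customs" activity is modelled as international shipping
plus customs only ($1.32/kg, 18.5 % of the total here); domestic transport,
storage and handling ($0.17/kg) is booked under logistics. Folding domestic
transport into the chain would push its share to 20.8 %, outside the
published composition.

What the fixture does **not** emulate: real district geography or any true
2018 costing line item; correlation between sub-region and mortality or
poverty; within-district heterogeneity; year-on-year cohort growth. Passing
tests therefore demonstrate that the model reproduces the published national
aggregates under a structurally faithful input set — not that any
district-level number is historically accurate.

## Numerical and degenerate-input choices

- Ratios with zero effect are reported as absent (`NA`), never infinite;
  zero cost with zero effect reports 0.
- Integer rescaling in the generator uses largest-remainder rounding so
  group sums are exact.
- `burden_years` rejects non-positive durations; zero-case entries
  short-circuit to zero burden.
- Configuration files fail fast on unknown keys, and every violation of a
  parameter invariant is reported (by field and rule) rather than only the
  first.
- Scenario overrides are purely functional: the base configuration is never
  mutated, the result is re-validated, and unknown override paths are
  rejected by name.

## Problem sizes

The default fixture (120 districts, 14 cost items, 10 + 1 years) runs the
full pipeline in well under a second; the complete test suite, including
property loops and byte-level determinism checks, runs in a few seconds.

## Known limitations

- Urban delivery platforms, facility-based distribution, local production
  and caregiver-side illness costs are out of scope.
- The customs rate is the published $1.01/kg taken directly; the tax
  arithmetic behind it is not reconstructible from the source material.
- Mortality uses a single 12-month-window risk (1.22 %) rather than
  age-specific rates, which are not published.
- Published stunting (55,858) and anaemia (> 160,000) counts deviate a few
  percent from the simple closed forms (56,364 and ≈ 145,000 here); the
  year-specific projected populations behind them are unavailable.
- Longitudinal and cross-sectional wasting are alternative measures of the
  same burden and are reported side by side, never summed.
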