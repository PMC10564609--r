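#' Cost-effectiveness ratio
#'
#' @param total_cost Total cost (2020 USD) over the period the effect covers.
#' @param effect Effect total (cases, deaths or DALYs averted).
#' @return `total_cost / effect`; `NA` (absent, not infinite) when the effect
#'   is zero and the cost is positive; 0 when the cost is 0.
#' @export
#' @examples
#' cer(58.7e6, 242292) # ~242
cer <- function(total_cost, effect) {
  if (total_cost < 0 || effect < 0) stop("cost and effect must be non-negative")
  if (total_cost == 0) return(0)
  if (effect == 0) return(NA_real_)
  total_cost / effect
}

#' A named scenario: parameter overrides on a model configuration
#'
#' @param name Scenario label.
#' @param overrides Named list mapping dotted parameter paths inside a
#'   `model_config` (e.g. `"costs.customs_usd_per_kg"`,
#'   `"outcomes.mortality.relative_reduction"`) to replacement values.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(name, overrides = list()) {
  structure(list(name = name, overrides = overrides), class = "scenario_spec")
}

#' Apply a scenario's overrides to a configuration
#'
#' Returns a new configuration with each override applied; the input is
#' untouched and the result is re-validated. Unknown override paths are an
#' error naming the offending path.
#'
#' @param config A `model_config`.
#' @param spec A [scenario_spec()].
#' @return A new validated `model_config` named after the scenario.
#' @export
apply_scenario <- function(config, spec) {
  out <- config
  for (path in names(spec$overrides)) {
    parts <- strsplit(path, ".", fixed = TRUE)[[1]]
    node <- out
    for (p in parts) {
      if (!is.list(node) || !p %in% names(node))
        stop(sprintf("unknown override path: %s", path), call. = FALSE)
      node <- node[[p]]
    }
    out[[parts]] <- spec$overrides[[path]]
  }
  out$scenario_name <- spec$name
  violations <- validate_config(out)
  if (length(violations) > 0)
    stop("scenario produces an invalid configuration:\n  ",
         paste(violations, collapse = "\n  "), call. = FALSE)
  out
}

#' The reported sensitivity scenarios
#'
#' Six single-parameter scenarios plus simultaneous best and worst cases:
#' mortality relative reduction 18 % instead of 27 %; elimination of customs
#' clearance; a 10 % product price decrease; a price increase to $0.09 per
#' sachet; lower ($0.29) and higher ($0.87) VHT incentives per delivery.
#' Best case combines customs elimination, the price decrease and the lower
#' incentive; worst case combines the 18 % mortality reduction, the $0.09
#' price and the higher incentive.
#'
#' @param config The base configuration the price overrides are derived from.
#' @return List of [scenario_spec()]s (base case not included).
#' @export
default_scenarios <- function(config = default_uganda_config()) {
  carton <- config$costs$price_per_carton_usd
  n_sachet <- config$costs$sachets_per_carton
  list(
    scenario_spec("mortality_rr_18",
      list("outcomes.mortality.relative_reduction" = 0.18)),
    scenario_spec("customs_eliminated",
      list("costs.customs_usd_per_kg" = 0)),
    scenario_spec("price_minus_10pct",
      list("costs.price_per_carton_usd" = carton * 0.9)),
    scenario_spec("price_0.09_per_sachet",
      list("costs.price_per_carton_usd" = 0.09 * n_sachet)),
    scenario_spec("incentive_0.29",
      list("costs.vht_incentive_usd_per_delivery" = 0.29)),
    scenario_spec("incentive_0.87",
      list("costs.vht_incentive_usd_per_delivery" = 0.87)),
    scenario_spec("best_case", list(
      "costs.customs_usd_per_kg" = 0,
      "costs.price_per_carton_usd" = carton * 0.9,
      "costs.vht_incentive_usd_per_delivery" = 0.29)),
    scenario_spec("worst_case", list(
      "outcomes.mortality.relative_reduction" = 0.18,
      "costs.price_per_carton_usd" = 0.09 * n_sachet,
      "costs.vht_incentive_usd_per_delivery" = 0.87))
  )
}

# Discounted sum of a yearly stream relative to the reference year.
discounted_sum <- function(years, values, r, ref) {
  if (r == 0) return(sum(values))
  sum(values * (1 + r)^-(years - ref))
}

#' Run the full cost-effectiveness model
#'
#' Orchestrates the cost ledger, the annual effect table, the DALY model and
#' the cost-effectiveness ratios, for both the undiscounted and the
#' configured discounted scenario. Ratios are computed on totals over the
#' full intervention horizon, not as means of annual ratios. Deterministic:
#' identical inputs give identical outputs.
#'
#' @param config A validated `model_config`.
#' @param districts District data frame.
#' @param items Activity-cost data frame.
#' @param cohorts A [cohort_projection()].
#' @param base Base district for extrapolation (default first row).
#' @param anaemia_person_base Passed to [annual_effect_table()].
#' @return A `cea_result`: scenario name, the cost ledger, average annual
#'   effects, DALY tables and cost-effectiveness ratios (`undiscounted` and
#'   `discounted` elements), plus the assumed unpublished parameters.
#' @export
run_model <- function(config, districts, items, cohorts,
                      base = districts[1, ],
                      anaemia_person_base = "band_occupancy") {
  violations <- validate_config(config)
  if (length(violations) > 0)
    stop("invalid configuration:\n  ", paste(violations, collapse = "\n  "))

  ledger <- build_cost_ledger(config, districts, items, cohorts, base = base)
  iy <- ledger$intervention_years
  cohorts_iy <- cohorts[cohorts$year %in% iy, , drop = FALSE]
  effects <- annual_effect_table(config, cohorts_iy,
                                 anaemia_person_base = anaemia_person_base)
  r <- config$discount$rate
  ref <- config$discount$reference_year

  daly0 <- dalys_averted(effects, config, r = 0)
  dalyr <- dalys_averted(effects, config, r = r)

  cost_by_year <- ledger$total_by_year
  total_cost0 <- sum(cost_by_year$cost_usd)
  total_costr <- discounted_sum(cost_by_year$year, cost_by_year$cost_usd, r, ref)

  outcome_totals <- function(discount_rate) {
    sapply(split(effects, effects$outcome), function(df) {
      discounted_sum(df$year, df$cases_averted, discount_rate, ref)
    })
  }
  eff0 <- outcome_totals(0)
  effr <- outcome_totals(r)

  ratio_block <- function(total_cost, eff_totals, daly_total) {
    per_case <- sapply(names(eff_totals), function(o)
      cer(total_cost, eff_totals[[o]]))
    list(
      total_cost = total_cost,
      dalys_averted = daly_total,
      cost_per_daly = cer(total_cost, daly_total),
      cost_per_death = cer(total_cost, eff_totals[["mortality"]]),
      cost_per_case = per_case
    )
  }

  eff_avg <- sapply(split(effects, effects$outcome),
                    function(df) mean(df$cases_averted))
  structure(
    list(
      scenario_name = config$scenario_name,
      discount_rate = r,
      ledger = ledger,
      cost_per_child = ledger$cost_per_child,
      average_annual_cost = ledger$average_annual_total,
      average_annual_effects = eff_avg,
      average_annual_dalys = mean(daly0$total_dalys_averted),
      effects = effects,
      dalys = list(undiscounted = daly0, discounted = dalyr),
      undiscounted = ratio_block(total_cost0, eff0,
                                 sum(daly0$total_dalys_averted)),
      discounted = ratio_block(total_costr, effr,
                               sum(dalyr$total_dalys_averted)),
      assumed_parameters = attr(daly0, "assumed_parameters")
    ),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result>", x$scenario_name, "\n")
  cat(sprintf("  average annual cost: $%.1f M; cost per child: $%.2f\n",
              x$average_annual_cost / 1e6, x$cost_per_child))
  cat(sprintf("  deaths averted/yr: %.0f; DALYs averted/yr: %.0f\n",
              x$average_annual_effects[["mortality"]],
              x$average_annual_dalys))
  cat(sprintf("  cost per DALY: $%.0f (undiscounted), $%.0f (discounted %.0f%%)\n",
              x$undiscounted$cost_per_daly, x$discounted$cost_per_daly,
              100 * x$discount_rate))
  cat(sprintf("  cost per death: $%.0f (undiscounted)\n",
              x$undiscounted$cost_per_death))
  invisible(x)
}

#' Run the model across a list of sensitivity scenarios
#'
#' @param config Base `model_config`.
#' @param scenarios List of [scenario_spec()]s (unique names).
#' @param districts,items,cohorts,base,anaemia_person_base As [run_model()].
#' @return List with `results` (named list of `cea_result`s, base case first,
#'   then scenarios in the order given) and `table` (one summary row per
#'   scenario).
#' @export
run_sensitivity <- function(config, scenarios, districts, items, cohorts,
                            base = districts[1, ],
                            anaemia_person_base = "band_occupancy") {
  if (length(scenarios) < 1) stop("at least one scenario is required")
  nm <- vapply(scenarios, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate scenario names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  configs <- c(list(config),
               lapply(scenarios, function(s) apply_scenario(config, s)))
  results <- lapply(configs, run_model, districts = districts, items = items,
                    cohorts = cohorts, base = base,
                    anaemia_person_base = anaemia_person_base)
  names(results) <- vapply(results, `[[`, character(1), "scenario_name")
  table <- do.call(rbind, lapply(results, function(res) {
    data.frame(
      scenario = res$scenario_name,
      cost_per_child = res$cost_per_child,
      average_annual_cost = res$average_annual_cost,
      deaths_averted_per_year = res$average_annual_effects[["mortality"]],
      dalys_averted_per_year = res$average_annual_dalys,
      cost_per_daly = res$undiscounted$cost_per_daly,
      cost_per_death = res$undiscounted$cost_per_death,
      cost_per_daly_discounted = res$discounted$cost_per_daly,
      cost_per_death_discounted = res$discounted$cost_per_death,
      stringsAsFactors = FALSE
    )
  }))
  rownames(table) <- NULL
  list(results = results, table = table)
}

#' Sub-regions used for mortality-based geographic targeting
#'
#' The five sub-regions with the worst under-five mortality in the 2016
#' Demographic and Health Survey.
#' @export
targeting_sub_regions <- function() {
  c("West Nile", "Busoga", "Tooro", "Ankole", "Karamoja")
}

#' Geographic targeting: restrict the programme to selected sub-regions
#'
#' Filters the district table to the selected sub-regions, scales the cohort
#' projection by the retained eligible-child share, and re-runs the full
#' model on the subset. Per-child product, supply-chain and incentive
#' components are unchanged by construction; programmatic costs re-scale with
#' the subset's extrapolation indices.
#'
#' @param config,districts,items,cohorts,base,anaemia_person_base As
#'   [run_model()]. `base` remains the original base district (it need not
#'   belong to the selection; it is the cost-extrapolation reference).
#' @param sub_regions Character vector of sub-regions to keep.
#' @return List: `districts` (the subset), `result` (a `cea_result` on the
#'   subset), `cohort_share` (retained share of eligible children) and
#'   `cost_ratio` (targeted / untargeted average annual cost).
#' @export
apply_targeting <- function(config, districts, items, cohorts,
                            sub_regions = targeting_sub_regions(),
                            base = districts[1, ],
                            anaemia_person_base = "band_occupancy") {
  if (length(sub_regions) == 0) stop("at least one sub-region must be selected")
  missing <- setdiff(sub_regions, unique(districts$sub_region))
  if (length(missing) > 0)
    stop("sub-region(s) not in the district table: ",
         paste(missing, collapse = ", "))
  subset <- districts[districts$sub_region %in% sub_regions, , drop = FALSE]
  share <- sum(subset$eligible_children) / sum(districts$eligible_children)
  cohorts_t <- cohort_projection(cohorts$year,
                                 cohorts$eligible_children * share)
  full <- run_model(config, districts, items, cohorts, base = base,
                    anaemia_person_base = anaemia_person_base)
  targeted <- run_model(config, subset, items, cohorts_t, base = base,
                        anaemia_person_base = anaemia_person_base)
  list(
    districts = subset,
    result = targeted,
    cohort_share = share,
    cost_ratio = targeted$average_annual_cost / full$average_annual_cost
  )
}
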