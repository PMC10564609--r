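#' Intervention design parameters
#'
#' Describes the supplementation programme: daily small-quantity lipid-based
#' nutrient supplements (SQ-LNS) given from `start_age_months` for
#' `duration_months`, delivered to households by Village Health Teams (VHTs)
#' `deliveries_per_year` times per year, over a multi-year horizon with a
#' start-up phase before the first intervention year.
#'
#' @param start_age_months Age (months) at which supplementation begins.
#' @param duration_months Months of daily supplementation per child.
#' @param sachets_per_day Sachets consumed per child per day.
#' @param sachet_mass_g Mass of one sachet in grams.
#' @param deliveries_per_year Household deliveries per year.
#' @param start_year First calendar year of the programme (the start-up year).
#' @param horizon_years Number of intervention (supplementation) years.
#' @param startup_years Number of start-up years preceding the intervention.
#'
#' @return A list of class `intervention_design`.
#' @export
intervention_design <- function(start_age_months = 6,
                                duration_months = 12,
                                sachets_per_day = 1,
                                sachet_mass_g = 20,
                                deliveries_per_year = 4,
                                start_year = 2021,
                                horizon_years = 10,
                                startup_years = 1) {
  structure(
    list(
      start_age_months = start_age_months,
      duration_months = duration_months,
      sachets_per_day = sachets_per_day,
      sachet_mass_g = sachet_mass_g,
      deliveries_per_year = deliveries_per_year,
      start_year = start_year,
      horizon_years = horizon_years,
      startup_years = startup_years
    ),
    class = "intervention_design"
  )
}

#' Outcome names recognised by the model
#' @export
outcome_names <- function() {
  c("mortality", "anaemia_mod_sev", "developmental_disability",
    "stunting", "wasting_cross_sectional", "wasting_longitudinal")
}

#' One health outcome's effectiveness parameters
#'
#' @param name Outcome name, one of [outcome_names()].
#' @param baseline Baseline prevalence/risk: a single fraction, or a data frame
#'   with columns `start_month`, `end_month`, `prevalence` for age-banded
#'   baselines (half-open bands `[start, end)` in months of age).
#' @param relative_reduction Fractional reduction attributable to SQ-LNS.
#' @param effect_window Length-2 numeric, `(start_month, end_month)` of age
#'   over which the effect applies.
#' @param counted_in_dalys Does the outcome contribute to the DALY total?
#'   Stunting and wasting do not (stunting carries no GBD disability weight
#'   and moderate wasting's weight is zero).
#' @param disability_weight GBD disability weight in `[0, 1]`, required when
#'   `counted_in_dalys` is `TRUE` (use `NA` for anaemia, whose weight is a
#'   moderate/severe-prevalence-weighted average computed at run time).
#' @param disability_duration_years Duration of disability in years, or the
#'   sentinel string `"remaining_life_expectancy"`.
#' @param correction_factors Optional numeric vector of cross-sectional to
#'   longitudinal prevalence correction factors (wasting only).
#'
#' @return A list of class `outcome_spec`.
#' @export
outcome_spec <- function(name, baseline, relative_reduction, effect_window,
                         counted_in_dalys = FALSE,
                         disability_weight = NULL,
                         disability_duration_years = NULL,
                         correction_factors = NULL) {
  structure(
    list(
      name = name,
      baseline = baseline,
      relative_reduction = relative_reduction,
      effect_window = as.numeric(effect_window),
      counted_in_dalys = counted_in_dalys,
      disability_weight = disability_weight,
      disability_duration_years = disability_duration_years,
      correction_factors = correction_factors
    ),
    class = "outcome_spec"
  )
}

#' Unit cost parameters (2020 US dollars)
#'
#' Product is priced per carton from the UNICEF Supply Catalog; the
#' international supply chain (shipping and handling, customs clearance,
#' domestic transport/storage/handling) is priced per kilogram of product;
#' VHT workers receive a performance-based incentive per household delivery.
#'
#' @param price_per_carton_usd Price of one carton, 2020 USD.
#' @param sachets_per_carton Sachets per carton.
#' @param intl_shipping_usd_per_kg International shipping and handling, USD/kg.
#' @param customs_usd_per_kg Customs clearance, USD/kg.
#' @param domestic_usd_per_kg Domestic transport, storage and handling, USD/kg.
#' @param vht_incentive_usd_per_delivery VHT incentive per delivery, USD.
#' @param deflator_table Named list mapping year to the implicit price
#'   deflator used to convert that year's costs to 2020 USD (applied only when
#'   ingesting non-2020 base costs).
#'
#' @return A list of class `cost_parameters`.
#' @export
cost_parameters <- function(price_per_carton_usd = 33.30,
                            sachets_per_carton = 546,
                            intl_shipping_usd_per_kg = 0.31,
                            customs_usd_per_kg = 1.01,
                            domestic_usd_per_kg = 0.17,
                            vht_incentive_usd_per_delivery = 0.44,
                            deflator_table = list()) {
  structure(
    list(
      price_per_carton_usd = price_per_carton_usd,
      sachets_per_carton = sachets_per_carton,
      intl_shipping_usd_per_kg = intl_shipping_usd_per_kg,
      customs_usd_per_kg = customs_usd_per_kg,
      domestic_usd_per_kg = domestic_usd_per_kg,
      vht_incentive_usd_per_delivery = vht_incentive_usd_per_delivery,
      deflator_table = deflator_table
    ),
    class = "cost_parameters"
  )
}

#' Discounting specification
#'
#' @param rate Annual discount rate (fraction); the two reported scenarios
#'   use 0 and 0.03.
#' @param reference_year Calendar year with discount factor 1.
#' @return A list of class `discount_spec`.
#' @export
discount_spec <- function(rate = 0.03, reference_year = 2021) {
  structure(list(rate = rate, reference_year = reference_year),
            class = "discount_spec")
}

#' Remaining life expectancy used for years of life lost
#'
#' @param remaining_life_expectancy_years Remaining life expectancy (years) at
#'   the modelled age at death or disability onset. No published value exists
#'   for this model; the default of 62.5 approximates Ugandan remaining life
#'   expectancy in early childhood and MUST be reviewed for other settings.
#' @return A list of class `life_table`.
#' @export
life_table <- function(remaining_life_expectancy_years = 62.5) {
  structure(
    list(remaining_life_expectancy_years = remaining_life_expectancy_years),
    class = "life_table"
  )
}

#' Assemble a full model configuration
#'
#' @param design An [intervention_design()].
#' @param outcomes Named list of [outcome_spec()]s, one per outcome name.
#' @param costs A [cost_parameters()].
#' @param discount A [discount_spec()].
#' @param life_table A [life_table()].
#' @param anaemia_severity_split Length-2 named numeric
#'   `c(moderate = , severe = )`: the split of moderate-or-severe anaemia
#'   cases between moderate and severe; must sum to 1. Used to form the
#'   prevalence-weighted anaemia disability weight.
#' @param scenario_name Label attached to results.
#' @return A list of class `model_config`.
#' @export
model_config <- function(design, outcomes, costs, discount, life_table,
                         anaemia_severity_split = c(moderate = 0.9, severe = 0.1),
                         scenario_name = "base") {
  structure(
    list(
      scenario_name = scenario_name,
      design = design,
      outcomes = outcomes,
      costs = costs,
      discount = discount,
      life_table = life_table,
      anaemia_severity_split = anaemia_severity_split
    ),
    class = "model_config"
  )
}

#' Baseline developmental-disability prevalence from under-5 prevalence and
#' predictive validity
#'
#' The modelled baseline is the under-5 developmental-disability prevalence
#' multiplied by the predictive validity of a lowest-decile early-childhood
#' language score for later language delay.
#'
#' @param prev_under5 Under-5 developmental-disability prevalence (fraction).
#' @param predictive_validity Predictive validity (fraction).
#' @return The product, a fraction.
#' @export
#' @examples
#' derived_dev_disability_baseline(0.10, 0.656) # 0.0656
derived_dev_disability_baseline <- function(prev_under5, predictive_validity) {
  stopifnot(is.numeric(prev_under5), is.numeric(predictive_validity))
  if (prev_under5 < 0 || prev_under5 > 1)
    stop("prev_under5 must be in [0, 1]")
  if (predictive_validity < 0 || predictive_validity > 1)
    stop("predictive_validity must be in [0, 1]")
  prev_under5 * predictive_validity
}

#' Default rural-Uganda parameterisation
#'
#' The base-case parameter set: 12 months of daily 20 g SQ-LNS from 6 months
#' of age, delivered quarterly by VHTs over 2021-2031 (1 start-up year + 10
#' intervention years), with meta-analysis relative reductions (mortality
#' 27 %, moderate/severe anaemia 28 %, language-domain developmental
#' disability 16 %, stunting 12 %, cross-sectional wasting 14 %, longitudinal
#' wasting 30 %) and Uganda survey baselines (mortality risk 1.22 % over the
#' supplementation window; anaemia 59/41/31 % at 6-9/9-18/18-24 months;
#' stunting 42 %; wasting 7.8 % cross-sectional with longitudinal correction
#' factors 2.6 and 6; developmental disability 10 % x 65.6 % = 6.6 %).
#'
#' Parameters with no published value (remaining life expectancy, anaemia
#' YLD duration and moderate/severe split, developmental-disability weight)
#' carry reviewed defaults; see the package vignette.
#'
#' @param discount_rate Discount rate for the discounted scenario.
#' @return A validated `model_config`.
#' @export
default_uganda_config <- function(discount_rate = 0.03) {
  anaemia_baseline <- data.frame(
    start_month = c(6, 9, 18),
    end_month   = c(9, 18, 24),
    prevalence  = c(0.59, 0.41, 0.31)
  )
  outcomes <- list(
    mortality = outcome_spec(
      name = "mortality",
      baseline = 0.0122,
      relative_reduction = 0.27,
      effect_window = c(6, 18),
      counted_in_dalys = TRUE,
      disability_weight = 1,
      disability_duration_years = "remaining_life_expectancy"
    ),
    anaemia_mod_sev = outcome_spec(
      name = "anaemia_mod_sev",
      baseline = anaemia_baseline,
      relative_reduction = 0.28,
      effect_window = c(9, 24),
      counted_in_dalys = TRUE,
      disability_weight = NA_real_, # weighted from the severity split at run time
      disability_duration_years = 1.25
    ),
    developmental_disability = outcome_spec(
      name = "developmental_disability",
      baseline = derived_dev_disability_baseline(0.10, 0.656),
      relative_reduction = 0.16,
      effect_window = c(18, 24),
      counted_in_dalys = TRUE,
      disability_weight = 0.011,
      disability_duration_years = "remaining_life_expectancy"
    ),
    stunting = outcome_spec(
      name = "stunting",
      baseline = 0.42,
      relative_reduction = 0.12,
      effect_window = c(6, 18)
    ),
    wasting_cross_sectional = outcome_spec(
      name = "wasting_cross_sectional",
      baseline = 0.078,
      relative_reduction = 0.14,
      effect_window = c(6, 18)
    ),
    wasting_longitudinal = outcome_spec(
      name = "wasting_longitudinal",
      baseline = 0.078,
      relative_reduction = 0.30,
      effect_window = c(6, 18),
      correction_factors = c(lower = 2.6, upper = 6)
    )
  )
  model_config(
    design = intervention_design(),
    outcomes = outcomes,
    costs = cost_parameters(),
    discount = discount_spec(rate = discount_rate),
    life_table = life_table(),
    anaemia_severity_split = c(moderate = 0.9, severe = 0.1),
    scenario_name = "base"
  )
}

## ---- validation -----------------------------------------------------------

frac_ok <- function(x) is.numeric(x) && all(x >= 0) && all(x <= 1)

validate_design <- function(d) {
  v <- character()
  pos <- c("start_age_months", "duration_months", "sachets_per_day",
           "sachet_mass_g", "deliveries_per_year", "horizon_years",
           "startup_years")
  for (f in pos) {
    if (!is.numeric(d[[f]]) || length(d[[f]]) != 1 || d[[f]] <= 0)
      v <- c(v, sprintf("design.%s: must be a positive number", f))
  }
  if (is.numeric(d$start_age_months) && is.numeric(d$duration_months) &&
      d$start_age_months + d$duration_months > 24)
    v <- c(v, "design.start_age_months + duration_months: must not exceed 24 months")
  v
}

validate_outcome <- function(o) {
  v <- character()
  if (!o$name %in% outcome_names())
    v <- c(v, sprintf("outcomes.%s.name: unknown outcome", o$name))
  bl <- o$baseline
  if (is.data.frame(bl)) {
    if (!frac_ok(bl$prevalence))
      v <- c(v, sprintf("outcomes.%s.baseline: banded prevalences must be in [0, 1]", o$name))
    if (any(bl$start_month >= bl$end_month))
      v <- c(v, sprintf("outcomes.%s.baseline: band start must precede end", o$name))
  } else if (!frac_ok(bl)) {
    v <- c(v, sprintf("outcomes.%s.baseline: must be in [0, 1]", o$name))
  }
  if (!frac_ok(o$relative_reduction))
    v <- c(v, sprintf("outcomes.%s.relative_reduction: must be in [0, 1]", o$name))
  w <- o$effect_window
  if (length(w) != 2 || w[1] >= w[2])
    v <- c(v, sprintf("outcomes.%s.effect_window: start must precede end", o$name))
  has_disability <- !is.null(o$disability_weight) &&
    !is.null(o$disability_duration_years)
  if (isTRUE(o$counted_in_dalys) && !has_disability)
    v <- c(v, sprintf(
      "outcomes.%s: disability_weight and disability_duration_years required when counted_in_dalys", o$name))
  if (!isTRUE(o$counted_in_dalys) && has_disability)
    v <- c(v, sprintf(
      "outcomes.%s: disability fields present but counted_in_dalys is FALSE", o$name))
  if (!is.null(o$disability_weight) && !is.na(o$disability_weight) &&
      !frac_ok(o$disability_weight))
    v <- c(v, sprintf("outcomes.%s.disability_weight: must be in [0, 1]", o$name))
  if (is.numeric(o$disability_duration_years) &&
      any(o$disability_duration_years <= 0))
    v <- c(v, sprintf("outcomes.%s.disability_duration_years: must be positive", o$name))
  v
}

validate_costs <- function(cst) {
  v <- character()
  rates <- c("price_per_carton_usd", "intl_shipping_usd_per_kg",
             "customs_usd_per_kg", "domestic_usd_per_kg",
             "vht_incentive_usd_per_delivery")
  for (f in rates) {
    if (!is.numeric(cst[[f]]) || cst[[f]] < 0)
      v <- c(v, sprintf("costs.%s: must be a non-negative number", f))
  }
  if (!is.numeric(cst$sachets_per_carton) || cst$sachets_per_carton <= 0)
    v <- c(v, "costs.sachets_per_carton: must be positive")
  v
}

#' Validate a model configuration
#'
#' Checks every structural invariant (positivity, fractions in `[0, 1]`,
#' window ordering, one outcome per name, severity split summing to 1) and
#' returns the violations rather than throwing, so a configuration can be
#' audited in full.
#'
#' @param config A `model_config`.
#' @return Character vector of violation messages; empty when valid.
#' @export
validate_config <- function(config) {
  v <- character()
  v <- c(v, validate_design(config$design))
  nm <- unname(vapply(config$outcomes, `[[`, character(1), "name"))
  if (anyDuplicated(nm) || !identical(sort(names(config$outcomes)), sort(nm)))
    v <- c(v, "outcomes: exactly one spec per outcome name, keyed by name")
  for (o in config$outcomes) v <- c(v, validate_outcome(o))
  v <- c(v, validate_costs(config$costs))
  if (!is.numeric(config$discount$rate) || config$discount$rate < 0)
    v <- c(v, "discount.rate: must be non-negative")
  L <- config$life_table$remaining_life_expectancy_years
  if (!is.numeric(L) || L <= 0)
    v <- c(v, "life_table.remaining_life_expectancy_years: must be positive")
  split <- config$anaemia_severity_split
  if (length(split) != 2 || !frac_ok(split) || abs(sum(split) - 1) > 1e-9)
    v <- c(v, "anaemia_severity_split: the two fractions must sum to 1")
  v
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>", x$scenario_name, "\n")
  cat(sprintf("  design: %d mo daily SQ-LNS from %d mo; %d g sachet; %d deliveries/yr\n",
              x$design$duration_months, x$design$start_age_months,
              x$design$sachet_mass_g, x$design$deliveries_per_year))
  cat(sprintf("  horizon: %d + %d years from %d; discount %.1f%%\n",
              x$design$startup_years, x$design$horizon_years,
              x$design$start_year, 100 * x$discount$rate))
  cat(sprintf("  outcomes: %s\n", paste(names(x$outcomes), collapse = ", ")))
  invisible(x)
}

## ---- config file IO -------------------------------------------------------

config_to_list <- function(config) {
  out <- unclass(config)
  out$design <- unclass(out$design)
  out$costs <- unclass(out$costs)
  out$discount <- unclass(out$discount)
  out$life_table <- unclass(out$life_table)
  out$anaemia_severity_split <- as.list(out$anaemia_severity_split)
  out$outcomes <- lapply(out$outcomes, function(o) {
    o <- unclass(o)
    if (is.data.frame(o$baseline)) {
      o$baseline <- lapply(seq_len(nrow(o$baseline)), function(i)
        as.list(o$baseline[i, , drop = FALSE]))
    }
    if (!is.null(o$correction_factors))
      o$correction_factors <- as.list(o$correction_factors)
    o[!vapply(o, is.null, logical(1))]
  })
  out
}

known_config_keys <- function() {
  list(
    top = c("scenario_name", "design", "outcomes", "costs", "discount",
            "life_table", "anaemia_severity_split"),
    design = names(intervention_design()),
    costs = names(cost_parameters()),
    discount = names(discount_spec()),
    life_table = names(life_table()),
    outcome = c("name", "baseline", "relative_reduction", "effect_window",
                "counted_in_dalys", "disability_weight",
                "disability_duration_years", "correction_factors"),
    split = c("moderate", "severe")
  )
}

check_keys <- function(found, allowed, where) {
  unknown <- setdiff(found, allowed)
  if (length(unknown) > 0)
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(unknown, collapse = ", ")), call. = FALSE)
}

#' Write a model configuration to a YAML config file
#'
#' @param config A `model_config`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(config, path) {
  txt <- yaml::as.yaml(config_to_list(config), precision = 15)
  writeLines(txt, path)
  invisible(path)
}

#' Read a model configuration from a YAML config file
#'
#' Unknown keys anywhere in the document are an error (fail-fast against
#' typos); numeric fields round-trip exactly for decimal inputs.
#'
#' @param path File path of a config written by [write_model_config()] or
#'   authored by hand to the same schema.
#' @return A `model_config`.
#' @export
read_model_config <- function(path) {
  raw <- yaml::read_yaml(path)
  keys <- known_config_keys()
  check_keys(names(raw), keys$top, "config")
  check_keys(names(raw$design), keys$design, "design")
  check_keys(names(raw$costs), keys$costs, "costs")
  check_keys(names(raw$discount), keys$discount, "discount")
  check_keys(names(raw$life_table), keys$life_table, "life_table")
  check_keys(names(raw$anaemia_severity_split), keys$split,
             "anaemia_severity_split")
  outcomes <- lapply(raw$outcomes, function(o) {
    check_keys(names(o), keys$outcome, sprintf("outcomes.%s", o$name))
    baseline <- o$baseline
    if (is.list(baseline)) {
      baseline <- do.call(rbind, lapply(baseline, as.data.frame))
    }
    cf <- o$correction_factors
    if (!is.null(cf)) cf <- unlist(cf)
    outcome_spec(
      name = o$name,
      baseline = baseline,
      relative_reduction = o$relative_reduction,
      effect_window = unlist(o$effect_window),
      counted_in_dalys = isTRUE(o$counted_in_dalys),
      disability_weight = o$disability_weight,
      disability_duration_years = o$disability_duration_years,
      correction_factors = cf
    )
  })
  names(outcomes) <- vapply(outcomes, `[[`, character(1), "name")
  model_config(
    design = do.call(intervention_design, raw$design),
    outcomes = outcomes,
    costs = do.call(cost_parameters, raw$costs),
    discount = do.call(discount_spec, raw$discount),
    life_table = do.call(life_table, raw$life_table),
    anaemia_severity_split = unlist(raw$anaemia_severity_split),
    scenario_name = raw$scenario_name
  )
}
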