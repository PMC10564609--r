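#' Specification of the synthetic rural-Uganda fixture
#'
#' The district-level inputs behind the published national aggregates (the
#' rural district table and the Namutumba base-district activity costs) are
#' not public. This module generates synthetic stand-ins with the structure
#' the model assumes, calibrated so the default fixture reproduces the
#' published national totals: district areas spread around the Namutumba-like
#' base area of 820 km2, eligible children summing exactly to the national
#' annual cohort, and base activity costs scaled in closed form so national
#' activity shares match the published cost composition and the non-product
#' programmatic cost per child hits its target.
#'
#' @param n_districts Number of rural districts.
#' @param seed Integer seed; generation is a pure function of this spec.
#' @param base_profile Namutumba-like base district: list with `name`,
#'   `area_km2`, `vht_count`, `sub_region` (eligible children are generated).
#' @param national_cohort_target National annual eligible-child count.
#' @param activity_share_targets Named fractions of the average annual total
#'   cost: `product`, `product_supply_chain` (international shipping +
#'   customs; diagnostic, not calibrated - it follows from the per-kg rates),
#'   `capacity_building`, `logistics`.
#' @param nonproduct_per_child_target Non-product programmatic cost per child
#'   (2020 USD), inclusive of VHT incentives.
#' @param targeted_share Share of national eligible children living in the
#'   five mortality-targeting sub-regions (study condition).
#' @param area_sdlog Log-scale SD of district areas; the default spans about
#'   0.3x-3x the base area over the central 95 %.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_districts = 120,
                         seed = 7,
                         base_profile = list(name = "Namutumba",
                                             area_km2 = 820,
                                             vht_count = 1400,
                                             sub_region = "Busoga"),
                         national_cohort_target = 1118340,
                         activity_share_targets = c(product = 0.425,
                                                    product_supply_chain = 0.187,
                                                    capacity_building = 0.153,
                                                    logistics = 0.06),
                         nonproduct_per_child_target = 19,
                         targeted_share = 396808 / 1118340,
                         area_sdlog = 0.56) {
  if (n_districts < 1) stop("n_districts must be at least 1")
  shares <- activity_share_targets
  if (any(shares < 0) || any(shares > 1) || sum(shares) > 1)
    stop("activity share targets must be fractions summing to at most 1")
  structure(
    list(n_districts = n_districts, seed = seed, base_profile = base_profile,
         national_cohort_target = national_cohort_target,
         activity_share_targets = shares,
         nonproduct_per_child_target = nonproduct_per_child_target,
         targeted_share = targeted_share, area_sdlog = area_sdlog),
    class = "fixture_spec"
  )
}

#' The fifteen survey sub-regions used for district labels
#' @export
uganda_sub_regions <- function() {
  c("Busoga", "West Nile", "Tooro", "Ankole", "Karamoja",
    "Acholi", "Lango", "Teso", "Bukedi", "Bugisu",
    "Bunyoro", "Kigezi", "Buganda North", "Buganda South", "Kampala")
}

# Round a positive vector so it sums exactly to `total` (largest-remainder).
round_to_total <- function(x, total) {
  if (length(x) == 1) return(round(total))
  f <- floor(x)
  rem <- x - f
  short <- round(total) - sum(f)
  if (short > 0) {
    bump <- order(rem, decreasing = TRUE)[seq_len(short)]
    f[bump] <- f[bump] + 1
  }
  f
}

#' Generate a synthetic rural-district table
#'
#' Areas are log-normal around the base area; eligible children are drawn
#' proportional to area with multiplicative noise and rescaled so that the
#' national sum equals the target exactly and the five targeting sub-regions
#' hold exactly `targeted_share` of children; VHT counts are proportional to
#' children with noise. Sub-regions are assigned cyclically. The base
#' district is row 1 with its profiled area and VHT count. Deterministic
#' given the seed.
#'
#' @param spec A [fixture_spec()].
#' @return District data frame (`name`, `area_km2`, `eligible_children`,
#'   `vht_count`, `sub_region`).
#' @export
gen_districts <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_districts
  bp <- spec$base_profile
  national <- spec$national_cohort_target

  area <- c(bp$area_km2,
            stats::rlnorm(n - 1, meanlog = log(bp$area_km2),
                          sdlog = spec$area_sdlog))
  kids_raw <- area * stats::rlnorm(n, meanlog = 0, sdlog = 0.35)
  sub_region <- uganda_sub_regions()[((seq_len(n) - 1) %% 15) + 1]

  in_target <- sub_region %in% targeting_sub_regions()
  if (n == 1) {
    kids <- round(national)
  } else if (all(in_target) || !any(in_target)) {
    kids <- round_to_total(kids_raw * national / sum(kids_raw), national)
  } else {
    t_total <- round(spec$targeted_share * national)
    kids <- numeric(n)
    kids[in_target] <- round_to_total(
      kids_raw[in_target] * t_total / sum(kids_raw[in_target]), t_total)
    kids[!in_target] <- round_to_total(
      kids_raw[!in_target] * (national - t_total) / sum(kids_raw[!in_target]),
      national - t_total)
  }

  vht_per_child <- bp$vht_count / kids[1]
  vht <- pmax(1, round(kids * vht_per_child *
                         stats::rlnorm(n, meanlog = 0, sdlog = 0.15)))
  vht[1] <- bp$vht_count

  data.frame(
    name = c(bp$name, sprintf("District_%03d", seq_len(n)[-1])),
    area_km2 = area,
    eligible_children = kids,
    vht_count = vht,
    sub_region = sub_region,
    stringsAsFactors = FALSE
  )
}

# Template of base-district activity items: relative weights by activity,
# input category, phase and index kind. Transport scales spatially, per-child
# materials/personnel with child population, VHT-facing items with VHT counts.
activity_template <- function() {
  tpl <- function(activity, input, phase, kind, w)
    data.frame(activity = activity, input_category = input, phase = phase,
               index_kind = kind, weight = w, stringsAsFactors = FALSE)
  rbind(
    tpl("capacity_building", "personnel", "recurring", "vht_pop", 1.0),
    tpl("capacity_building", "transport", "recurring", "spatial", 0.6),
    tpl("capacity_building", "materials", "startup", "vht_pop", 0.8),
    tpl("capacity_building", "personnel", "startup", "vht_pop", 0.5),
    tpl("logistics", "transport", "recurring", "spatial", 0.7),
    tpl("logistics", "personnel", "recurring", "child_pop", 0.3),
    tpl("sbcc", "personnel", "recurring", "child_pop", 0.8),
    tpl("sbcc", "materials", "startup", "child_pop", 0.6),
    tpl("sbcc", "transport", "recurring", "spatial", 0.2),
    tpl("monitoring_evaluation", "personnel", "recurring", "child_pop", 0.5),
    tpl("monitoring_evaluation", "transport", "recurring", "spatial", 0.2),
    tpl("overhead", "other", "recurring", "child_pop", 0.6),
    tpl("capital", "other", "startup", "none", 0.3),
    tpl("caregiver_opportunity", "in_kind", "recurring", "child_pop", 1.2)
  )
}

# National average annual cost of one base-cost dollar for each template row:
# sum of extrapolation indices over districts, start-up rows annualised.
template_national_factor <- function(tpl, districts, base, horizon_years) {
  vapply(seq_len(nrow(tpl)), function(i) {
    idx_sum <- sum(vapply(seq_len(nrow(districts)), function(d)
      extrapolation_index(districts[d, ], base, tpl$index_kind[i]),
      numeric(1)))
    if (tpl$phase[i] == "startup") idx_sum / horizon_years else idx_sum
  }, numeric(1))
}

#' Generate a calibrated base-district activity-cost table
#'
#' Scales a fixed template of activity items (activity x input category x
#' phase x index kind) by closed-form factors so that, after extrapolation to
#' all districts and combination with the analytic product, supply-chain and
#' incentive costs, the national cost composition matches the share targets
#' and the non-product programmatic cost per child hits its target. No
#' iterative fitting is involved.
#'
#' Calibration anchors: total per-child cost T = product + supply chain +
#' `nonproduct_per_child_target`; capacity-building items are scaled to
#' `share * T` per child, logistics items to `share * T` minus the analytic
#' domestic-transport component, and the remaining programmatic budget
#' (after VHT incentives) is spread over the sbcc / monitoring & evaluation /
#' overhead / capital / caregiver-opportunity template weights.
#'
#' @param spec A [fixture_spec()].
#' @param districts Output of [gen_districts()].
#' @param config Model configuration supplying unit costs and the design
#'   (defaults to [default_uganda_config()]).
#' @return Activity-cost data frame (`activity`, `input_category`, `phase`,
#'   `base_cost_usd`, `index_kind`); rows whose calibrated budget is zero are
#'   dropped.
#' @export
gen_base_activity_costs <- function(spec, districts,
                                    config = default_uganda_config()) {
  design <- config$design
  costs <- config$costs
  base <- districts[1, ]
  N <- sum(districts$eligible_children)

  p_pc <- product_cost_per_child(costs, design)
  s_pc <- supply_chain_cost_per_child(costs, design)
  dom_pc <- domestic_transport_cost_per_child(costs, design)
  i_pc <- incentive_cost_per_child(costs, design)

  shares <- spec$activity_share_targets
  T_pc <- p_pc + s_pc + spec$nonproduct_per_child_target

  available <- max(0, spec$nonproduct_per_child_target - i_pc)
  cap_pc <- unname(shares["capacity_building"]) * T_pc
  log_pc <- max(0, unname(shares["logistics"]) * T_pc - dom_pc)
  if (cap_pc + log_pc > available && cap_pc + log_pc > 0) {
    squeeze <- available / (cap_pc + log_pc)
    cap_pc <- cap_pc * squeeze
    log_pc <- log_pc * squeeze
    rest_pc <- 0
  } else {
    rest_pc <- available - cap_pc - log_pc
  }

  tpl <- activity_template()
  factor_per_dollar <- template_national_factor(tpl, districts, base,
                                                design$horizon_years)
  group <- ifelse(tpl$activity == "capacity_building", "capacity",
                  ifelse(tpl$activity == "logistics", "logistics", "rest"))
  targets_national <- c(capacity = cap_pc, logistics = log_pc,
                        rest = rest_pc) * N

  base_cost <- numeric(nrow(tpl))
  for (g in unique(group)) {
    in_g <- group == g
    template_total <- sum(tpl$weight[in_g] * factor_per_dollar[in_g])
    scale <- if (template_total > 0) targets_national[[g]] / template_total else 0
    base_cost[in_g] <- tpl$weight[in_g] * scale
  }

  out <- data.frame(
    activity = tpl$activity,
    input_category = tpl$input_category,
    phase = tpl$phase,
    base_cost_usd = base_cost,
    index_kind = tpl$index_kind,
    stringsAsFactors = FALSE
  )
  out[out$base_cost_usd > 0, , drop = FALSE]
}

#' Constant cohort projection at the national target
#'
#' @param spec A [fixture_spec()].
#' @param design An [intervention_design()].
#' @return A [cohort_projection()] with the national eligible-child count in
#'   every intervention year.
#' @export
gen_cohort_projection <- function(spec, design = intervention_design()) {
  years <- seq(design$start_year + design$startup_years,
               length.out = design$horizon_years)
  cohort_projection(years, rep(spec$national_cohort_target, length(years)))
}

#' Generate the complete synthetic fixture
#'
#' @param spec A [fixture_spec()].
#' @param config A `model_config` (defaults to [default_uganda_config()]).
#' @return List: `districts`, `items`, `cohorts`, `base` (first district
#'   row), `spec`.
#' @export
simulate_fixture <- function(spec = fixture_spec(),
                             config = default_uganda_config()) {
  districts <- gen_districts(spec)
  items <- gen_base_activity_costs(spec, districts, config)
  cohorts <- gen_cohort_projection(spec, config$design)
  list(districts = districts, items = items, cohorts = cohorts,
       base = districts[1, ], spec = spec)
}

#' Write a fixture's tables to a directory
#'
#' @param fixture Output of [simulate_fixture()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_districts(fixture$districts, file.path(dir, "districts.csv"))
  write_activity_costs(fixture$items, file.path(dir, "activity_costs.csv"))
  write_cohort_projection(fixture$cohorts, file.path(dir, "cohorts.csv"))
  invisible(dir)
}
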