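#' Activity and extrapolation-index vocabularies
#' @export
activity_names <- function() {
  c("sbcc", "capacity_building", "logistics", "monitoring_evaluation",
    "overhead", "capital", "caregiver_opportunity", "vht_incentives",
    "product", "product_supply_chain")
}

#' @rdname activity_names
#' @export
index_kinds <- function() {
  c("spatial", "child_pop", "vht_pop", "vht_child_ratio", "none")
}

#' Annual product mass per child
#'
#' @param design An [intervention_design()].
#' @return Kilograms of SQ-LNS per child-year
#'   (`365 * sachets_per_day * sachet_mass_g / 1000`).
#' @export
annual_mass_kg_per_child <- function(design) {
  365 * design$sachets_per_day * design$sachet_mass_g / 1000
}

#' Product cost per sachet
#'
#' @param costs A [cost_parameters()].
#' @return Carton price divided by sachets per carton (2020 USD).
#' @export
#' @examples
#' cost_per_sachet(cost_parameters()) # ~0.061
cost_per_sachet <- function(costs) {
  if (costs$sachets_per_carton <= 0) stop("sachets_per_carton must be positive")
  costs$price_per_carton_usd / costs$sachets_per_carton
}

#' Product cost per child-year
#' @param costs A [cost_parameters()].
#' @param design An [intervention_design()].
#' @return `cost_per_sachet * sachets_per_day * 365`, 2020 USD.
#' @export
product_cost_per_child <- function(costs, design) {
  cost_per_sachet(costs) * design$sachets_per_day * 365
}

#' Supply-chain cost per child-year
#'
#' International shipping and handling, customs clearance and domestic
#' transport/storage/handling, each priced per kilogram of product.
#'
#' @inheritParams product_cost_per_child
#' @return 2020 USD per child-year.
#' @export
supply_chain_cost_per_child <- function(costs, design) {
  (costs$intl_shipping_usd_per_kg + costs$customs_usd_per_kg +
     costs$domestic_usd_per_kg) * annual_mass_kg_per_child(design)
}

#' @rdname supply_chain_cost_per_child
#' @details `shipping_customs_cost_per_child()` is the international portion
#'   (shipping + customs) only; `domestic_transport_cost_per_child()` is the
#'   in-country portion, booked under logistics in the activity ledger.
#' @export
shipping_customs_cost_per_child <- function(costs, design) {
  (costs$intl_shipping_usd_per_kg + costs$customs_usd_per_kg) *
    annual_mass_kg_per_child(design)
}

#' @rdname supply_chain_cost_per_child
#' @export
domestic_transport_cost_per_child <- function(costs, design) {
  costs$domestic_usd_per_kg * annual_mass_kg_per_child(design)
}

#' VHT incentive cost per child-year
#' @inheritParams product_cost_per_child
#' @return `vht_incentive_usd_per_delivery * deliveries_per_year`, 2020 USD.
#' @export
incentive_cost_per_child <- function(costs, design) {
  costs$vht_incentive_usd_per_delivery * design$deliveries_per_year
}

#' Extrapolation index of a district relative to the base district
#'
#' Base-district activity costs are extrapolated to other rural districts by
#' a ratio chosen to match what drives each cost: district area (transport),
#' eligible-child population (per-child materials and personnel), VHT
#' population (per-worker costs), or the VHT-to-child ratio.
#'
#' @param district,base Lists or one-row data frames with fields `area_km2`,
#'   `eligible_children`, `vht_count`.
#' @param kind One of [index_kinds()].
#' @return Dimensionless ratio; 1 for `kind = "none"`.
#' @export
#' @examples
#' extrapolation_index(list(area_km2 = 1585), list(area_km2 = 820), "spatial") # 1.93
extrapolation_index <- function(district, base, kind) {
  kind <- match.arg(kind, index_kinds())
  get2 <- function(x, f) as.numeric(x[[f]])
  chk <- function(x) {
    if (!is.finite(x) || x <= 0) stop("base district values must be positive")
    x
  }
  switch(kind,
    spatial = get2(district, "area_km2") / chk(get2(base, "area_km2")),
    child_pop = get2(district, "eligible_children") /
      chk(get2(base, "eligible_children")),
    vht_pop = get2(district, "vht_count") / chk(get2(base, "vht_count")),
    vht_child_ratio = {
      r_d <- get2(district, "vht_count") / get2(district, "eligible_children")
      r_b <- chk(get2(base, "vht_count")) / chk(get2(base, "eligible_children"))
      r_d / r_b
    },
    none = 1
  )
}

#' Read a district table from delimited text
#'
#' @param path CSV with columns `name`, `area_km2`, `eligible_children`,
#'   `vht_count`, `sub_region`.
#' @return A data frame.
#' @export
read_districts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("name", "area_km2", "eligible_children", "vht_count", "sub_region")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0)
    stop("district table missing column(s): ", paste(missing, collapse = ", "))
  if (any(df$area_km2 <= 0) || any(df$eligible_children <= 0) ||
      any(df$vht_count <= 0))
    stop("district areas and counts must be positive")
  df
}

#' @rdname read_districts
#' @param districts District data frame.
#' @export
write_districts <- function(districts, path) {
  utils::write.csv(districts, path, row.names = FALSE)
  invisible(path)
}

#' Read an activity-cost table from delimited text
#'
#' @param path CSV with columns `activity`, `input_category`, `phase`,
#'   `base_cost_usd`, `index_kind` (base-district costs, 2020 USD/year).
#' @return A data frame.
#' @export
read_activity_costs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("activity", "input_category", "phase", "base_cost_usd", "index_kind")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0)
    stop("activity-cost table missing column(s): ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(df$index_kind), index_kinds())
  if (length(bad) > 0)
    stop("unknown index_kind: ", paste(bad, collapse = ", "))
  if (any(df$base_cost_usd < 0)) stop("base costs must be non-negative")
  df
}

#' @rdname read_activity_costs
#' @param items Activity-cost data frame.
#' @export
write_activity_costs <- function(items, path) {
  utils::write.csv(items, path, row.names = FALSE)
  invisible(path)
}

#' Extrapolate base-district activity costs to all districts
#'
#' Each item's cost in a district is its base-district cost times the item's
#' extrapolation index for that district.
#'
#' @param items Activity-cost data frame (see [read_activity_costs()]).
#' @param districts District data frame.
#' @param base Base district (one row of `districts` or a compatible list).
#' @return Data frame with one row per item x district: `district`,
#'   `activity`, `input_category`, `phase`, `index_kind`, `cost_usd`.
#' @export
scale_activity_costs <- function(items, districts, base) {
  base_name <- if (is.data.frame(base)) base$name[[1]] else base$name
  if (!base_name %in% districts$name)
    stop("base district must be present in the district table")
  scale_activity_costs_impl(items, districts, base)
}

# As scale_activity_costs but the base may be an external reference profile
# (used when re-running the model on a district subset under targeting).
scale_activity_costs_impl <- function(items, districts, base) {
  bad <- setdiff(unique(items$index_kind), index_kinds())
  if (length(bad) > 0)
    stop("unknown index_kind: ", paste(bad, collapse = ", "))
  if (nrow(items) == 0) {
    return(data.frame(district = character(), activity = character(),
                      input_category = character(), phase = character(),
                      index_kind = character(), cost_usd = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- vector("list", nrow(districts))
  for (d in seq_len(nrow(districts))) {
    dist <- districts[d, ]
    idx <- vapply(items$index_kind, function(k)
      extrapolation_index(dist, base, k), numeric(1), USE.NAMES = FALSE)
    out[[d]] <- data.frame(
      district = dist$name,
      activity = items$activity,
      input_category = items$input_category,
      phase = items$phase,
      index_kind = items$index_kind,
      cost_usd = items$base_cost_usd * idx,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Build the full programme cost ledger
#'
#' Assembles year x district x activity costs over the programme horizon:
#' per-child analytic components (product, international shipping + customs,
#' domestic transport under logistics, VHT incentives) scale with each year's
#' cohort apportioned to districts by eligible-child share; activity-based
#' items recur each intervention year at their extrapolated district costs;
#' start-up-phase items occur once, in the start-up year(s), and are
#' annualised (divided evenly across the intervention horizon) in all
#' "average annual" figures.
#'
#' @param config A validated `model_config`.
#' @param districts District data frame.
#' @param items Activity-cost data frame.
#' @param cohorts A [cohort_projection()] covering every intervention year.
#' @param base Base district for extrapolation (default: first row of
#'   `districts`).
#' @return A `cost_ledger`: list with elements `costs` (tidy data frame
#'   `year`, `district`, `activity`, `cost_usd`), `total_by_year`,
#'   `average_annual_total`, `average_annual_cohort`, `cost_per_child`,
#'   `activity_totals` (average annual, start-up annualised),
#'   `activity_shares`, and `per_child_components`.
#' @export
build_cost_ledger <- function(config, districts, items, cohorts,
                              base = districts[1, ]) {
  if (nrow(districts) == 0) stop("district list must not be empty")
  design <- config$design
  costs <- config$costs

  startup_years <- seq(design$start_year, length.out = design$startup_years)
  intervention_years <- seq(design$start_year + design$startup_years,
                            length.out = design$horizon_years)
  missing_years <- setdiff(intervention_years, cohorts$year)
  if (length(missing_years) > 0)
    stop("cohort projection missing intervention year(s): ",
         paste(missing_years, collapse = ", "))

  p_pc <- product_cost_per_child(costs, design)
  sc_pc <- shipping_customs_cost_per_child(costs, design)
  dom_pc <- domestic_transport_cost_per_child(costs, design)
  inc_pc <- incentive_cost_per_child(costs, design)

  child_share <- districts$eligible_children / sum(districts$eligible_children)
  scaled <- scale_activity_costs_impl(items, districts, base)
  recurring <- scaled[scaled$phase == "recurring", , drop = FALSE]
  startup <- scaled[scaled$phase == "startup", , drop = FALSE]

  agg <- function(df) {
    if (nrow(df) == 0)
      return(df[, c("district", "activity", "cost_usd")][0, ])
    stats::aggregate(cost_usd ~ district + activity, data = df, FUN = sum)
  }
  recurring_da <- agg(recurring)
  startup_da <- agg(startup)

  rows <- list()
  for (y in startup_years) {
    if (nrow(startup_da) > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        year = y, district = startup_da$district,
        activity = startup_da$activity,
        cost_usd = startup_da$cost_usd / design$startup_years,
        stringsAsFactors = FALSE
      )
    }
  }
  for (y in intervention_years) {
    cohort_y <- cohorts$eligible_children[match(y, cohorts$year)]
    kids <- cohort_y * child_share
    analytic <- data.frame(
      year = y,
      district = rep(districts$name, times = 4),
      activity = rep(c("product", "product_supply_chain", "logistics",
                       "vht_incentives"), each = nrow(districts)),
      cost_usd = c(p_pc * kids, sc_pc * kids, dom_pc * kids, inc_pc * kids),
      stringsAsFactors = FALSE
    )
    rows[[length(rows) + 1]] <- analytic
    if (nrow(recurring_da) > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        year = y, district = recurring_da$district,
        activity = recurring_da$activity, cost_usd = recurring_da$cost_usd,
        stringsAsFactors = FALSE
      )
    }
  }
  ledger <- do.call(rbind, rows)
  ledger <- stats::aggregate(cost_usd ~ year + district + activity,
                             data = ledger, FUN = sum)
  ledger <- ledger[order(ledger$year, ledger$district, ledger$activity), ]
  rownames(ledger) <- NULL

  total_by_year <- stats::aggregate(cost_usd ~ year, data = ledger, FUN = sum)
  grand_total <- sum(ledger$cost_usd)
  average_annual_total <- grand_total / design$horizon_years
  avg_cohort <- mean(cohorts$eligible_children[cohorts$year %in% intervention_years])
  activity_totals <- stats::aggregate(cost_usd ~ activity, data = ledger,
                                      FUN = sum)
  activity_totals$cost_usd <- activity_totals$cost_usd / design$horizon_years
  shares <- stats::setNames(activity_totals$cost_usd / average_annual_total,
                            activity_totals$activity)

  per_child <- c(
    product = p_pc,
    supply_chain = sc_pc + dom_pc,
    shipping_customs = sc_pc,
    domestic_transport = dom_pc,
    vht_incentives = inc_pc,
    total = average_annual_total / avg_cohort
  )
  per_child <- c(per_child,
                 nonproduct_programmatic = unname(
                   per_child["total"] - per_child["product"] -
                     per_child["supply_chain"]))

  structure(
    list(
      costs = ledger,
      total_by_year = total_by_year,
      average_annual_total = average_annual_total,
      average_annual_cohort = avg_cohort,
      cost_per_child = unname(per_child["total"]),
      activity_totals = activity_totals,
      activity_shares = shares,
      per_child_components = per_child,
      intervention_years = intervention_years,
      startup_years_seq = startup_years
    ),
    class = "cost_ledger"
  )
}

#' @export
print.cost_ledger <- function(x, ...) {
  cat("<cost_ledger>\n")
  cat(sprintf("  average annual total: $%.1f M (2020 USD)\n",
              x$average_annual_total / 1e6))
  cat(sprintf("  average annual cohort: %.0f children\n",
              x$average_annual_cohort))
  cat(sprintf("  cost per child: $%.2f\n", x$cost_per_child))
  invisible(x)
}

#' Export a cost ledger as tidy delimited text
#'
#' @param ledger A `cost_ledger`.
#' @param path Output CSV path for the year/district/activity table.
#' @return `path`, invisibly.
#' @export
write_cost_ledger <- function(ledger, path) {
  utils::write.csv(ledger$costs, path, row.names = FALSE)
  invisible(path)
}
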