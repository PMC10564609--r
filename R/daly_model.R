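#' Prevalence-weighted anaemia disability weight
#'
#' The moderate-or-severe anaemia disability weight is the weighted average
#' of the GBD weights for moderate (0.052) and severe (0.149) anaemia,
#' weighted by the split of cases between the two severities.
#'
#' @param split Length-2 numeric `c(moderate = , severe = )` summing to 1.
#' @param weight_moderate,weight_severe GBD disability weights.
#' @return Dimensionless weight in `[0, 1]`.
#' @export
#' @examples
#' weighted_anaemia_weight(c(moderate = 0.9, severe = 0.1)) # 0.0617
weighted_anaemia_weight <- function(split, weight_moderate = 0.052,
                                    weight_severe = 0.149) {
  if (length(split) != 2 || any(split < 0) || abs(sum(split) - 1) > 1e-9)
    stop("split must be two non-negative fractions summing to 1")
  mod <- if (!is.null(names(split))) split[["moderate"]] else split[[1]]
  sev <- if (!is.null(names(split))) split[["severe"]] else split[[2]]
  weight_moderate * mod + weight_severe * sev
}

#' Disability (or life-lost) years for a block of cases
#'
#' Undiscounted burden is cases x duration x disability weight. With a
#' positive discount rate `r` the within-case duration is discounted
#' continuously, giving `cases x weight x (1/r) (1 - exp(-r * duration))`
#' (no age weighting). Years of life lost are the special case weight = 1 and
#' duration = remaining life expectancy.
#'
#' @param cases Number of cases (deaths for YLL).
#' @param duration Duration in years (> 0).
#' @param weight Disability weight in `[0, 1]` (1 for death).
#' @param r Annual discount rate (>= 0).
#' @return Years of healthy life lost.
#' @export
#' @examples
#' burden_years(100, 2, 0.5, 0)        # 100
#' burden_years(1, 1e9, 1, 0.03)       # -> 1/0.03
burden_years <- function(cases, duration, weight, r = 0) {
  if (cases < 0) stop("cases must be non-negative")
  if (duration <= 0) stop("duration must be positive")
  if (weight < 0 || weight > 1) stop("weight must be in [0, 1]")
  if (r < 0) stop("discount rate must be non-negative")
  if (r == 0) {
    cases * duration * weight
  } else {
    # -expm1 keeps full precision as r*duration -> 0
    cases * weight * (-expm1(-r * duration)) / r
  }
}

# Resolve an outcome's disability duration (years), honouring the
# remaining-life-expectancy sentinel.
resolve_duration <- function(spec, config) {
  d <- spec$disability_duration_years
  if (identical(d, "remaining_life_expectancy"))
    config$life_table$remaining_life_expectancy_years
  else as.numeric(d)
}

#' DALYs averted per year from an annual effect table
#'
#' DALYs averted are years of life lost (YLL, from deaths averted at the
#' configured remaining life expectancy) plus years lived with disability
#' (YLD) averted for moderate/severe anaemia and developmental disability.
#' Stunting and wasting contribute zero (no GBD disability weight). With a
#' positive rate each year's burden is further discounted to the reference
#' year by `(1 + r)^-(year - reference_year)`; within-case durations are
#' discounted continuously by [burden_years()].
#'
#' @param effects Output of [annual_effect_table()].
#' @param config A validated `model_config`.
#' @param r Annual discount rate; defaults to 0 (undiscounted).
#' @return Data frame of class `daly_result`: `year`, `yll_averted`,
#'   `yld_anaemia`, `yld_developmental_disability`, `total_dalys_averted`,
#'   `discount_rate`; metadata attribute `assumed_parameters` records the
#'   unpublished inputs (remaining life expectancy, durations, anaemia
#'   severity split and weights) the totals depend on.
#' @export
dalys_averted <- function(effects, config, r = 0) {
  L <- config$life_table$remaining_life_expectancy_years
  w_anaemia <- weighted_anaemia_weight(config$anaemia_severity_split)
  dur_anaemia <- resolve_duration(config$outcomes$anaemia_mod_sev, config)
  dd <- config$outcomes$developmental_disability
  dur_dd <- resolve_duration(dd, config)
  ref <- config$discount$reference_year

  years <- sort(unique(effects$year))
  get_cases <- function(y, outcome) {
    i <- effects$year == y & effects$outcome == outcome
    if (!any(i)) 0 else sum(effects$cases_averted[i])
  }
  out <- do.call(rbind, lapply(years, function(y) {
    stream <- if (r > 0) (1 + r)^-(y - ref) else 1
    yll <- burden_years(get_cases(y, "mortality"), L, 1, r) * stream
    yld_an <- burden_years2(get_cases(y, "anaemia_mod_sev"), dur_anaemia,
                            w_anaemia, r) * stream
    yld_dd <- burden_years2(get_cases(y, "developmental_disability"), dur_dd,
                            dd$disability_weight, r) * stream
    data.frame(year = y, yll_averted = yll, yld_anaemia = yld_an,
               yld_developmental_disability = yld_dd,
               total_dalys_averted = yll + yld_an + yld_dd,
               discount_rate = r)
  }))
  rownames(out) <- NULL
  attr(out, "assumed_parameters") <- list(
    remaining_life_expectancy_years = L,
    anaemia_duration_years = dur_anaemia,
    anaemia_severity_split = config$anaemia_severity_split,
    anaemia_disability_weight = w_anaemia,
    developmental_disability_weight = dd$disability_weight,
    developmental_disability_duration_years = dur_dd
  )
  class(out) <- c("daly_result", "data.frame")
  out
}

# burden_years that tolerates zero cases without tripping duration checks
burden_years2 <- function(cases, duration, weight, r) {
  if (cases == 0) return(0)
  burden_years(cases, duration, weight, r)
}

#' Export a DALY table as tidy delimited text
#' @param dalys Output of [dalys_averted()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_daly_table <- function(dalys, path) {
  long <- do.call(rbind, lapply(seq_len(nrow(dalys)), function(i) {
    data.frame(
      year = dalys$year[i],
      component = c("yll_mortality", "yld_anaemia_mod_sev",
                    "yld_developmental_disability"),
      years_averted = c(dalys$yll_averted[i], dalys$yld_anaemia[i],
                        dalys$yld_developmental_disability[i]),
      discount_rate = dalys$discount_rate[i]
    )
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
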