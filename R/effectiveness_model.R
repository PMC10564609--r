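#' Cases averted by the intervention
#'
#' The core effectiveness identity: cases (or deaths) averted equal the
#' baseline prevalence (or risk) of the adverse outcome, times the relative
#' reduction attributable to SQ-LNS, times the relevant population.
#'
#' @param baseline Baseline prevalence/risk, fraction in `[0, 1]`.
#' @param relative_reduction Relative reduction, fraction in `[0, 1]`.
#' @param population Relevant population size (persons).
#' @return Cases averted (count, not rounded).
#' @export
#' @examples
#' averted(0.468, 0.30, 1118340) # ~157015
averted <- function(baseline, relative_reduction, population) {
  if (baseline < 0 || baseline > 1) stop("baseline must be in [0, 1]")
  if (relative_reduction < 0 || relative_reduction > 1)
    stop("relative_reduction must be in [0, 1]")
  if (population < 0) stop("population must be non-negative")
  baseline * relative_reduction * population
}

#' Longitudinal from cross-sectional wasting prevalence
#'
#' Point-in-time (cross-sectional) wasting prevalence understates the
#' cumulative burden of wasting episodes; a correction factor converts it to
#' a longitudinal (cumulative-episode) prevalence.
#'
#' @param cross_sectional Cross-sectional prevalence, fraction.
#' @param correction_factor Multiplier (2.6 and 6 are the bounding values
#'   used here).
#' @return Longitudinal prevalence, fraction; the product must not exceed 1.
#' @export
#' @examples
#' longitudinal_prevalence(0.078, 2.6) # 0.2028
longitudinal_prevalence <- function(cross_sectional, correction_factor) {
  if (cross_sectional < 0 || cross_sectional > 1)
    stop("cross_sectional must be in [0, 1]")
  if (correction_factor < 0) stop("correction_factor must be non-negative")
  p <- cross_sectional * correction_factor
  if (p > 1) stop("longitudinal prevalence exceeds 1; correction factor too large")
  p
}

#' Annual deaths averted
#'
#' @param config A validated `model_config`.
#' @param cohort Annual eligible cohort (children supplemented that year).
#' @return Deaths averted per year: mortality risk over the supplementation
#'   window x relative reduction x cohort.
#' @export
deaths_averted <- function(config, cohort) {
  m <- config$outcomes$mortality
  averted(m$baseline, m$relative_reduction, cohort)
}

# Population base for a banded outcome, restricted to the effect window.
band_populations <- function(annual_cohort, bands, window, design,
                             person_base = c("band_occupancy",
                                             "full_cohort_per_band")) {
  person_base <- match.arg(person_base)
  lo <- pmax(bands$start_month, window[1])
  hi <- pmin(bands$end_month, window[2])
  keep <- lo < hi
  bands <- bands[keep, , drop = FALSE]
  lo <- lo[keep]; hi <- hi[keep]
  pop <- if (person_base == "band_occupancy") {
    vapply(seq_along(lo), function(i)
      band_person_count(annual_cohort, c(lo[i], hi[i]), design), numeric(1))
  } else {
    rep(annual_cohort, length(lo))
  }
  data.frame(start_month = lo, end_month = hi,
             prevalence = bands$prevalence, population = pop)
}

#' Annual effect table: cases and deaths averted per outcome and year
#'
#' Mortality, stunting and both wasting measures apply over the full
#' supplementation window (6-18 months), so their population base is the
#' annual cohort. Moderate/severe anaemia applies from 9 to 24 months using
#' the age-banded baseline prevalences; developmental disability applies in
#' the 18-24-month band. Longitudinal wasting is reported as a (lower, upper)
#' pair of rows (`wasting_longitudinal_lower` / `_upper`) from the two
#' correction factors; it is never summed with the cross-sectional estimate.
#'
#' @param config A validated `model_config`.
#' @param cohorts A [cohort_projection()] (intervention years).
#' @param anaemia_person_base `"band_occupancy"` (steady-state band residents;
#'   the default) or `"full_cohort_per_band"` (the full annual cohort exposed
#'   in every band). The published anaemia case count lies between the two
#'   conventions; see the vignette.
#' @return Data frame: `year`, `outcome`, `population_base`, `cases_averted`.
#' @export
annual_effect_table <- function(config, cohorts,
                                anaemia_person_base = c("band_occupancy",
                                                        "full_cohort_per_band")) {
  anaemia_person_base <- match.arg(anaemia_person_base)
  design <- config$design
  rows <- list()
  add <- function(year, outcome, pop, cases) {
    rows[[length(rows) + 1]] <<- data.frame(
      year = year, outcome = outcome, population_base = pop,
      cases_averted = cases, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(cohorts))) {
    y <- cohorts$year[i]
    N <- cohorts$eligible_children[i]
    for (o in config$outcomes) {
      switch(o$name,
        mortality = ,
        stunting = ,
        wasting_cross_sectional = {
          pop <- band_person_count(N, o$effect_window, design)
          add(y, o$name, pop, averted(o$baseline, o$relative_reduction, pop))
        },
        wasting_longitudinal = {
          pop <- band_person_count(N, o$effect_window, design)
          for (b in names(o$correction_factors)) {
            prev <- longitudinal_prevalence(o$baseline, o$correction_factors[[b]])
            add(y, paste0("wasting_longitudinal_", b), pop,
                averted(prev, o$relative_reduction, pop))
          }
        },
        anaemia_mod_sev = {
          bp <- band_populations(N, o$baseline, o$effect_window, design,
                                 anaemia_person_base)
          cases <- sum(vapply(seq_len(nrow(bp)), function(j)
            averted(bp$prevalence[j], o$relative_reduction, bp$population[j]),
            numeric(1)))
          add(y, o$name, sum(bp$population), cases)
        },
        developmental_disability = {
          pop <- band_person_count(N, o$effect_window, design)
          add(y, o$name, pop, averted(o$baseline, o$relative_reduction, pop))
        }
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export an effect table as tidy delimited text
#' @param effects Output of [annual_effect_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_effect_table <- function(effects, path) {
  utils::write.csv(effects, path, row.names = FALSE)
  invisible(path)
}
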