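#' Age bands and steady-state cohort occupancy
#'
#' The annual eligible cohort (children supplemented in a year) is assumed to
#' be uniformly distributed across the months of supplementation, so at steady
#' state each one-month age slice holds `annual_cohort / duration_months`
#' children. Age bands outside the supplementation window (e.g. 18-24 months,
#' where anaemia and developmental-disability effects persist) use the same
#' slice size: the cohort that has aged out of supplementation.
#'
#' @name demography
NULL

#' Construct an age band
#'
#' @param start_month,end_month Months of age; the band is half-open
#'   `[start, end)` and must lie within 0-60 months.
#' @return Numeric length-2 vector of class `age_band`.
#' @export
age_band <- function(start_month, end_month) {
  if (start_month < 0 || end_month > 60 || start_month >= end_month)
    stop("age band must satisfy 0 <= start < end <= 60 months")
  structure(c(start_month, end_month), class = "age_band")
}

#' Children per one-month age slice at steady state
#'
#' @param annual_cohort Annual eligible-child count.
#' @param design An [intervention_design()].
#' @return `annual_cohort / duration_months`.
#' @export
#' @examples
#' monthly_cohort(1118340, intervention_design()) # 93195
monthly_cohort <- function(annual_cohort, design) {
  if (annual_cohort < 0) stop("annual_cohort must be non-negative")
  if (design$duration_months <= 0) stop("duration_months must be positive")
  annual_cohort / design$duration_months
}

#' Persons resident in an age band at steady state
#'
#' @param annual_cohort Annual eligible-child count.
#' @param band An [age_band()] or length-2 numeric `(start, end)` in months.
#' @param design An [intervention_design()].
#' @return `(end - start) * monthly_cohort`.
#' @export
#' @examples
#' band_person_count(1118340, age_band(18, 24), intervention_design()) # 559170
band_person_count <- function(annual_cohort, band, design) {
  band <- as.numeric(band)
  if (band[1] < 0 || band[2] > 60 || band[1] >= band[2])
    stop("band must lie within 0-60 months with start < end")
  (band[2] - band[1]) * monthly_cohort(annual_cohort, design)
}

#' Annual cohort projections
#'
#' @param years Calendar years.
#' @param eligible_children Eligible-child count per year.
#' @return A data frame of class `cohort_projection` with an
#'   `average_annual_cohort` attribute (the arithmetic mean across years).
#' @export
cohort_projection <- function(years, eligible_children) {
  if (length(years) != length(eligible_children))
    stop("years and eligible_children must have equal length")
  if (any(eligible_children < 0)) stop("cohort counts must be non-negative")
  out <- data.frame(year = as.integer(years),
                    eligible_children = as.numeric(eligible_children))
  attr(out, "average_annual_cohort") <- mean(out$eligible_children)
  class(out) <- c("cohort_projection", "data.frame")
  out
}

#' Mean annual cohort of a projection
#' @param cohorts A [cohort_projection()].
#' @return The arithmetic mean of the yearly counts.
#' @export
average_annual_cohort <- function(cohorts) {
  mean(cohorts$eligible_children)
}

#' Read a cohort projection from a two-column delimited file
#'
#' @param path CSV file with columns `year`, `eligible_children`.
#' @return A [cohort_projection()].
#' @export
read_cohort_projection <- function(path) {
  df <- utils::read.csv(path)
  cohort_projection(df$year, df$eligible_children)
}

#' Write a cohort projection to a delimited file
#' @param cohorts A [cohort_projection()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_projection <- function(cohorts, path) {
  utils::write.csv(as.data.frame(cohorts), path, row.names = FALSE)
  invisible(path)
}
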