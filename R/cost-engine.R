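## Charge-to-cost conversion and inclusion filters.
##
## A visit's hospital cost is the product of its total billed charge and the
## hospital- and year-specific cost-to-charge ratio; costs are then
## expressed in base-year dollars with an annual price index.  Two row
## filters implement the study's inclusion rules: only new-injury encounters
## (external-cause code ending in "A") enter the sample, and visits with a
## missing charge are excluded (and counted, not silently dropped).

#' Keep only new-injury encounters
#'
#' Retains visits whose external-cause code's final character is "A"
#' (initial encounter for a new injury).  Subsequent-encounter ("D"),
#' sequela ("S"), malformed and empty codes are dropped and counted.
#' Input order is preserved.
#'
#' @param visits data.frame/data.table with a `cause_code` column.
#' @return list with `visits` (kept rows) and `dropped` (count removed).
#' @examples
#' v <- data.frame(cause_code = c("W32.0XXA", "W32.0XXD"), total_charge = 1)
#' filter_new_injury(v)$dropped
#' @export
filter_new_injury <- function(visits) {
  visits <- as.data.table(visits)
  code <- visits$cause_code
  if (is.null(code)) stopf("visits table has no cause_code column")
  ok <- !is.na(code) & nzchar(code) &
    substr(code, nchar(code), nchar(code)) == "A"
  list(visits = visits[ok], dropped = sum(!ok))
}

#' Exclude visits with a missing charge
#'
#' @param visits data.frame/data.table with a `total_charge` column
#'   (missing charge = `NA`).
#' @return list with `visits` (kept rows, order preserved) and `excluded`
#'   (count removed).
#' @export
exclude_missing_charge <- function(visits) {
  visits <- as.data.table(visits)
  ok <- !is.na(visits$total_charge)
  list(visits = visits[ok], excluded = sum(!ok))
}

#' Convert a billed charge to an estimated hospital cost
#'
#' Cost is charge times the hospital- and year-specific cost-to-charge
#' ratio.  Ratios above 1 occur in real hospital files; ratios outside
#' (0, 1.5] are rejected as corrupt.
#'
#' @param charge numeric vector of billed charges (non-missing).
#' @param ratio numeric vector of cost-to-charge ratios in (0, 1.5].
#' @return numeric vector of costs (nominal dollars).
#' @export
compute_cost <- function(charge, ratio) {
  if (anyNA(charge)) stopf("compute_cost(): charge must be non-missing")
  if (anyNA(ratio) || any(ratio <= 0) || any(ratio > 1.5))
    stopf("compute_cost(): cost-to-charge ratio must lie in (0, 1.5]")
  charge * ratio
}

#' Look up hospital-year cost-to-charge ratios
#'
#' @param ccr data.table with columns hospital_id, year, ccr.
#' @param hospital_id,year vectors identifying the visits.
#' @return numeric vector of ratios, aligned with the input.
#' @export
lookup_ccr <- function(ccr, hospital_id, year) {
  ccr <- as.data.table(ccr)
  key <- paste(hospital_id, year, sep = "\r")
  pos <- match(key, paste(ccr$hospital_id, ccr$year, sep = "\r"))
  if (anyNA(pos)) {
    miss <- which(is.na(pos))[1L]
    stopf("no cost-to-charge ratio for hospital '%s', year %s",
          hospital_id[miss], year[miss])
  }
  ccr$ccr[pos]
}

cpi_index <- function(cpi, year) {
  pos <- match(year, cpi$year)
  if (anyNA(pos))
    stopf("no price index for year %s", paste(unique(year[is.na(pos)]),
                                              collapse = ", "))
  cpi$index[pos]
}

#' Inflation-adjust costs to base-year dollars
#'
#' Multiplies each cost by index(base year) / index(data year).  The
#' adjustment is multiplicative-linear: `adjust(a * x) = a * adjust(x)`.
#'
#' @param cost numeric vector of nominal-dollar costs.
#' @param year calendar year of each cost.
#' @param cpi data.table with columns year, index; the base year is taken
#'   from its `base_year` attribute unless overridden.
#' @param base_year target year for the adjustment (default 2024 when the
#'   table carries no attribute).
#' @return numeric vector of base-year-dollar costs.
#' @export
adjust_to_base_year <- function(cost, year, cpi, base_year = NULL) {
  if (is.null(base_year)) base_year <- attr(cpi, "base_year")
  if (is.null(base_year)) base_year <- 2024L
  cost * cpi_index(cpi, base_year) / cpi_index(cpi, year)
}

#' Apply the full cost model to a visits table
#'
#' Runs the inclusion filters (new-injury encounters only, non-missing
#' charge) and derives two columns: `cost` (charge times cost-to-charge
#' ratio, nominal dollars) and `cost_base` (inflation-adjusted to the base
#' year).  Drop counts are returned, mirroring a study log that reports
#' excluded-visit counts rather than failing.
#'
#' @param visits visit-level table (see [generate_claims()]).
#' @param ccr hospital-year cost-to-charge table.
#' @param cpi annual price-index table.
#' @param base_year base year for the inflation adjustment (default: the
#'   CPI table's `base_year` attribute, else 2024).
#' @return list with `visits` (costed table), `dropped_non_initial`,
#'   `excluded_missing_charge`.
#' @examples
#' study <- generate_claims(claims_config(seed = 1, n_sample_states = 1,
#'   n_nonsample_states = 0, years = 2016:2016, visits_per_state_year = 30))
#' costed <- apply_cost_model(study$visits, study$ccr, study$cpi)
#' costed$excluded_missing_charge
#' @export
apply_cost_model <- function(visits, ccr, cpi, base_year = NULL) {
  f1 <- filter_new_injury(visits)
  f2 <- exclude_missing_charge(f1$visits)
  v <- f2$visits
  if (nrow(v)) {
    ratio <- lookup_ccr(ccr, v$hospital_id, v$year)
    v[, cost := compute_cost(total_charge, ratio)]
    v[, cost_base := adjust_to_base_year(cost, year, cpi, base_year)]
  } else {
    v[, `:=`(cost = numeric(0), cost_base = numeric(0))]
  }
  list(visits = v[],
       dropped_non_initial = f1$dropped,
       excluded_missing_charge = f2$excluded)
}
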