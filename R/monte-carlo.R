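## Monte Carlo extrapolation from sample states to the nation.
##
## Each simulation (1) draws, for every year, a pure random sample with
## replacement of inpatient visits from the sample states, sized to the
## external inpatient-admission targets of the non-sample states; (2) draws
## an analogous ED-only sample sized by the targets times the sample
## states' ED:inpatient ratio for that year; (3) combines the resampled
## rows with the original sample-state rows into a national annual sample,
## and tallies stratified costs and counts.  Estimates are means across
## simulations; simulation standard errors are across-simulation SDs.

#' ED-only resampling target from an inpatient target
#'
#' The number of ED-only visits to draw for a non-sample state-year is the
#' inpatient admission target times the ratio of ED-only visits to
#' inpatient admissions observed in the sample states that year, rounded
#' half-up to an integer.
#'
#' @param ip_target inpatient admission target(s), non-negative.
#' @param sample_ed,sample_ip pooled sample-state ED-only and inpatient
#'   visit counts for the year (`sample_ip` must be positive).
#' @return integer vector of ED draw counts.
#' @examples
#' compute_ed_target(500, 8, 5)   # 800
#' compute_ed_target(100, 161, 100)
#' @export
compute_ed_target <- function(ip_target, sample_ed, sample_ip) {
  if (any(sample_ip == 0))
    stopf("degenerate ED:inpatient ratio: no sample inpatient visits")
  if (any(ip_target < 0)) stopf("inpatient targets must be non-negative")
  as.integer(round_half_up(ip_target * sample_ed / sample_ip))
}

#' Resample visits with replacement
#'
#' Draws `n` independent uniform rows with replacement from `pool`.  Drawn
#' copies keep every attribute of the donor visit but receive fresh visit
#' ids and `origin = "resampled"`.
#'
#' @param pool visits table to draw from.
#' @param n number of draws.
#' @param context optional string (e.g. year and visit type) included in
#'   the empty-pool error message.
#' @return data.table of `n` resampled visit rows.
#' @export
resample_visits <- function(pool, n, context = NULL) {
  pool <- as.data.table(pool)
  n <- as.integer(n)
  if (n == 0L) {
    out <- pool[0L]
    out[, origin := character(0)]
    return(out[])
  }
  if (nrow(pool) == 0L)
    stopf("cannot resample %d visits from an empty pool%s", n,
          if (is.null(context)) "" else paste0(" (", context, ")"))
  out <- pool[sample.int(nrow(pool), n, replace = TRUE)]
  out[, visit_id := sprintf("R%07d", seq_len(n))]
  out[, origin := "resampled"]
  out[]
}

#' Build one national annual sample
#'
#' Combines the original sample-state visits of one year with resampled
#' inpatient visits (one with-replacement draw per non-sample state's
#' inpatient target) and resampled ED-only visits (targets scaled by the
#' year's sample ED:inpatient ratio).  Resampled rows inherit the donor
#' visit's hospital and patient attributes.
#'
#' @param year calendar year to build.
#' @param sample_visits costed, derived sample-state visits (all years).
#' @param targets data.table (state, year, inpatient_count) for non-sample
#'   states.
#' @return data.table: original rows (`origin = "original"`) plus
#'   resampled rows (`origin = "resampled"`).
#' @export
build_national_sample <- function(year, sample_visits, targets) {
  v <- as.data.table(sample_visits)
  yr <- year
  vy <- v[v$year == yr]
  if (nrow(vy) == 0L) stopf("no sample visits in year %s", yr)
  tg <- as.data.table(targets)[year == yr]
  t_ip <- sum(tg$inpatient_count)
  n_ed <- sum(vy$visit_type == "ed_only")
  n_ip <- sum(vy$visit_type == "inpatient")
  t_ed <- if (nrow(tg)) sum(compute_ed_target(tg$inpatient_count, n_ed, n_ip)) else 0L
  orig <- copy(vy)[, origin := "original"]
  res_ip <- resample_visits(vy[visit_type == "inpatient"], t_ip,
                            context = sprintf("year %s, inpatient", yr))
  res_ed <- resample_visits(vy[visit_type == "ed_only"], t_ed,
                            context = sprintf("year %s, ed_only", yr))
  rbind(orig, res_ip, res_ed)
}

#' Attach hospital attributes to visits
#'
#' Left-joins hospital survey attributes onto visits by hospital id and
#' derives the hospital-level stratifier columns: bed-size category
#' (1-99 / 100-499 / >=500), Medicaid discharge share, CBSA class, trauma
#' level, rural flag, admission and ED volumes, medical-school affiliation.
#'
#' @param visits visit-level table.
#' @param hospitals hospital table (see [generate_hospitals()]).
#' @return visits with `hosp_*` columns appended.
#' @export
join_hospital_attributes <- function(visits, hospitals) {
  v <- as.data.table(visits)
  h <- as.data.table(hospitals)
  cols <- h[, .(hospital_id,
                hosp_beds_category = as.character(cut(beds,
                  breaks = c(0, 99, 499, Inf),
                  labels = c("1-99", "100-499", ">=500"))),
                hosp_medicaid_share = medicaid_share,
                hosp_cbsa = cbsa,
                hosp_trauma_level = trauma_level,
                hosp_rural = ifelse(rural == 1L, "yes", "no"),
                hosp_admissions = admissions,
                hosp_ed_visits = ed_visits,
                hosp_med_school = ifelse(med_school == 1L, "yes", "no"))]
  out <- merge(v, cols, by = "hospital_id", all.x = TRUE, sort = FALSE)
  setcolorder(out, names(v))
  out[]
}

#' Default stratifier set for national cost tables
#'
#' Named list defining every reporting stratum: patient demographics,
#' injury variables, hospital attributes, calendar year, and the
#' year-by-age and year-by-race interactions used for trend series.  A
#' plain character element groups by those columns; an element of the form
#' `list(var = , quartile = TRUE)` assigns ascending quartiles of a
#' numeric hospital variable with thresholds recomputed from the realized
#' visits of each simulated national sample (so the resampled composition
#' determines the cut points, and hospitals are implicitly weighted by
#' their visit multiplicity).
#'
#' @return named list of stratifier definitions.
#' @export
default_stratifiers <- function() {
  list(
    year = "year",
    age_group = "age_group",
    sex = "sex",
    race_ethnicity = "race_ethnicity",
    payer = "payer",
    zip_income_quartile = "zip_income_quartile",
    disposition = "disposition",
    intent = "intent",
    body_region = "body_region",
    iss_category = "iss_category",
    comorbidity_category = "comorbidity_category",
    reinjury = "reinjury_flag",
    hospital_beds = "hosp_beds_category",
    medicaid_discharge_quartile = list(var = "hosp_medicaid_share", quartile = TRUE),
    cbsa = "hosp_cbsa",
    trauma_level = "hosp_trauma_level",
    rural_hospital = "hosp_rural",
    admissions_quartile = list(var = "hosp_admissions", quartile = TRUE),
    ed_volume_quartile = list(var = "hosp_ed_visits", quartile = TRUE),
    medical_school = "hosp_med_school",
    year_age = c("year", "age_group"),
    year_race = c("year", "race_ethnicity")
  )
}

strat_columns <- function(stratifiers) {
  unique(unlist(lapply(stratifiers, function(s) {
    if (is.list(s)) s$var else s
  }), use.names = FALSE))
}

## paste grouping columns into a level label; NA in any column -> "missing"
level_label <- function(dt, cols) {
  vals <- lapply(cols, function(cl) {
    x <- as.character(dt[[cl]])
    x[is.na(x)] <- "missing"
    x
  })
  do.call(paste, c(vals, sep = "|"))
}

#' Tally stratified costs and counts of one national sample
#'
#' For every stratifier level and visit type (ED-only, inpatient, overall)
#' the total base-year cost and visit count over matching rows; missing
#' stratifier values accumulate into a reserved `"missing"` level, so
#' category totals need not sum to the overall total.  Quartile
#' stratifiers recompute their thresholds from this sample before cells
#' are tallied.  An `"overall"` pseudo-stratifier holds the grand totals.
#'
#' @param sample a national sample (see [build_national_sample()]) with a
#'   `cost_base` column.
#' @param stratifiers named list as in [default_stratifiers()].
#' @param collect_median also compute the median per-visit cost per cell.
#' @return data.table with columns stratifier, level, visit_type,
#'   total_cost, n_visits (and median_cost when requested).
#' @export
summarize_sample <- function(sample, stratifiers = default_stratifiers(),
                             collect_median = FALSE) {
  s <- as.data.table(sample)
  if (!"cost_base" %in% names(s))
    stopf("sample has no cost_base column; run apply_cost_model() first")
  missing_cols <- setdiff(strat_columns(stratifiers), names(s))
  if (length(missing_cols))
    stopf("unknown stratifier column(s): %s", paste(missing_cols, collapse = ", "))

  empty_cells <- function() {
    out <- data.table(stratifier = character(0), level = character(0),
                      visit_type = character(0), total_cost = numeric(0),
                      n_visits = integer(0))
    if (collect_median) out[, median_cost := numeric(0)]
    out
  }

  tally_one <- function(lvl, name) {
    if (length(lvl) == 0L) return(empty_cells())
    grp <- data.table(level = lvl, visit_type = s$visit_type,
                      cost_base = s$cost_base)
    by_type <- grp[, c(.(total_cost = sum(cost_base), n_visits = .N),
                       if (collect_median) .(median_cost = median(cost_base))),
                   by = .(level, visit_type)]
    overall <- grp[, c(.(total_cost = sum(cost_base), n_visits = .N,
                         visit_type = "overall"),
                       if (collect_median) .(median_cost = median(cost_base))),
                   by = level]
    out <- rbind(by_type, overall, use.names = TRUE, fill = TRUE)
    out[, stratifier := name]
    setcolorder(out, c("stratifier", "level", "visit_type",
                       "total_cost", "n_visits"))
    out
  }

  pieces <- vector("list", length(stratifiers) + 1L)
  pieces[[1L]] <- tally_one(rep("overall", nrow(s)), "overall")

  for (i in seq_along(stratifiers)) {
    name <- names(stratifiers)[i]
    sdef <- stratifiers[[i]]
    if (is.list(sdef)) {
      thr <- compute_quartile_thresholds(s[[sdef$var]])
      lvl <- assign_quartile(s[[sdef$var]], thr)
      lvl[is.na(lvl)] <- "missing"
      pieces[[i + 1L]] <- tally_one(lvl, name)
    } else {
      pieces[[i + 1L]] <- tally_one(level_label(s, sdef), name)
    }
  }
  out <- rbindlist(pieces, use.names = TRUE)
  setorder(out, stratifier, level, visit_type)
  out[]
}

#' National cost estimation by Monte Carlo resampling
#'
#' The package's central estimator.  Sample-state visits (costed with
#' [apply_cost_model()] and derived with [derive_clinical()]) are
#' extrapolated to the nation: in every simulation and year, inpatient
#' visits are resampled with replacement to match the non-sample states'
#' inpatient admission targets, ED-only visits are resampled to the
#' targets scaled by that year's sample ED:inpatient ratio, and the
#' combined national sample is tallied over all requested stratifiers.
#'
#' Each simulation uses a child seed derived deterministically from
#' `(seed, simulation index)`, so results are reproducible and independent
#' of execution order.
#'
#' @param visits costed, derived sample-state visits.
#' @param targets data.table (state, year, inpatient_count) for non-sample
#'   states; must cover every year present in `visits`.
#' @param hospitals optional hospital table; when supplied,
#'   [join_hospital_attributes()] is applied first.
#' @param n_sims number of simulations (the study default is 2400).
#' @param seed master seed.
#' @param stratifiers named list as in [default_stratifiers()]; use
#'   `list()` for overall totals only.
#' @param ref_sim index of the reference simulation whose pooled per-visit
#'   cost distribution supplies cell medians.
#' @return object of class `national_cost_mc`; see
#'   [aggregate_simulations()], `summary()`, `plot()`.
#' @examples
#' cfg <- claims_config(seed = 7, n_sample_states = 2, n_nonsample_states = 3,
#'                      years = 2016:2017, visits_per_state_year = 80)
#' study <- generate_claims(cfg)
#' costed <- apply_cost_model(study$visits, study$ccr, study$cpi)$visits
#' costed <- derive_clinical(costed)
#' fit <- national_cost_mc(costed, study$targets, n_sims = 10, seed = 1,
#'                         stratifiers = list(sex = "sex"))
#' fit
#' @export
national_cost_mc <- function(visits, targets, hospitals = NULL,
                             n_sims = 2400L, seed = 1L,
                             stratifiers = default_stratifiers(),
                             ref_sim = 1L) {
  if (n_sims < 1L) stopf("n_sims must be at least 1")
  v <- as.data.table(visits)
  if (!is.null(hospitals)) v <- join_hospital_attributes(v, hospitals)
  if (!"cost_base" %in% names(v))
    stopf("visits have no cost_base column; run apply_cost_model() first")
  targets <- as.data.table(targets)
  if (any(targets$inpatient_count < 0))
    stopf("inpatient targets must be non-negative")

  keep <- unique(c("year", "visit_type", "cost_base",
                   intersect(strat_columns(stratifiers), names(v))))
  missing_cols <- setdiff(strat_columns(stratifiers), names(v))
  if (length(missing_cols))
    stopf("unknown stratifier column(s): %s", paste(missing_cols, collapse = ", "))
  vsub <- v[, ..keep]

  years <- sort(unique(vsub$year))
  miss_t <- setdiff(years, unique(targets$year))
  if (length(miss_t))
    stopf("targets missing for year(s): %s", paste(miss_t, collapse = ", "))

  idx_by <- list(
    ed_only = lapply(setNames(years, years),
                     function(y) which(vsub$year == y & vsub$visit_type == "ed_only")),
    inpatient = lapply(setNames(years, years),
                       function(y) which(vsub$year == y & vsub$visit_type == "inpatient"))
  )

  ## per-year targets: inpatient straight from the table, ED via the
  ## sample ED:inpatient ratio (per non-sample state, then summed)
  t_ip <- t_ed <- setNames(integer(length(years)), years)
  for (y in as.character(years)) {
    n_ed <- length(idx_by$ed_only[[y]])
    n_ip <- length(idx_by$inpatient[[y]])
    tg <- targets[year == as.integer(y), inpatient_count]
    t_ip[[y]] <- as.integer(sum(tg))
    t_ed[[y]] <- if (length(tg) && sum(tg) > 0)
      sum(compute_ed_target(tg, n_ed, n_ip)) else 0L
    if (t_ip[[y]] > 0L && n_ip == 0L)
      stopf("cannot resample %d visits from an empty pool (year %s, inpatient)",
            t_ip[[y]], y)
  }

  pool_stats <- vsub[, .(n = .N, mean_cost = mean(cost_base),
                         var_cost = var(cost_base)), by = .(year, visit_type)]

  cost <- vsub$cost_base
  n_orig <- nrow(vsub)
  child_seeds <- derive_child_seeds(seed, n_sims)

  results <- vector("list", n_sims)
  per_year <- vector("list", n_sims)
  ref_medians <- NULL
  for (k in seq_len(n_sims)) {
    sim <- with_seed(child_seeds[k], {
      res_idx <- integer(0)
      py <- vector("list", length(years))
      for (j in seq_along(years)) {
        y <- as.character(years[j])
        pool_ip <- idx_by$inpatient[[y]]
        pool_ed <- idx_by$ed_only[[y]]
        r_ip <- if (t_ip[[y]] > 0L)
          pool_ip[sample.int(length(pool_ip), t_ip[[y]], replace = TRUE)]
          else integer(0)
        r_ed <- if (t_ed[[y]] > 0L) {
          if (length(pool_ed) == 0L)
            stopf("cannot resample %d visits from an empty pool (year %s, ed_only)",
                  t_ed[[y]], y)
          pool_ed[sample.int(length(pool_ed), t_ed[[y]], replace = TRUE)]
        } else integer(0)
        res_idx <- c(res_idx, r_ip, r_ed)
        py[[j]] <- data.table(
          year = years[j],
          visit_type = c("inpatient", "ed_only"),
          sample_count = c(length(pool_ip), length(pool_ed)),
          sample_total = c(sum(cost[pool_ip]), sum(cost[pool_ed])),
          resampled_count = c(length(r_ip), length(r_ed)),
          resampled_total = c(sum(cost[r_ip]), sum(cost[r_ed]))
        )
      }
      nat <- vsub[c(seq_len(n_orig), res_idx)]
      summ <- summarize_sample(nat, stratifiers,
                               collect_median = (k == ref_sim))
      list(summ = summ, py = rbindlist(py))
    })
    if (k == ref_sim) {
      ref_medians <- sim$summ[, .(stratifier, level, visit_type, median_cost)]
      sim$summ[, median_cost := NULL]
    }
    sim$summ[, sim := k]
    sim$py[, sim := k]
    results[[k]] <- sim$summ
    per_year[[k]] <- sim$py
  }

  structure(list(
    results = rbindlist(results),
    per_year = rbindlist(per_year),
    ref_medians = ref_medians,
    n_sims = as.integer(n_sims),
    seed = as.integer(seed),
    ref_sim = as.integer(ref_sim),
    stratifiers = stratifiers,
    pool_stats = pool_stats,
    t_ip = t_ip,
    t_ed = t_ed,
    years = years,
    call = match.call()
  ), class = "national_cost_mc")
}
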