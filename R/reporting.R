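## Aggregation of simulation results into reporting surfaces: stratified
## total-cost and mean-cost tables with simulation standard errors, median
## per-visit costs, annual trend series, share-of-total statistics, and
## plain-CSV table writers.

#' Aggregate Monte Carlo simulation results
#'
#' For every stratum cell (stratifier, level, visit type):
#' * `mean_total` — arithmetic mean of the cell's total cost across
#'   simulations (2024 USD);
#' * `se_total` — across-simulation standard deviation (the headline
#'   simulation SE); `se_mean_total` = `se_total / sqrt(n_sims)` is also
#'   emitted, labelled as the SE of the across-simulation mean;
#' * `mean_count` — mean visit count;
#' * `mean_per_visit` — the per-visit cost computed within each simulation
#'   as total/count, then averaged (not the ratio of the means);
#'   simulations where the cell is empty contribute nothing and are
#'   tracked in `n_sims_nonzero`; `se_per_visit` is its
#'   across-simulation SD;
#' * `median_per_visit` — median of the pooled per-visit cost
#'   distribution of the reference simulation's national sample.
#'
#' Cells absent from an individual simulation are treated as zero-count
#' zero-cost; simulations must share the same stratifier set.
#'
#' @param fit a [national_cost_mc()] object.
#' @return data.table of class `cost_aggregate`.
#' @export
aggregate_simulations <- function(fit) {
  stopifnot(inherits(fit, "national_cost_mc"))
  res <- fit$results
  if (nrow(res) == 0L) stopf("no simulation results to aggregate")
  strat_by_sim <- res[, .(key = paste(sort(unique(stratifier)), collapse = ",")),
                      by = sim]
  if (length(unique(strat_by_sim$key)) != 1L)
    stopf("inconsistent cell universes: simulations disagree on stratifiers")
  cells <- unique(res[, .(stratifier, level, visit_type)])
  full <- cells[, .(sim = seq_len(fit$n_sims)), by = .(stratifier, level, visit_type)]
  full <- merge(full, res, by = c("stratifier", "level", "visit_type", "sim"),
                all.x = TRUE)
  full[is.na(total_cost), total_cost := 0]
  full[is.na(n_visits), n_visits := 0L]
  full[, per_visit := ifelse(n_visits > 0L, total_cost / n_visits, NA_real_)]

  agg <- full[, .(
    mean_total = mean(total_cost),
    se_total = if (.N > 1L) sd(total_cost) else 0,
    mean_count = mean(n_visits),
    mean_per_visit = if (any(n_visits > 0L)) mean(per_visit, na.rm = TRUE) else NA_real_,
    se_per_visit = if (sum(n_visits > 0L) > 1L) sd(per_visit, na.rm = TRUE) else 0,
    n_sims_nonzero = sum(n_visits > 0L)
  ), by = .(stratifier, level, visit_type)]
  agg[, se_mean_total := se_total / sqrt(fit$n_sims)]

  if (!is.null(fit$ref_medians)) {
    agg <- merge(agg, fit$ref_medians[, .(stratifier, level, visit_type,
                                          median_per_visit = median_cost)],
                 by = c("stratifier", "level", "visit_type"), all.x = TRUE)
  }
  setorder(agg, stratifier, level, visit_type)
  setattr(agg, "n_sims", fit$n_sims)
  setattr(agg, "class", c("cost_aggregate", class(agg)))
  agg[]
}

## locate one cell in an aggregate (or any table carrying the three key
## columns plus a value column)
cell_value <- function(estimate, cell, value_col) {
  est <- as.data.table(estimate)
  hit <- est[stratifier == cell[[1L]] & level == cell[[2L]] &
               visit_type == cell[[3L]]]
  if (nrow(hit) != 1L)
    stopf("cell (%s, %s, %s) matches %d rows", cell[[1L]], cell[[2L]],
          cell[[3L]], nrow(hit))
  hit[[value_col]]
}

#' Share of one stratum cell's cost in another's
#'
#' 100 times the ratio of the numerator cell's mean total cost to the
#' denominator cell's, optionally rounded.  Works on a [aggregate_simulations()]
#' result or on any table with columns stratifier, level, visit_type and a
#' total-cost column (e.g. the published-estimate fixture).
#'
#' @param estimate aggregate or compatible table.
#' @param numerator,denominator length-3 character vectors
#'   `c(stratifier, level, visit_type)`.
#' @param digits rounding digits, or `NULL` for the raw percentage.
#' @param value_col column holding the totals; defaults to `mean_total`
#'   when present, else `total_cost`.
#' @return percentage (numeric scalar).
#' @export
share_of_total <- function(estimate, numerator, denominator,
                           digits = NULL, value_col = NULL) {
  if (is.null(value_col))
    value_col <- if ("mean_total" %in% names(estimate)) "mean_total" else "total_cost"
  num <- cell_value(estimate, numerator, value_col)
  den <- cell_value(estimate, denominator, value_col)
  if (!is.finite(den) || den == 0)
    stopf("share_of_total(): zero or undefined denominator")
  pct <- 100 * num / den
  if (!is.null(digits)) pct <- round(pct, digits)
  pct
}

#' Percent change between two values
#'
#' @param v1,v2 numeric: earlier and later value.
#' @return `100 * (v2 - v1) / v1`.
#' @export
percent_change <- function(v1, v2) 100 * (v2 - v1) / v1

#' Annual trend series from a fitted Monte Carlo object
#'
#' Per-year means across simulations of total cost and per-visit cost,
#' either by visit type (from the `year` stratifier) or by age group /
#' race and ethnicity (from the year interactions in
#' [default_stratifiers()]).
#'
#' @param fit a [national_cost_mc()] object.
#' @param by `"visit_type"`, `"age_group"` or `"race_ethnicity"`.
#' @return data.table with columns year, group, mean_total,
#'   mean_per_visit.
#' @export
trend_table <- function(fit, by = c("visit_type", "age_group", "race_ethnicity")) {
  stopifnot(inherits(fit, "national_cost_mc"))
  by <- match.arg(by)
  res <- fit$results
  if (by == "visit_type") {
    sub <- res[stratifier == "year"]
    if (nrow(sub) == 0L) stopf("fit has no 'year' stratifier")
    sub <- sub[, .(year = as.integer(level), group = visit_type,
                   total_cost, n_visits, sim)]
  } else {
    sname <- if (by == "age_group") "year_age" else "year_race"
    sub <- res[stratifier == sname & visit_type == "overall"]
    if (nrow(sub) == 0L) stopf("fit has no '%s' stratifier", sname)
    parts <- tstrsplit(sub$level, "|", fixed = TRUE)
    sub <- sub[, .(year = as.integer(parts[[1L]]), group = parts[[2L]],
                   total_cost, n_visits, sim)]
  }
  out <- sub[, .(
    mean_total = mean(total_cost),
    mean_per_visit = {
      pv <- total_cost[n_visits > 0L] / n_visits[n_visits > 0L]
      if (length(pv)) mean(pv) else NA_real_
    }
  ), by = .(year, group)]
  setorder(out, group, year)
  out[]
}

fmt_millions <- function(x) round(x / 1e6, 1)

#' Write reporting tables as plain CSV plus a JSON run summary
#'
#' Emits into `dir`:
#' * `table1_total_cost.csv` — total cost (millions of base-year dollars,
#'   1 decimal) with simulation SE, wide by visit type;
#' * `table2_mean_cost.csv` — mean per-visit cost (whole dollars) with SE,
#'   for ED-only and inpatient visits;
#' * `medians.csv` — median per-visit cost per cell;
#' * `estimates_full.csv` — every cell at full precision;
#' * `trends.csv` — annual trend series (when supplied);
#' * `run_summary.json` — seeds, simulation count and drop counts.
#'
#' An empty estimate produces header-only files with a warning.
#'
#' @param estimate a [aggregate_simulations()] result.
#' @param trend optional [trend_table()] result.
#' @param dir output directory (created if needed).
#' @param run_info named list merged into the JSON run summary.
#' @return invisibly, the vector of files written.
#' @export
write_cost_tables <- function(estimate, trend = NULL, dir, run_info = list()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  est <- as.data.table(estimate)
  if (nrow(est) == 0L)
    warning("empty estimate: writing header-only tables", call. = FALSE)

  t1 <- dcast(est, stratifier + level ~ visit_type,
              value.var = c("mean_total", "se_total"))
  num_cols <- setdiff(names(t1), c("stratifier", "level"))
  for (cl in num_cols) set(t1, j = cl, value = fmt_millions(t1[[cl]]))
  setnames(t1, num_cols, paste0(num_cols, "_musd"))
  fwrite(t1, file.path(dir, "table1_total_cost.csv"))

  t2 <- dcast(est[visit_type %in% c("ed_only", "inpatient")],
              stratifier + level ~ visit_type,
              value.var = c("mean_per_visit", "se_per_visit"))
  for (cl in intersect(c("mean_per_visit_ed_only", "mean_per_visit_inpatient"),
                       names(t2)))
    set(t2, j = cl, value = round(t2[[cl]]))
  for (cl in intersect(c("se_per_visit_ed_only", "se_per_visit_inpatient"),
                       names(t2)))
    set(t2, j = cl, value = round(t2[[cl]], 1))
  fwrite(t2, file.path(dir, "table2_mean_cost.csv"))

  med_cols <- intersect(c("stratifier", "level", "visit_type",
                          "median_per_visit"), names(est))
  fwrite(est[, ..med_cols], file.path(dir, "medians.csv"))

  fwrite(est, file.path(dir, "estimates_full.csv"))

  files <- c("table1_total_cost.csv", "table2_mean_cost.csv",
             "medians.csv", "estimates_full.csv")
  if (!is.null(trend)) {
    fwrite(as.data.table(trend), file.path(dir, "trends.csv"))
    files <- c(files, "trends.csv")
  }
  summary_json <- c(list(n_sims = attr(estimate, "n_sims"),
                         n_cells = nrow(est),
                         written = as.character(Sys.time())),
                    run_info)
  jsonlite::write_json(summary_json, file.path(dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(files, "run_summary.json")
  invisible(file.path(dir, files))
}

#' Published national estimates used for arithmetic cross-checks
#'
#' The published national Monte Carlo estimates that this package's
#' methodology reimplements, typed in from the public report: per stratum
#' cell the total cost in millions of 2024 dollars with its simulation SE,
#' the mean per-visit cost with its SE, and (for the overall cells) the
#' national visit counts.  These printed values serve as a fixture for
#' arithmetic-identity checks (shares, totals over visit types,
#' total/count consistency); they are inputs, not package output.
#'
#' @return data.table with columns stratifier, level, visit_type,
#'   total_cost_millions, se_total_millions, mean_cost, se_mean_cost,
#'   n_visits, and a derived `total_cost` column in dollars.
#' @export
published_estimates <- function() {
  path <- system.file("extdata", "published_national_estimates.csv",
                      package = "firearmcost", mustWork = TRUE)
  out <- fread(path)
  out[, total_cost := total_cost_millions * 1e6]
  out[]
}
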