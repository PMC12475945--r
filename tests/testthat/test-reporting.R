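## minimal hand-built fit object for aggregation arithmetic
fake_fit <- function(totals, counts = rep(10L, length(totals)),
                     stratifier = "overall", level = "overall",
                     visit_type = "overall") {
  n <- length(totals)
  res <- data.table::data.table(
    sim = seq_len(n), stratifier = stratifier, level = level,
    visit_type = visit_type, total_cost = totals, n_visits = counts)
  structure(list(results = res, per_year = NULL, ref_medians = NULL,
                 n_sims = n, seed = 1L, ref_sim = 1L,
                 stratifiers = list(), years = 2016L),
            class = "national_cost_mc")
}

test_that("aggregation is mean across simulations with SD as the simulation SE", {
  agg <- aggregate_simulations(fake_fit(c(10, 12, 14)))
  expect_equal(agg$mean_total, 12)
  expect_equal(agg$se_total, 2)
  expect_equal(agg$se_mean_total, 2 / sqrt(3))
  expect_equal(agg$mean_per_visit, mean(c(1.0, 1.2, 1.4)))

  single <- aggregate_simulations(fake_fit(42))
  expect_equal(single$se_total, 0)

  ident <- aggregate_simulations(fake_fit(rep(7, 5)))
  expect_identical(ident$se_total, 0)
})

test_that("per-visit means are averaged within-simulation ratios, skipping empty cells", {
  fit <- fake_fit(c(100, 0, 300), counts = c(10L, 0L, 10L))
  agg <- aggregate_simulations(fit)
  expect_equal(agg$mean_per_visit, mean(c(10, 30)))
  expect_equal(agg$n_sims_nonzero, 2L)
  ## but the total mean still averages over all simulations
  expect_equal(agg$mean_total, mean(c(100, 0, 300)))
})

test_that("share_of_total reproduces published share identities", {
  pub <- published_estimates()
  expect_equal(share_of_total(pub, c("overall", "overall", "inpatient"),
                              c("overall", "overall", "overall"), digits = 0), 93)
  expect_equal(share_of_total(pub, c("reinjury", ">=1", "overall"),
                              c("overall", "overall", "overall"), digits = 0), 9)
  expect_equal(share_of_total(pub, c("overall", "overall", "overall"),
                              c("overall", "overall", "overall")), 100)
  zero <- data.table::data.table(stratifier = "overall", level = "overall",
                                 visit_type = c("overall", "inpatient"),
                                 total_cost = c(0, 1))
  expect_error(share_of_total(zero, c("overall", "overall", "inpatient"),
                              c("overall", "overall", "overall")), "denominator")
})

test_that("trend series aggregate per year and support percent change", {
  expect_equal(percent_change(100, 154), 54)
  expect_equal(percent_change(100, 73), -27)

  tc <- tiny_costed(seed = 51)
  fit <- national_cost_mc(tc$visits, tc$study$targets, n_sims = 6, seed = 4,
                          stratifiers = list(year = "year",
                                             year_age = c("year", "age_group")))
  tr <- trend_table(fit, "visit_type")
  agg <- aggregate_simulations(fit)
  ## yearly totals sum to the all-years total
  expect_equal(tr[group == "overall", sum(mean_total)],
               agg[stratifier == "overall" & level == "overall" &
                     visit_type == "overall", mean_total],
               tolerance = 1e-9)
  tra <- trend_table(fit, "age_group")
  expect_true(all(c("year", "group", "mean_total", "mean_per_visit") %in% names(tra)))
  expect_equal(sort(unique(tra$year)), fit$years)
  expect_error(trend_table(fit, "race_ethnicity"), "year_race")
})

test_that("with zero targets and a constant sample the trend series is flat", {
  v <- hand_visits10()
  ## make the two years identical in cost and composition
  v[, cost_base := rep(c(100, 900), 5)]
  v <- rbind(v[1:4], v[1:4][, `:=`(year = 2017L,
                                   visit_id = paste0(visit_id, "b"),
                                   person_link = paste0(person_link, "b"))])
  targets0 <- data.table::data.table(state = "N01", year = 2016:2017,
                                     inpatient_count = 0L)
  fit <- national_cost_mc(v, targets0, n_sims = 3, seed = 1,
                          stratifiers = list(year = "year"))
  tr <- trend_table(fit, "visit_type")
  expect_equal(tr[group == "overall" & year == 2016, mean_total],
               tr[group == "overall" & year == 2017, mean_total])
})

test_that("written tables round-trip and use millions formatting", {
  tc <- tiny_costed(seed = 52)
  fit <- national_cost_mc(tc$visits, tc$study$targets, n_sims = 4, seed = 8,
                          stratifiers = list(sex = "sex", year = "year"))
  agg <- aggregate_simulations(fit)
  dir <- withr::local_tempdir()
  files <- write_cost_tables(agg, trend_table(fit, "visit_type"), dir,
                             run_info = list(seed = 8))
  expect_true(all(file.exists(files)))
  full <- data.table::fread(file.path(dir, "estimates_full.csv"))
  expect_equal(full$mean_total, agg$mean_total, tolerance = 1e-8)
  t1 <- data.table::fread(file.path(dir, "table1_total_cost.csv"))
  ov <- agg[stratifier == "overall" & visit_type == "overall", mean_total]
  expect_equal(t1[stratifier == "overall", mean_total_overall_musd],
               round(ov / 1e6, 1))
  js <- jsonlite::read_json(file.path(dir, "run_summary.json"))
  expect_equal(js$n_sims, 4L)
  expect_equal(js$seed, 8L)
  ## millions formatting example
  expect_equal(firearmcost:::fmt_millions(7746300000), 7746.3)
})

test_that("stratum means plus the missing level reproduce the overall mean", {
  tc <- tiny_costed(seed = 53)
  fit <- national_cost_mc(tc$visits, tc$study$targets, n_sims = 5, seed = 2,
                          stratifiers = list(payer = "payer",
                                             zipq = "zip_income_quartile"))
  agg <- aggregate_simulations(fit)
  overall <- agg[stratifier == "overall" & visit_type == "overall", mean_total]
  for (sname in c("payer", "zipq")) {
    lvl_sum <- agg[stratifier == sname & visit_type == "overall", sum(mean_total)]
    expect_equal(lvl_sum, overall, tolerance = 1e-6)
  }
})

test_that("medians come from the reference simulation and ignore simulation order", {
  tc <- tiny_costed(seed = 54)
  fit <- national_cost_mc(tc$visits, tc$study$targets, n_sims = 5, seed = 3,
                          stratifiers = list(sex = "sex"))
  agg <- aggregate_simulations(fit)
  expect_true("median_per_visit" %in% names(agg))
  expect_true(all(is.finite(agg$median_per_visit)))
  ## the reference simulation is fixed by its child seed, so medians are
  ## unchanged when more simulations are appended
  fit2 <- national_cost_mc(tc$visits, tc$study$targets, n_sims = 8, seed = 3,
                           stratifiers = list(sex = "sex"))
  expect_equal(fit$ref_medians, fit2$ref_medians)
})

test_that("inconsistent simulation universes are rejected", {
  bad <- fake_fit(c(1, 2))
  bad$results[2, stratifier := "payer"]
  expect_error(aggregate_simulations(bad), "inconsistent")
})
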