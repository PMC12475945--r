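test_that("ED resampling targets scale inpatient targets by the sample ratio", {
  expect_equal(compute_ed_target(500, 8, 5), 800L)
  expect_equal(compute_ed_target(0, 8, 5), 0L)
  expect_equal(compute_ed_target(100, 161, 100), 161L)
  ## half-up rounding: 1 * 3/2 = 1.5 -> 2
  expect_equal(compute_ed_target(1, 3, 2), 2L)
  expect_error(compute_ed_target(10, 5, 0), "degenerate")
})

test_that("resampling draws uniform copies with fresh ids and provenance", {
  pool <- hand_visits10()
  expect_equal(nrow(resample_visits(pool, 0)), 0L)
  one <- resample_visits(pool[3], 5)
  expect_equal(nrow(one), 5L)
  expect_equal(unique(one$person_link), "p2")
  expect_equal(unique(one$origin), "resampled")
  expect_equal(anyDuplicated(one$visit_id), 0L)
  expect_error(resample_visits(pool[0], 3, context = "year 2016, inpatient"),
               "empty pool.*year 2016, inpatient")
  ## CLT check: with n = 10000 the resampled mean cost lies within
  ## 4 * SD/sqrt(n) of the pool mean with probability > 0.999
  set.seed(5)
  big <- resample_visits(pool, 10000)
  tol <- 4 * stats::sd(pool$cost_base) / sqrt(10000)
  expect_lt(abs(mean(big$cost_base) - mean(pool$cost_base)), tol)
})

test_that("a national annual sample is original visits plus target-sized resamples", {
  v <- hand_visits10()
  targets0 <- data.table::data.table(state = c("N01", "N02"),
                                     year = 2016L, inpatient_count = 0L)
  set.seed(1)
  nat0 <- build_national_sample(2016L, v, targets0)
  expect_equal(nrow(nat0), 4L)
  expect_equal(unique(nat0$origin), "original")

  targets <- data.table::data.table(state = c("N01", "N02"),
                                    year = 2016L, inpatient_count = c(3L, 4L))
  set.seed(1)
  nat <- build_national_sample(2016L, v, targets)
  expect_equal(sum(nat$origin == "resampled" & nat$visit_type == "inpatient"), 7L)
  ## ED draws: per state round(t_ip * 2/2) -> 3 + 4
  expect_equal(sum(nat$origin == "resampled" & nat$visit_type == "ed_only"), 7L)
  expect_equal(sum(nat$origin == "original"), 4L)
})

test_that("summarize_sample tallies strata, missing levels, and grand totals", {
  one <- hand_visits10()[4][, cost_base := 100]
  s1 <- summarize_sample(one, list(payer = "payer"))
  expect_equal(s1[stratifier == "overall" & visit_type == "overall", total_cost], 100)
  expect_equal(s1[stratifier == "overall" & visit_type == "inpatient", total_cost], 100)
  expect_equal(s1[stratifier == "payer" & level == "Medicaid" &
                    visit_type == "inpatient", total_cost], 100)

  v <- hand_visits10()
  s <- summarize_sample(v, list(payer = "payer", age_group = "age_group"))
  overall <- s[stratifier == "overall" & visit_type == "overall", total_cost]
  payer_sum <- s[stratifier == "payer" & visit_type == "overall", sum(total_cost)]
  expect_equal(payer_sum, overall, tolerance = 1e-12)
  expect_true("missing" %in% s[stratifier == "payer", level])
  expect_true("missing" %in% s[stratifier == "age_group", level])

  expect_equal(nrow(summarize_sample(v[0], list(payer = "payer"))), 0L)
  expect_error(summarize_sample(v, list(bogus = "nope")), "unknown stratifier")
})

test_that("per-simulation quartile stratifiers recompute thresholds from the sample", {
  v <- hand_visits10()
  v[, hosp_admissions := rep(c(10, 1000), 5)]
  s <- summarize_sample(v, list(admq = list(var = "hosp_admissions", quartile = TRUE)))
  lv <- s[stratifier == "admq" & visit_type == "overall"]
  ## two distinct values: q1 = 10 so the low half ties into Q1, and
  ## q3 = 1000 puts the high half in Q3 (lower-tie rule)
  expect_setequal(lv$level, c("Q1", "Q3"))
  expect_equal(sum(lv$n_visits), 10L)
})

test_that("the Monte Carlo fit is reproducible and respects count conservation", {
  tc <- tiny_costed(seed = 41)
  fit1 <- national_cost_mc(tc$visits, tc$study$targets, n_sims = 8, seed = 5,
                           stratifiers = list(sex = "sex"))
  fit2 <- national_cost_mc(tc$visits, tc$study$targets, n_sims = 8, seed = 5,
                           stratifiers = list(sex = "sex"))
  expect_identical(fit1$results, fit2$results)
  expect_identical(fit1$per_year, fit2$per_year)
  fit3 <- national_cost_mc(tc$visits, tc$study$targets, n_sims = 8, seed = 6,
                           stratifiers = list(sex = "sex"))
  expect_false(identical(fit1$results, fit3$results))

  ## exact count conservation in every simulation and year
  py <- fit1$per_year
  t_ip <- fit1$t_ip
  for (y in names(t_ip)) {
    ip <- py[year == as.integer(y) & visit_type == "inpatient"]
    expect_true(all(ip$resampled_count == t_ip[[y]]))
    ed <- py[year == as.integer(y) & visit_type == "ed_only"]
    expect_true(all(ed$resampled_count == fit1$t_ed[[y]]))
  }
})

test_that("with all targets zero every simulation equals the sample summary", {
  tc <- tiny_costed(seed = 42)
  targets0 <- data.table::copy(tc$study$targets)[, inpatient_count := 0L]
  fit <- national_cost_mc(tc$visits, targets0, n_sims = 5, seed = 2,
                          stratifiers = list(payer = "payer"))
  direct <- summarize_sample(tc$visits, list(payer = "payer"))
  for (k in 1:5) {
    simk <- fit$results[sim == k, .(stratifier, level, visit_type,
                                    total_cost, n_visits)]
    data.table::setorder(simk, stratifier, level, visit_type)
    expect_equal(as.data.frame(simk), as.data.frame(direct))
  }
  agg <- aggregate_simulations(fit)
  expect_true(all(agg$se_total == 0))
})

test_that("resampled totals match their closed-form expectation and variance", {
  ## E[total] = T * pool mean; Var[total] = T * pool variance (iid draws
  ## with replacement); check the empirical mean within 4 SEs of the mean
  ## and the SD within 25% at 150 simulations
  tc <- tiny_costed(seed = 43, visits_per_state_year = 400)
  fit <- national_cost_mc(tc$visits, tc$study$targets, n_sims = 150, seed = 9,
                          stratifiers = list())
  ps <- fit$pool_stats
  for (y in fit$years) {
    t_ip <- fit$t_ip[[as.character(y)]]
    pool <- ps[year == y & visit_type == "inpatient"]
    res <- fit$per_year[year == y & visit_type == "inpatient", resampled_total]
    analytic_se <- sqrt(t_ip * pool$var_cost)
    expect_lt(abs(mean(res) - t_ip * pool$mean_cost),
              4 * analytic_se / sqrt(150))
    expect_lt(abs(stats::sd(res) - analytic_se), 0.25 * analytic_se)
  }
})

test_that("overall totals are the sum of the two visit types in every simulation", {
  tc <- tiny_costed(seed = 44)
  fit <- national_cost_mc(tc$visits, tc$study$targets, n_sims = 6, seed = 3,
                          stratifiers = list())
  ov <- data.table::dcast(fit$results[stratifier == "overall"],
                          sim ~ visit_type, value.var = "total_cost")
  expect_equal(ov$overall, ov$ed_only + ov$inpatient, tolerance = 1e-9)
})
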