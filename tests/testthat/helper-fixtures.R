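## Shared fixtures and independent oracles.

library(data.table)

## small synthetic study for fast tests
tiny_study <- function(seed = 11, n_sample_states = 2, n_nonsample_states = 3,
                       years = 2016:2017, visits_per_state_year = 200, ...) {
  generate_claims(claims_config(
    seed = seed, n_sample_states = n_sample_states,
    n_nonsample_states = n_nonsample_states, years = years,
    visits_per_state_year = visits_per_state_year, ...))
}

## tiny study taken through costing and clinical derivation
tiny_costed <- function(...) {
  study <- tiny_study(...)
  v <- apply_cost_model(study$visits, study$ccr, study$cpi)$visits
  v <- derive_clinical(v)
  list(visits = join_hospital_attributes(v, study$hospitals), study = study)
}

## ten hand-built visits with known costs and stratifiers
hand_visits10 <- function() {
  data.table(
    visit_id = sprintf("V%02d", 1:10),
    person_link = c("p1", "p1", "p2", "p3", "p4", "p5", "p6", "p7", "p8", "p9"),
    state = "S01",
    year = c(2016L, 2016L, 2016L, 2016L, 2017L, 2017L, 2017L, 2017L, 2017L, 2017L),
    hospital_id = rep(c("H1", "H2"), 5),
    visit_type = c("ed_only", "inpatient", "ed_only", "inpatient", "inpatient",
                   "ed_only", "inpatient", "ed_only", "inpatient", "ed_only"),
    cost_base = c(100, 5000, 250, 12000, 8000, 150, 20000, 300, 700, 90),
    age_group = c("0-17", "18-24", "25-44", "25-44", NA, "45-64", ">=65",
                  "18-24", "25-44", "0-17"),
    sex = c("male", "male", "female", "male", "male", "female", "male",
            "male", "female", "male"),
    payer = c("Medicaid", "self-pay", NA, "Medicaid", "private", "Medicare",
              "Medicaid", "other", "no-charge", "self-pay"),
    intent = c("assault", "assault", "unintentional", "self-inflicted",
               "assault", "undetermined", "unintentional", "assault",
               "legal intervention", "unintentional")
  )
}

## independent ISS oracle: maximize the sum of squares over every subset of
## at most three distinct regions (region severity = max AIS in region)
brute_iss <- function(severity, region) {
  if (length(severity) == 0L) return(0L)
  if (any(severity == 6L)) return(75L)
  per_region <- tapply(severity, as.character(region), max)
  regions <- names(per_region)
  best <- 0L
  for (k in seq_len(min(3L, length(regions)))) {
    combs <- utils::combn(regions, k)
    for (j in seq_len(ncol(combs)))
      best <- max(best, sum(as.integer(per_region[combs[, j]])^2L))
  }
  min(75L, as.integer(best))
}

## brute-force stratified totals: plain loops over levels and visit types
brute_strat_totals <- function(visits, col) {
  lev <- as.character(visits[[col]])
  lev[is.na(lev)] <- "missing"
  out <- list()
  for (lv in unique(lev)) {
    for (vt in c("ed_only", "inpatient", "overall")) {
      rows <- which(lev == lv &
                      (vt == "overall" | visits$visit_type == vt))
      if (length(rows))
        out[[length(out) + 1L]] <- data.table(
          level = lv, visit_type = vt,
          total_cost = sum(visits$cost_base[rows]),
          n_visits = length(rows))
    }
  }
  rbindlist(out)
}

## random AIS profile (region codes may repeat across injuries)
random_ais_profile <- function() {
  k <- sample(1:6, 1L)
  list(severity = sample(1:6, k, replace = TRUE, prob = c(.3, .25, .2, .15, .07, .03)),
       region = sample(LETTERS[1:4], k, replace = TRUE))
}
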