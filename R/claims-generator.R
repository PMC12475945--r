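## Synthetic administrative-claims generator.
##
## Emulates the statistical structure of state inpatient (SID) and state
## emergency-department (SEDD) discharge databases linked to hospital survey
## attributes: per-visit billed charges with a heavy right tail, a
## missing-charge fraction, mutually exclusive ED-only vs inpatient visit
## types, person-level linkage that never crosses a calendar year, and
## hospital- and year-specific cost-to-charge ratios.  Ground truth (true
## counts and base-year costs per state-year) is recorded at generation time
## so the downstream resampling estimator can be validated against known
## quantities.

#' Default marginal category distributions for synthetic visits
#'
#' Marginal probabilities for each patient-level stratifier, loosely
#' calibrated so the synthetic population resembles published national
#' firearm-injury visit profiles (predominantly male, aged 18-44, injured
#' in assaults or unintentional incidents, publicly insured or self-pay).
#' Stratifiers are sampled independently of one another.
#'
#' @return named list of named probability vectors, each summing to 1.
#'   A name of `"missing"` denotes the probability that the field is
#'   missing (emitted as `NA`).
#' @export
default_category_probabilities <- function() {
  list(
    age_group = c("0-17" = 0.09, "18-24" = 0.27, "25-44" = 0.45,
                  "45-64" = 0.14, ">=65" = 0.05),
    sex = c(female = 0.13, male = 0.87),
    race_ethnicity = c("Asian/Pacific Islander" = 0.01, "Black" = 0.54,
                       "Hispanic" = 0.11, "Native American" = 0.005,
                       "White" = 0.28, "other" = 0.055),
    payer = c(Medicaid = 0.44, Medicare = 0.06, private = 0.19,
              "self-pay" = 0.21, "no-charge" = 0.02, other = 0.08),
    zip_income_quartile = c("1" = 0.44, "2" = 0.25, "3" = 0.17, "4" = 0.11,
                            missing = 0.03),
    disposition = c("routine home" = 0.66, "transfer acute" = 0.04,
                    "transfer other facility" = 0.09, "home health" = 0.06,
                    "AMA" = 0.03, "died" = 0.12),
    intent = c(assault = 0.45, "self-inflicted" = 0.06,
               unintentional = 0.39, undetermined = 0.08,
               "legal intervention" = 0.02),
    body_region = c(HN = 0.10, FC = 0.05, CH = 0.12, AB = 0.14,
                    UE = 0.20, LE = 0.31, OT = 0.08),
    comorbidity_count = c("0" = 0.50, "1" = 0.24, "2" = 0.14, "3" = 0.07,
                          "4" = 0.03, "5" = 0.02)
  )
}

#' Configuration for the synthetic claims generator
#'
#' Bundles and validates every parameter of the synthetic study population:
#' the state/year grid, hospital counts, visit volumes, the target ED-only
#' to inpatient visit ratio, the log-normal nominal-charge laws per visit
#' type, the missing-charge fraction, the within-year reinjury rate, and
#' the per-stratifier marginal distributions.
#'
#' Nominal charges are log-normal with visit-type-specific parameters
#' because hospital charge distributions are strongly right-skewed: a small
#' number of very expensive visits carries a large share of total cost.
#'
#' @param seed integer seed controlling every random draw; a fixed seed
#'   regenerates all tables bit-identically.
#' @param n_sample_states number of "sample" states with full visit-level
#'   claims (the observed data).
#' @param n_nonsample_states number of states represented only by
#'   inpatient-admission targets.
#' @param years inclusive calendar-year range of the data.
#' @param hospitals_per_state hospitals generated per state.
#' @param visits_per_state_year mean visit count per state-year (Poisson).
#' @param ed_to_inpatient_ratio target ratio of ED-only visits to inpatient
#'   admissions (> 0).
#' @param charge_meanlog,charge_sdlog named numeric vectors with elements
#'   `ed_only` and `inpatient`: location and scale of the log-normal
#'   nominal-charge law per visit type (`charge_sdlog` > 0).
#' @param missing_charge_rate probability that a visit's charge is missing.
#' @param reinjury_rate fraction of persons with at least two new-injury
#'   visits in the same calendar year.
#' @param base_year base year for inflation-adjusted ground-truth costs.
#' @param category_probabilities list as returned by
#'   [default_category_probabilities()].
#' @param no_charge_as_self_pay_states states whose payer dialect records
#'   "no-charge" visits as self-pay (recoded downstream, see
#'   [derive_clinical()]).
#' @return an object of class `claims_config` (a validated list).
#' @seealso [generate_claims()]
#' @export
claims_config <- function(seed = 1L,
                          n_sample_states = 6L,
                          n_nonsample_states = 44L,
                          years = 2016:2021,
                          hospitals_per_state = 4L,
                          visits_per_state_year = 2500,
                          ed_to_inpatient_ratio = 1.61,
                          charge_meanlog = c(ed_only = 8.3, inpatient = 11.2),
                          charge_sdlog = c(ed_only = 0.8, inpatient = 1.0),
                          missing_charge_rate = 0.17,
                          reinjury_rate = 0.05,
                          base_year = 2024L,
                          category_probabilities = default_category_probabilities(),
                          no_charge_as_self_pay_states = character(0)) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (n_sample_states < 1L) stopf("need at least one sample state")
  if (n_nonsample_states < 0L) stopf("n_nonsample_states must be >= 0")
  if (hospitals_per_state < 1L) stopf("hospitals_per_state must be positive")
  if (visits_per_state_year <= 0) stopf("visits_per_state_year must be positive")
  if (ed_to_inpatient_ratio <= 0) stopf("ed_to_inpatient_ratio must be > 0")
  for (nm in c("ed_only", "inpatient")) {
    if (!nm %in% names(charge_meanlog) || !nm %in% names(charge_sdlog))
      stopf("charge parameters must be named for '%s'", nm)
    if (charge_sdlog[[nm]] <= 0) stopf("charge_sdlog must be > 0")
  }
  if (missing_charge_rate < 0 || missing_charge_rate > 1)
    stopf("missing_charge_rate must be in [0, 1]")
  if (reinjury_rate < 0 || reinjury_rate > 1)
    stopf("reinjury_rate must be in [0, 1]")
  for (nm in names(category_probabilities)) {
    p <- category_probabilities[[nm]]
    if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-9)
      stopf("category probabilities for '%s' must lie in [0,1] and sum to 1", nm)
  }
  years <- as.integer(years)
  structure(list(
    seed = as.integer(seed),
    n_sample_states = as.integer(n_sample_states),
    n_nonsample_states = as.integer(n_nonsample_states),
    years = seq(min(years), max(years)),
    hospitals_per_state = as.integer(hospitals_per_state),
    visits_per_state_year = visits_per_state_year,
    ed_to_inpatient_ratio = ed_to_inpatient_ratio,
    charge_meanlog = charge_meanlog,
    charge_sdlog = charge_sdlog,
    missing_charge_rate = missing_charge_rate,
    reinjury_rate = reinjury_rate,
    base_year = as.integer(base_year),
    category_probabilities = category_probabilities,
    no_charge_as_self_pay_states = no_charge_as_self_pay_states
  ), class = "claims_config")
}

sample_states <- function(cfg) sprintf("S%02d", seq_len(cfg$n_sample_states))
nonsample_states <- function(cfg) {
  if (cfg$n_nonsample_states == 0L) return(character(0))
  sprintf("N%02d", seq_len(cfg$n_nonsample_states))
}
all_states <- function(cfg) c(sample_states(cfg), nonsample_states(cfg))

#' @export
print.claims_config <- function(x, ...) {
  cat("Synthetic claims generator configuration\n")
  cat(sprintf("  states: %d sample + %d non-sample; years %d-%d\n",
              x$n_sample_states, x$n_nonsample_states,
              min(x$years), max(x$years)))
  cat(sprintf("  ~%g visits/state-year, ED:inpatient target %.2f\n",
              x$visits_per_state_year, x$ed_to_inpatient_ratio))
  cat(sprintf("  missing-charge rate %.2f, reinjury rate %.2f, seed %d\n",
              x$missing_charge_rate, x$reinjury_rate, x$seed))
  invisible(x)
}

#' Generate synthetic hospitals and their cost-to-charge ratios
#'
#' One row per hospital with the survey attributes used for hospital-level
#' stratification (bed count, Medicaid discharge share, CBSA class, trauma
#' level, rural flag, annual admission and ED volumes, medical-school
#' affiliation), plus one cost-to-charge ratio per (hospital, year).
#'
#' @param cfg a [claims_config()].
#' @return list with elements `hospitals` (data.table) and `ccr`
#'   (data.table with columns hospital_id, year, ccr).
#' @export
generate_hospitals <- function(cfg) {
  stopifnot(inherits(cfg, "claims_config"))
  with_seed(cfg$seed + 101L, {
    states <- all_states(cfg)
    n <- length(states) * cfg$hospitals_per_state
    state <- rep(states, each = cfg$hospitals_per_state)
    hospitals <- data.table(
      hospital_id = sprintf("%s-H%02d", state,
                            rep(seq_len(cfg$hospitals_per_state),
                                times = length(states))),
      state = state,
      beds = pmax(1L, as.integer(round(rlnorm(n, log(250), 0.8)))),
      medicaid_share = rbeta(n, 2.2, 6.5),
      cbsa = sample(c("metro", "micro", "rural"), n, replace = TRUE,
                    prob = c(0.70, 0.20, 0.10)),
      trauma_level = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                            prob = c(0.25, 0.30, 0.30, 0.15)),
      med_school = rbinom(n, 1L, 0.35)
    )
    hospitals[, rural := as.integer(rbinom(.N, 1L,
                                           ifelse(cbsa == "rural", 0.9, 0.04)))]
    hospitals[, admissions := as.integer(round(beds * runif(.N, 35, 90)))]
    hospitals[, ed_visits := as.integer(round(admissions * runif(.N, 1.5, 4)))]
    ccr <- CJ(hospital_id = hospitals$hospital_id, year = cfg$years)
    ccr[, ccr := runif(.N, 0.2, 0.5)]
    list(hospitals = hospitals[], ccr = ccr[])
  })
}

## intent -> external-cause code family prefixes (firearm families)
intent_code_prefixes <- list(
  unintentional = c("W32.0", "W33.0", "W34.0"),
  "self-inflicted" = c("X72.", "X73.0", "X74.0"),
  assault = c("X93.", "X94.0", "X95.0"),
  undetermined = c("Y22.", "Y23.0", "Y24.0"),
  "legal intervention" = c("Y35.0")
)

## AIS severity distributions; inpatient visits skew more severe
ais_probs <- list(
  ed_only = c(0.55, 0.32, 0.10, 0.025, 0.005, 0),
  inpatient = c(0.06, 0.24, 0.30, 0.25, 0.12, 0.03)
)

#' Generate synthetic visit-level claims with ground truth
#'
#' Generates one row per hospital visit for every state (sample and
#' non-sample) and year in the configuration.  Each visit carries a new
#' injury external-cause code (final character "A"), a nominal billed
#' charge (missing with probability `missing_charge_rate`), a person-link
#' id that never crosses states or calendar years, injured body-region
#' codes with per-region AIS severities, and independently sampled patient
#' stratifiers.  Ground truth — the true visit count and true base-year
#' cost per (state, year, visit type), over visits with a non-missing
#' charge — is computed at generation time.
#'
#' Within each state-year a fraction `reinjury_rate` of persons receives
#' two visits (a within-year reinjury); all other persons have one visit.
#'
#' @param cfg a [claims_config()].
#' @param hospitals output of [generate_hospitals()] (list with `hospitals`
#'   and `ccr`), or a hospital data.table plus `ccr` passed separately.
#' @param ccr cost-to-charge table; defaults to `hospitals$ccr`.
#' @param cpi CPI table used for ground-truth base-year conversion;
#'   defaults to [generate_cpi_table()].
#' @return list with elements `visits` (all states) and `truth` (list with
#'   `state_year` counts/costs and `national` totals by stratifier level).
#' @export
generate_visits <- function(cfg, hospitals, ccr = NULL, cpi = NULL) {
  stopifnot(inherits(cfg, "claims_config"))
  if (is.list(hospitals) && !is.data.frame(hospitals)) {
    if (is.null(ccr)) ccr <- hospitals$ccr
    hospitals <- hospitals$hospitals
  }
  if (is.null(hospitals) || nrow(hospitals) == 0L)
    stopf("generate_visits() needs a non-empty hospital table")
  if (is.null(ccr)) stopf("generate_visits() needs a cost-to-charge table")
  if (is.null(cpi)) cpi <- generate_cpi_table(cfg)

  cp <- cfg$category_probabilities
  p_ip <- 1 / (1 + cfg$ed_to_inpatient_ratio)

  with_seed(cfg$seed + 202L, {
    grid <- CJ(state = all_states(cfg), year = cfg$years)
    n_sy <- rpois(nrow(grid), cfg$visits_per_state_year)
    n_sy <- pmax(n_sy, 1L)
    n_tot <- sum(n_sy)

    visits <- data.table(
      state = rep(grid$state, n_sy),
      year = rep(grid$year, n_sy)
    )
    visits[, visit_id := sprintf("V%07d", .I)]

    ## person linkage: within each state-year, a fraction reinjury_rate of
    ## persons gets two visits.  With m paired persons among n visits,
    ## m = round(r * n / (1 + r)) gives m / (n - m) = r.
    visits[, person_link := {
      n <- .N
      m <- as.integer(round(cfg$reinjury_rate * n / (1 + cfg$reinjury_rate)))
      m <- min(m, n %/% 2L)
      pid <- integer(n)
      pid[seq_len(2L * m)] <- rep(seq_len(m), each = 2L)
      if (2L * m < n) pid[(2L * m + 1L):n] <- m + seq_len(n - 2L * m)
      pid <- sample(pid)  # shuffle so pairs are not adjacent
      sprintf("%s-%d-P%05d", state[1L], year[1L], pid)
    }, by = .(state, year)]

    ## hospital assignment within state
    hosp_by_state <- split(hospitals$hospital_id, hospitals$state)
    visits[, hospital_id := {
      ids <- hosp_by_state[[state[1L]]]
      ids[sample.int(length(ids), .N, replace = TRUE)]
    }, by = state]

    visits[, visit_type := ifelse(rbinom(.N, 1L, p_ip) == 1L,
                                  "inpatient", "ed_only")]

    ## nominal charges, missing with configured probability
    chg <- numeric(n_tot)
    for (vt in c("ed_only", "inpatient")) {
      idx <- which(visits$visit_type == vt)
      chg[idx] <- rlnorm(length(idx), cfg$charge_meanlog[[vt]],
                         cfg$charge_sdlog[[vt]])
    }
    chg[runif(n_tot) < cfg$missing_charge_rate] <- NA_real_
    visits[, total_charge := chg]

    ## external-cause code: intent family prefix + final character "A"
    intent <- sample_categorical(n_tot, cp$intent)
    prefix <- vapply(intent, function(it) {
      fams <- intent_code_prefixes[[it]]
      fams[sample.int(length(fams), 1L)]
    }, character(1))
    visits[, cause_code := paste0(prefix,
                                  sprintf("%d", sample(0:9, n_tot, TRUE)),
                                  "XA")]

    ## injured regions (1-3 distinct) with AIS severities per region
    n_regions <- sample(1:3, n_tot, replace = TRUE, prob = c(0.62, 0.27, 0.11))
    region_codes <- names(cp$body_region)
    reg_list <- lapply(seq_len(n_tot), function(i) {
      sample(region_codes, n_regions[i], replace = FALSE,
             prob = cp$body_region)
    })
    sev_fun <- function(vt, k) sample(1:6, k, replace = TRUE, prob = ais_probs[[vt]])
    ais_list <- mapply(function(vt, k) sev_fun(vt, k),
                       visits$visit_type, n_regions, SIMPLIFY = FALSE)
    visits[, diagnosis_region_codes := vapply(reg_list, paste, character(1),
                                              collapse = ";")]
    visits[, ais_codes := mapply(function(r, s) paste(r, s, sep = ":",
                                                      collapse = ";"),
                                 reg_list, ais_list)]

    ## patient stratifiers, sampled independently
    visits[, age_group := sample_categorical(n_tot, cp$age_group)]
    visits[, sex := sample_categorical(n_tot, cp$sex)]
    visits[, race_ethnicity := sample_categorical(n_tot, cp$race_ethnicity)]
    visits[, payer := sample_categorical(n_tot, cp$payer)]
    visits[, zip_income_quartile :=
             suppressWarnings(as.integer(sample_categorical(n_tot,
                                                            cp$zip_income_quartile)))]
    visits[, disposition := sample_categorical(n_tot, cp$disposition)]
    visits[, comorbidity_count :=
             as.integer(sample_categorical(n_tot, cp$comorbidity_count))]

    setcolorder(visits, c("visit_id", "person_link", "state", "year",
                          "hospital_id", "visit_type", "total_charge",
                          "cause_code", "diagnosis_region_codes", "ais_codes"))

    truth <- compute_ground_truth(visits, ccr, cpi, cfg$base_year)
    list(visits = visits[], truth = truth)
  })
}

## True counts and base-year costs, restricted to visits with a non-missing
## charge (mirrors the downstream missing-charge exclusion).
compute_ground_truth <- function(visits, ccr, cpi, base_year) {
  v <- visits[!is.na(total_charge)]
  v <- merge(v, ccr, by = c("hospital_id", "year"), all.x = TRUE, sort = FALSE)
  if (anyNA(v$ccr)) stopf("ground truth: missing cost-to-charge ratio entries")
  idx_base <- cpi_index(cpi, base_year)
  v[, cost_base := total_charge * ccr * idx_base / cpi_index(cpi, year),
    by = year]
  state_year <- v[, .(n_visits = .N, total_cost_base = sum(cost_base)),
                  by = .(state, year, visit_type)]
  setkey(state_year, state, year, visit_type)
  national <- list(
    total_cost_base = sum(state_year$total_cost_base),
    n_visits = sum(state_year$n_visits),
    by_visit_type = v[, .(n_visits = .N, total_cost_base = sum(cost_base)),
                      by = visit_type]
  )
  list(state_year = state_year[], national = national, base_year = base_year)
}

#' Generate state-year inpatient admission targets for non-sample states
#'
#' Stand-in for an external state-level database of inpatient
#' firearm-injury admission estimates.  In `"consistent"` mode the targets
#' equal the generator's ground-truth inpatient counts for each non-sample
#' state-year, so the resampling estimator's recovery of known totals is
#' testable; in `"external"` mode counts are drawn independently around the
#' same volume.
#'
#' @param cfg a [claims_config()].
#' @param truth ground truth from [generate_visits()].
#' @param mode `"consistent"` or `"external"`.
#' @return data.table with columns state, year, inpatient_count.
#' @export
generate_nonsample_targets <- function(cfg, truth, mode = c("consistent", "external")) {
  stopifnot(inherits(cfg, "claims_config"))
  if (length(mode) == 1L && !mode %in% c("consistent", "external"))
    stopf("unknown target mode '%s'", mode)
  mode <- match.arg(mode)
  ns <- nonsample_states(cfg)
  grid <- CJ(state = ns, year = cfg$years)
  if (mode == "consistent") {
    ip <- truth$state_year[visit_type == "inpatient",
                           .(state, year, inpatient_count = n_visits)]
    out <- merge(grid, ip, by = c("state", "year"), all.x = TRUE)
    out[is.na(inpatient_count), inpatient_count := 0L]
  } else {
    mean_ip <- cfg$visits_per_state_year / (1 + cfg$ed_to_inpatient_ratio)
    out <- with_seed(cfg$seed + 303L, {
      grid[, inpatient_count := pmax(1L, rpois(.N, mean_ip))][]
    })
  }
  out[]
}

## Annual all-items CPI-U averages (US city average), used as the default
## price series; years outside the embedded range grow at 3%/yr.
.cpi_reference <- c(
  "2016" = 240.007, "2017" = 245.120, "2018" = 251.107, "2019" = 255.657,
  "2020" = 258.811, "2021" = 270.970, "2022" = 292.655, "2023" = 304.702,
  "2024" = 313.689
)

#' Generate the annual price-index table
#'
#' Annual consumer price index covering the configured data years plus the
#' base year, used to express all costs in base-year dollars.
#'
#' @param cfg a [claims_config()].
#' @return data.table with columns year, index and attribute `base_year`.
#' @export
generate_cpi_table <- function(cfg) {
  stopifnot(inherits(cfg, "claims_config"))
  years <- sort(unique(c(cfg$years, cfg$base_year)))
  idx <- vapply(years, function(y) {
    key <- as.character(y)
    if (key %in% names(.cpi_reference)) return(.cpi_reference[[key]])
    known <- as.integer(names(.cpi_reference))
    nearest <- known[which.min(abs(known - y))]
    .cpi_reference[[as.character(nearest)]] * 1.03^(y - nearest)
  }, numeric(1))
  out <- data.table(year = years, index = idx)
  setattr(out, "base_year", cfg$base_year)
  out[]
}

#' Generate a complete synthetic claims study
#'
#' Convenience wrapper running every generator stage: hospitals and
#' cost-to-charge ratios, visits for all states with ground truth, the CPI
#' table, and non-sample inpatient targets.  The returned `visits` table
#' contains only the sample states (the observed data); ground truth covers
#' all states.
#'
#' @param cfg a [claims_config()].
#' @param target_mode passed to [generate_nonsample_targets()].
#' @return list of class `claims_study` with elements `visits` (sample
#'   states only), `hospitals`, `ccr`, `cpi`, `targets`, `truth`, `config`.
#' @examples
#' cfg <- claims_config(seed = 42, n_sample_states = 2, n_nonsample_states = 3,
#'                      years = 2016:2017, visits_per_state_year = 50)
#' study <- generate_claims(cfg)
#' nrow(study$visits)
#' @export
generate_claims <- function(cfg, target_mode = "consistent") {
  hs <- generate_hospitals(cfg)
  cpi <- generate_cpi_table(cfg)
  gv <- generate_visits(cfg, hs$hospitals, hs$ccr, cpi)
  targets <- generate_nonsample_targets(cfg, gv$truth, target_mode)
  structure(list(
    visits = gv$visits[state %in% sample_states(cfg)],
    hospitals = hs$hospitals,
    ccr = hs$ccr,
    cpi = cpi,
    targets = targets,
    truth = gv$truth,
    config = cfg
  ), class = "claims_study")
}

#' @export
print.claims_study <- function(x, ...) {
  cat("Synthetic claims study\n")
  cat(sprintf("  %d sample-state visits (%d hospitals, %d states), years %d-%d\n",
              nrow(x$visits), nrow(x$hospitals),
              length(unique(x$hospitals$state)),
              min(x$config$years), max(x$config$years)))
  cat(sprintf("  %d non-sample target cells; true national cost $%.1fM (%d base-year dollars)\n",
              nrow(x$targets), x$truth$national$total_cost_base / 1e6,
              x$config$base_year))
  invisible(x)
}

#' Write or read a claims study as plain CSV files
#'
#' `write_claims()` writes visits.csv, hospitals.csv, ccr.csv, cpi.csv and
#' targets.csv into `dir` (missing charges are written as empty fields);
#' `read_claims()` reads them back.
#'
#' @param study a `claims_study` (or any list with those five tables).
#' @param dir directory path.
#' @return `write_claims()` returns the directory invisibly;
#'   `read_claims()` returns a list of the five tables.
#' @export
write_claims <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fwrite(study$visits, file.path(dir, "visits.csv"))
  fwrite(study$hospitals, file.path(dir, "hospitals.csv"))
  fwrite(study$ccr, file.path(dir, "ccr.csv"))
  cpi <- copy(study$cpi)
  cpi[, base_year := attr(study$cpi, "base_year")]
  fwrite(cpi, file.path(dir, "cpi.csv"))
  fwrite(study$targets, file.path(dir, "targets.csv"))
  invisible(dir)
}

#' @rdname write_claims
#' @export
read_claims <- function(dir) {
  visits <- fread(file.path(dir, "visits.csv"),
                  colClasses = list(character = c("visit_id", "person_link",
                                                  "state", "hospital_id")))
  cpi_raw <- fread(file.path(dir, "cpi.csv"))
  base_year <- cpi_raw$base_year[1L]
  cpi <- cpi_raw[, .(year, index)]
  setattr(cpi, "base_year", base_year)
  list(
    visits = visits,
    hospitals = fread(file.path(dir, "hospitals.csv")),
    ccr = fread(file.path(dir, "ccr.csv")),
    cpi = cpi,
    targets = fread(file.path(dir, "targets.csv"))
  )
}
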