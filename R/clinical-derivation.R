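## Injury and visit-level derived variables: intent from external-cause
## code prefixes, body region from coded injury regions, the Injury
## Severity Score (ISS) from per-region AIS severities, comorbidity and ISS
## categories, the within-calendar-year reinjury flag, and quartile
## threshold computation/assignment for hospital-level stratifiers.

#' Default external-cause code prefix to injury-intent map
#'
#' Longest-prefix-match table covering the firearm external-cause code
#' families: W32-W34 unintentional, X72-X74 self-inflicted, X93-X95
#' assault, Y22-Y24 undetermined, Y35.0 legal intervention.  The map is an
#' ordinary data.frame and can be replaced or extended without code
#' changes; a copy ships as a CSV under `inst/extdata/intent_map.csv`.
#'
#' @return data.table with columns `prefix`, `intent`.
#' @export
default_intent_map <- function() {
  data.table(
    prefix = c("W32", "W33", "W34", "X72", "X73", "X74",
               "X93", "X94", "X95", "Y22", "Y23", "Y24", "Y35.0"),
    intent = c(rep("unintentional", 3), rep("self-inflicted", 3),
               rep("assault", 3), rep("undetermined", 3),
               "legal intervention")
  )
}

#' Default injured-region code to body-region label map
#'
#' Maps the generator's coded injury regions to reporting labels.  Distinct
#' upper- and lower-extremity codes both map to "extremities"; code OT is
#' the residual "other" region (injuries unclassifiable by body site).
#' Ships as `inst/extdata/region_map.csv`.
#'
#' @return data.table with columns `code`, `region`.
#' @export
default_region_map <- function() {
  data.table(
    code = c("HN", "FC", "CH", "AB", "UE", "LE", "OT"),
    region = c("head/neck", "face", "chest", "abdomen",
               "extremities", "extremities", "other")
  )
}

#' Classify injury intent from an external-cause code
#'
#' Longest matching prefix wins; dots are ignored when matching, so
#' "Y35.013A" matches prefix "Y35.0".  Codes matching no prefix are
#' classified as undetermined with a warning.
#'
#' @param cause_code character vector of external-cause codes.
#' @param map prefix-to-intent table, default [default_intent_map()].
#' @return character vector of intent labels.
#' @examples
#' classify_intent(c("X93XXXA", "W33.01XA", "Y35.013A"))
#' @export
classify_intent <- function(cause_code, map = default_intent_map()) {
  map <- as.data.table(map)
  norm_code <- gsub(".", "", cause_code, fixed = TRUE)
  norm_pref <- gsub(".", "", map$prefix, fixed = TRUE)
  ord <- order(-nchar(norm_pref))  # longest prefix first
  norm_pref <- norm_pref[ord]
  labels <- map$intent[ord]
  out <- rep(NA_character_, length(cause_code))
  for (i in seq_along(norm_pref)) {
    hit <- is.na(out) & startsWith(norm_code, norm_pref[i])
    out[hit] <- labels[i]
  }
  if (anyNA(out)) {
    warning(sprintf("%d cause code(s) matched no intent prefix; classified as undetermined",
                    sum(is.na(out))), call. = FALSE)
    out[is.na(out)] <- "undetermined"
  }
  out
}

#' Assign a body-region label from the coded injury regions of one visit
#'
#' Exactly one distinct mapped region yields its label; two or more
#' distinct mapped regions yield "multiple regions"; no mappable region
#' yields "other".
#'
#' @param codes character vector of region codes for a single visit.
#' @param map code-to-region table, default [default_region_map()].
#' @return a single region label.
#' @examples
#' assign_body_region(c("CH", "UE"))
#' assign_body_region(c("UE", "LE"))  # both extremities -> one region
#' @export
assign_body_region <- function(codes, map = default_region_map()) {
  map <- as.data.table(map)
  regions <- unique(map$region[match(codes, map$code)])
  regions <- regions[!is.na(regions)]
  if (length(regions) == 0L) return("other")
  if (length(regions) == 1L) return(regions)
  "multiple regions"
}

## vectorized body-region assignment over semicolon-joined code strings
assign_body_region_batch <- function(region_strings, map = default_region_map()) {
  long <- parse_region_codes(region_strings)
  long[, region := map$region[match(code, map$code)]]
  agg <- long[!is.na(region), .(n_regions = uniqueN(region),
                                region = region[1L]), by = id]
  out <- rep("other", length(region_strings))
  out[agg$id] <- ifelse(agg$n_regions >= 2L, "multiple regions", agg$region)
  out
}

#' Injury Severity Score from AIS severities
#'
#' The strict ISS convention: take the highest AIS severity in each injured
#' body region, square the severities of the three most severely injured
#' distinct regions, and sum.  Any AIS of 6 (unsurvivable) forces the
#' maximum score of 75, and the score is capped at 75.  `mode = "sum"`
#' instead sums the squares of all coded severities (capped at 75), for
#' sensitivity analyses against the simpler squared-and-summed reading.
#'
#' @param severity integer AIS severities in 1-6, one per coded injury.
#' @param region body-region code per injury; defaults to each injury in
#'   its own region.  Ignored for `mode = "sum"`.
#' @param mode `"strict"` (default) or `"sum"`.
#' @return integer score in \[0, 75\]; 0 for an empty input.
#' @examples
#' compute_iss(c(5, 4, 3, 2), c("A", "B", "C", "D"))  # 25 + 16 + 9 = 50
#' @export
compute_iss <- function(severity, region = seq_along(severity),
                        mode = c("strict", "sum")) {
  mode <- match.arg(mode)
  if (length(severity) == 0L) return(0L)
  severity <- as.integer(severity)
  if (anyNA(severity) || any(severity < 1L) || any(severity > 6L))
    stopf("AIS severities must be integers in 1-6")
  if (mode == "sum") return(as.integer(min(75, sum(severity^2))))
  if (any(severity == 6L)) return(75L)
  per_region <- tapply(severity, as.character(region), max)
  top <- sort(as.integer(per_region), decreasing = TRUE)
  top <- top[seq_len(min(3L, length(top)))]
  as.integer(min(75, sum(top^2)))
}

## vectorized ISS over semicolon-joined "region:severity" strings
compute_iss_batch <- function(ais_strings, mode = "strict") {
  long <- parse_ais_codes(ais_strings)
  if (anyNA(long$severity) || (nrow(long) &&
        (min(long$severity) < 1L || max(long$severity) > 6L)))
    stopf("AIS severities must be integers in 1-6")
  out <- integer(length(ais_strings))
  if (!nrow(long)) return(out)
  if (mode == "sum") {
    agg <- long[, .(iss = as.integer(min(75, sum(severity^2)))), by = id]
  } else {
    per_region <- long[, .(severity = max(severity)), by = .(id, region)]
    setorder(per_region, id, -severity)
    per_region[, n_in_group := seq_len(.N), by = id]
    agg <- per_region[n_in_group <= 3L,
                      .(iss = as.integer(min(75, sum(severity^2))),
                        any6 = any(severity == 6L)), by = id]
    agg[any6 == TRUE, iss := 75L]
  }
  out[agg$id] <- agg$iss
  out
}

#' Categorize an Injury Severity Score
#'
#' Mild: 0-8; serious: 9-25; severe: 26-75 (boundaries inclusive).
#'
#' @param score integer vector in \[0, 75\].
#' @return character vector of categories.
#' @export
categorize_iss <- function(score) {
  if (anyNA(score) || any(score < 0) || any(score > 75))
    stopf("ISS must lie in [0, 75]")
  c("mild", "serious", "severe")[findInterval(score, c(0, 9, 26))]
}

#' Categorize a comorbidity count as 0, 1, 2 or >=3
#'
#' @param count non-negative integer vector.
#' @return character vector in `{"0", "1", "2", ">=3"}`.
#' @export
categorize_comorbidity <- function(count) {
  if (anyNA(count) || any(count < 0))
    stopf("comorbidity count must be non-negative")
  ifelse(count >= 3, ">=3", as.character(as.integer(count)))
}

#' Flag within-calendar-year reinjury
#'
#' All visits of a (person, calendar year) group with two or more
#' new-injury visits are flagged ">=1"; person linkage never crosses
#' calendar years, so one visit in each of two years is not a reinjury.
#' The result is invariant to row order.
#'
#' @param visits table with `person_link` and `year` columns.
#' @return character vector (`"0"` / `">=1"`) aligned with the input rows.
#' @export
flag_reinjury <- function(visits) {
  visits <- as.data.table(visits)
  grp <- data.table(person_link = visits$person_link, year = visits$year)
  grp[, n_in_group := .N, by = .(person_link, year)]
  ifelse(grp$n_in_group >= 2L, ">=1", "0")
}

#' Quartile thresholds by inclusive linear interpolation
#'
#' The 25th, 50th and 75th percentiles of `values` under the inclusive
#' linear-interpolation definition ([stats::quantile()] type 7).  Values
#' are assigned with a lower-inclusive rule: `x <= q1` is Q1, `x <= q2`
#' Q2, `x <= q3` Q3, else Q4 (ties go to the lower quartile).
#'
#' @param values numeric vector with at least 4 finite values.
#' @return named numeric vector `c(q1, q2, q3)`.
#' @examples
#' compute_quartile_thresholds(1:8)  # 2.75 4.50 6.25
#' @export
compute_quartile_thresholds <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4L)
    stopf("quartile thresholds need at least 4 finite values")
  q <- quantile(values, probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  if (is.unsorted(q)) stopf("internal: unsorted quartile thresholds")
  c(q1 = q[1L], q2 = q[2L], q3 = q[3L])
}

#' @rdname compute_quartile_thresholds
#' @param x numeric vector to assign.
#' @param thresholds output of `compute_quartile_thresholds()`.
#' @return `assign_quartile()`: character vector in `{"Q1",...,"Q4"}` with
#'   `NA` for missing values.
#' @export
assign_quartile <- function(x, thresholds) {
  out <- rep(NA_character_, length(x))
  ok <- is.finite(x)
  out[ok] <- ifelse(x[ok] <= thresholds[1L], "Q1",
             ifelse(x[ok] <= thresholds[2L], "Q2",
             ifelse(x[ok] <= thresholds[3L], "Q3", "Q4")))
  out
}

#' Derive all clinical and visit-level variables
#'
#' Appends to a costed visits table: `intent`, `body_region`, `iss`,
#' `iss_category`, `comorbidity_category` and `reinjury_flag`.  For states
#' whose payer dialect records no-charge visits as self-pay, the payer is
#' recoded accordingly.
#'
#' @param visits costed visits table (see [apply_cost_model()]).
#' @param intent_map,region_map lookup tables; see [default_intent_map()]
#'   and [default_region_map()].
#' @param iss_mode `"strict"` or `"sum"`, see [compute_iss()].
#' @param no_charge_as_self_pay_states states for which payer "no-charge"
#'   is recoded to "self-pay".
#' @return the visits table with derived columns appended.
#' @export
derive_clinical <- function(visits,
                            intent_map = default_intent_map(),
                            region_map = default_region_map(),
                            iss_mode = "strict",
                            no_charge_as_self_pay_states = character(0)) {
  v <- as.data.table(visits)
  v[, intent := classify_intent(cause_code, intent_map)]
  v[, body_region := assign_body_region_batch(diagnosis_region_codes, region_map)]
  v[, iss := compute_iss_batch(ais_codes, iss_mode)]
  v[, iss_category := categorize_iss(iss)]
  v[, comorbidity_category := categorize_comorbidity(comorbidity_count)]
  v[, reinjury_flag := flag_reinjury(v)]
  if (length(no_charge_as_self_pay_states)) {
    v[state %in% no_charge_as_self_pay_states & payer == "no-charge",
      payer := "self-pay"]
  }
  v[]
}
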