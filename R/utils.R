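## Internal helpers shared across the pipeline.

#' Round half away from zero ("half-up" for non-negative input)
#'
#' Used for converting fractional resampling targets (inpatient target times
#' ED:inpatient ratio) into integer draw counts.  Unlike [base::round()],
#' 0.5 always rounds up, so target counts are deterministic and do not
#' depend on banker's rounding.
#'
#' @param x numeric vector, assumed non-negative in pipeline use.
#' @return numeric vector of whole numbers.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.4))
#' @export
round_half_up <- function(x) {
  floor(x + 0.5)
}

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Derive one reproducible child seed per simulation index from the master
## seed.  The whole vector is generated up front from the master seed alone,
## so child k is a pure function of (master_seed, k) regardless of execution
## order; simulations can run in any order or in parallel.
derive_child_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## semicolon-joined "region:severity" pairs <-> long table ------------------

## Parse per-visit AIS strings ("EX:3;AB:4") into a long data.table with one
## row per coded injury.  `id` indexes the originating visit.
parse_ais_codes <- function(ais_strings) {
  parts <- strsplit(ais_strings, ";", fixed = TRUE)
  n_per <- lengths(parts)
  flat <- unlist(parts, use.names = FALSE)
  if (is.null(flat)) flat <- character(0)
  keep <- nzchar(flat)
  id <- rep.int(seq_along(ais_strings), n_per)[keep]
  flat <- flat[keep]
  region <- sub(":.*$", "", flat)
  severity <- suppressWarnings(as.integer(sub("^.*:", "", flat)))
  data.table(id = id, region = region, severity = severity)
}

parse_region_codes <- function(region_strings) {
  parts <- strsplit(region_strings, ";", fixed = TRUE)
  n_per <- lengths(parts)
  flat <- unlist(parts, use.names = FALSE)
  if (is.null(flat)) flat <- character(0)
  keep <- nzchar(flat)
  data.table(id = rep.int(seq_along(region_strings), n_per)[keep],
             code = flat[keep])
}

## categorical sampler from a named probability vector; names ending in
## "missing" emit NA
sample_categorical <- function(n, probs) {
  stopifnot(abs(sum(probs) - 1) < 1e-9)
  lev <- names(probs)
  out <- sample(lev, n, replace = TRUE, prob = probs)
  out[out == "missing"] <- NA_character_
  out
}
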