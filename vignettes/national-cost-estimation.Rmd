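---
title: "Estimating national firearm-injury hospital costs by Monte Carlo resampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating national firearm-injury hospital costs by Monte Carlo resampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firearmcost)
library(data.table)
```

## The estimation problem

Visit-level hospital claims with billed charges exist, in public-use form,
only for a handful of states: state inpatient databases (SID) hold
admissions, and state emergency-department databases (SEDD) hold
treat-and-release ED visits.  The two are mutually exclusive by
construction — a patient admitted through the ED appears once, as an
inpatient.  To estimate a *national* cost of new firearm injuries from a
six-state sample, this package implements a Monte Carlo resampling
extrapolation: external state-year estimates of inpatient firearm-injury
admissions in the 44 non-sample states serve as targets, and sample-state
visits are resampled, with replacement, to fill them.

Each simulation, independently for every calendar year:

1. draws a pure random sample, with replacement, of inpatient visits from
   the pooled sample states, of size equal to the summed non-sample
   inpatient targets for that year;
2. draws an analogous ED-only sample, sized per non-sample state as the
   state's inpatient target times the ratio of ED-only visits to
   inpatient admissions in the pooled sample states that year (rounded
   half-up), then summed;
3. combines the resampled rows with the original sample-state rows into a
   national annual sample and tallies stratified costs and counts.

Cost estimates are arithmetic means across simulations; the simulation
standard error is the across-simulation standard deviation.  Because the
same quantity could also be read as the standard error of the
across-simulation mean, `aggregate_simulations()` emits both
(`se_total` and `se_mean_total`), with the across-simulation SD as the
headline.

### The cost model

A visit's cost is not its charge.  Billed charges are converted with the
hospital- and year-specific cost-to-charge ratio (CCR),

$$\text{cost}_{i} = \text{charge}_{i} \times \text{CCR}_{h(i),\,y(i)},$$

and expressed in base-year (2024) dollars with an annual consumer price
index, $\text{cost}^{2024}_{i} = \text{cost}_{i} \times I_{2024}/I_{y(i)}$.
Two inclusion rules are applied first: only new-injury encounters (cause
code ending in "A") enter, and visits with a missing charge are excluded.
Both filters count what they drop rather than failing, because excluded
counts are themselves a reported quantity.  CCRs outside $(0, 1.5]$ are
rejected: ratios above 1 occur legitimately in real hospital files, but
far larger values indicate corrupt entries.

### Derived clinical variables

* **Intent** by longest-prefix match of the external-cause code against a
  configurable table (shipped default: W32–W34 unintentional, X72–X74
  self-inflicted, X93–X95 assault, Y22–Y24 undetermined, Y35.0 legal
  intervention).  The map is data, not code, because the exact code
  inventory differs between studies; unmatched codes fall back to
  "undetermined" with a warning.
* **Body region** from the coded injury regions: one distinct mapped
  region keeps its label, two or more become "multiple regions", none
  mappable becomes "other".
* **ISS** under the strict convention: the highest AIS severity per
  region, squared and summed over the three most severely injured
  distinct regions, capped at 75, with any AIS 6 forcing 75.  The
  literature sometimes describes ISS loosely as "squared and summed"
  AIS; a plain squared-sum variant is available behind
  `compute_iss(mode = "sum")` for sensitivity analysis, but the strict
  top-three rule is the default and is validated in the test suite
  against a brute-force subset-maximization oracle.
* **Reinjury**: all visits of a person with two or more new-injury visits
  in the same calendar year are flagged.  Person linkage deliberately
  never crosses calendar years — the linkage identifier in the emulated
  databases resets yearly — so reinjury is biased downward by
  construction, as in the source data.
* **Comorbidity** counts (an input, standing in for a weighted Elixhauser
  index computed upstream) are binned 0 / 1 / 2 / ≥3.

### Hospital quartile stratifiers

Hospital Medicaid-discharge share, total admissions and total ED volume
are reported in ascending quartiles whose thresholds are recomputed
*within every simulation* from the realized national sample.  This means
hospitals are weighted by their visit multiplicity after resampling — a
hospital drawn often influences the cut points more — which is the
reading most consistent with per-simulation threshold recomputation.
Thresholds use the inclusive linear-interpolation percentile definition
(`quantile(type = 7)`), and boundary ties go to the lower quartile so the
assignment is deterministic.

## The synthetic claims generator

The generator emulates the statistical structure of SID/SEDD claims
linked to hospital survey attributes, with known ground truth, so every
downstream stage runs and is testable without restricted-access data.
Its defaults define the study conditions:

| parameter | default | rationale |
|---|---|---|
| states | 6 sample + 44 non-sample | the sample/non-sample split of the design |
| years | 2016–2021 | the study period |
| visits per state-year | 2500 (mean, Poisson) | ≈90 000 sample visits over the grid, matching the observed sample's order of magnitude |
| ED:inpatient ratio | 1.61 | the national ED-to-admission visit ratio implied by the published counts |
| charge law | log-normal, meanlog 8.3 (ED) / 11.2 (inpatient), sdlog 0.8 / 1.0 | hospital charges are strongly right-skewed; parameters chosen so mean costs after CCR and inflation land near published per-visit means |
| missing-charge rate | 0.17 | the published excluded fraction (15 193 of ≈89 800) |
| reinjury rate | 0.05 | within-year reinjured-person fraction; modest, consistent with a downward-biased yearly linkage |
| CCR | uniform 0.2–0.5 per hospital-year | the typical range of hospital cost-to-charge ratios |
| CPI | annual all-items CPI-U averages, base 2024 | annual conversion to a base year |

Patient stratifiers are sampled independently of one another with
marginals loosely matched to published visit profiles; the joint
distribution (e.g. payer × income quartile) is not modelled, so passing
tests demonstrate correct *machinery*, not realistic cross-tabulations.
Within a state-year, a fraction $r$ of persons receives two visits: with
$m = \operatorname{round}(rn/(1+r))$ paired persons among $n$ visits, the
reinjured-person fraction is exactly $m/(n-m) \approx r$.  Person ids
never span states, mirroring state-internal linkage.

Ground truth records, per (state, year, visit type), the true visit count
and true base-year cost over visits with a non-missing charge — the same
exclusion the pipeline applies.  In "consistent" target mode the
non-sample inpatient targets equal the ground-truth counts, so the
estimator's recovery of a known national total is directly checkable; in
"external" mode targets are drawn independently, emulating a genuinely
external source.

## What validates the estimator

With-replacement resampling has closed-form moments: if $T$ rows are
drawn from a pool with mean cost $\mu$ and variance $\sigma^2$, the
resampled total has expectation $T\mu$ and variance $T\sigma^2$.  The
test suite runs 200 simulations on a ≈50 000-visit synthetic sample and
checks, per year, that the Monte Carlo mean of the resampled inpatient
total lies within four standard errors of $T\mu$ and that the
across-simulation SD is within ±25% of $\sqrt{T\sigma^2}$.  Exact
invariants are checked everywhere they exist: count conservation
(national count = sample count + targets, in every simulation), the
zero-target limit (all simulations identical, all SEs exactly zero),
seed determinism, and agreement of stratified tallies with brute-force
enumeration on a hand-built fixture.

Arithmetic identities over the published national estimates (shipped as
a typed-in fixture) close the loop at the reporting end: visit counts
sum to the published national total, the inpatient share of total cost
rounds to 93%, the reinjury share to 9%, and the overall ED total
divided by the ED visit count reproduces the published mean ED cost.

## Numerical and design choices

* **Resampling unit is the visit**, not the person: the procedure
  resamples "admissions" and "ED visits", i.e. rows.
* **Per-state draws**: non-sample states are resampled state by state
  rather than as a yearly sum.  The yearly totals are identical in
  distribution, but per-state draws keep per-state outputs possible.
* **ED ratio scope**: the ED:inpatient ratio is computed per year from
  the pooled sample states, matching the per-year cadence of the
  inpatient step.
* **Donor attributes**: resampled visits inherit the donor's hospital
  attributes, since no hospital data exist for non-sample states but
  hospital-level tables must still be computable.
* **Child seeds** are pre-generated as a vector from the master seed, so
  simulation $k$'s seed is a pure function of (master seed, $k$) and
  execution order is irrelevant.
* **Rounding**: ED targets round half-up (never banker's rounding), so
  target counts are deterministic integers.
* **Per-visit means** are computed within each simulation as
  total/count and then averaged across simulations — not as the ratio of
  the means — because a mean and an SE per visit are reported across
  simulations.  Simulations where a cell is empty contribute nothing and
  are counted in `n_sims_nonzero`.
* **Medians** are computed on the pooled per-visit cost distribution of
  a designated reference simulation's national sample (original plus
  resampled rows), since the interaction of medians with resampling
  admits several readings; the reference simulation is fixed by its
  child seed.
* **Missing stratifier values** accumulate into a reserved "missing"
  level, so printed categories need not sum to the overall total — the
  overall row is always tallied directly, never as a sum of categories.
* **Currency** is carried as real-valued dollars; CCR and CPI products
  are non-integral, so downstream comparisons are tolerance-based.

## Problem sizes

The default generator grid (50 states × 6 years × 2500 mean visits) is
used for full-scale runs.  The test suite and the acceptance script use
a reduced grid — 1400 mean visits per state-year, giving ≈50 000
sample-state visits and ≈420 000 generated visits overall — with 200
simulations for the statistical oracles; property tests use still
smaller studies (two sample states, a few hundred visits).  These sizes
were chosen so the oracle bounds are sharp (analytic SEs small relative
to the quantities checked) while the whole suite runs in minutes.

## Limitations

The generator emulates marginal structure only: stratifiers are
independent, charges are log-normal within visit type, and hospital
attributes are drawn independently of each other and of case mix.  Real
claims have correlated demographics, payer–severity gradients, and
hospital case-mix effects, so synthetic results validate the estimator's
correctness, not any substantive cost finding.  The cost perspective
excludes professional fees, transport, trauma activation fees,
readmissions and post-acute care; no imputation is attempted for missing
charges; and uncertainty in the external inpatient targets themselves is
not propagated — the simulation SE reflects resampling variation only.
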