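Package: firearmcost
Title: National Hospital Cost Estimation for Firearm Injury Visits by
    Monte Carlo Resampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates national emergency department and inpatient hospital
    costs of new firearm injuries from state-level administrative claims.
    Visit charges are converted to hospital costs with hospital- and
    year-specific cost-to-charge ratios and inflation-adjusted to a base
    year with Consumer Price Index data.  Sample-state visits are
    extrapolated to non-sample states by repeated with-replacement
    resampling against external state-year inpatient admission targets,
    and stratified totals, per-visit means and simulation standard errors
    are aggregated across simulations.  A synthetic claims generator with
    known ground truth emulates the structure of state inpatient and
    emergency department databases so the whole pipeline runs and is
    testable without restricted-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
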