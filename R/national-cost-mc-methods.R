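## S3 methods for the fitted Monte Carlo estimator.

#' @export
print.national_cost_mc <- function(x, ...) {
  cat("National cost estimate by Monte Carlo resampling\n")
  cat(sprintf("  %d simulations, master seed %d, years %d-%d\n",
              x$n_sims, x$seed, min(x$years), max(x$years)))
  ov <- x$results[stratifier == "overall",
                  .(mean_total = mean(total_cost), se = sd(total_cost),
                    mean_count = mean(n_visits)), by = visit_type]
  for (i in seq_len(nrow(ov))) {
    cat(sprintf("  %-10s total $%.1fM (SE %.1f), mean visits %.0f\n",
                ov$visit_type[i], ov$mean_total[i] / 1e6,
                ifelse(is.na(ov$se[i]), 0, ov$se[i]) / 1e6,
                ov$mean_count[i]))
  }
  invisible(x)
}

#' Summarize a fitted national cost estimator
#'
#' @param object a [national_cost_mc()] fit.
#' @param ... unused.
#' @return the [aggregate_simulations()] table (class `cost_aggregate`).
#' @export
summary.national_cost_mc <- function(object, ...) {
  aggregate_simulations(object)
}

#' @export
print.cost_aggregate <- function(x, ...) {
  n_sims <- attr(x, "n_sims")
  cat(sprintf("Aggregated cost estimates over %s simulations (%d cells)\n",
              ifelse(is.null(n_sims), "?", n_sims), nrow(x)))
  ov <- if (all(c("stratifier", "visit_type", "mean_total", "se_total",
                  "mean_per_visit") %in% names(x)))
    x[stratifier == "overall"] else x[0]
  if (nrow(ov)) {
    cat("Overall (totals in millions of base-year dollars):\n")
    for (i in seq_len(nrow(ov)))
      cat(sprintf("  %-10s total %.1f (SE %.2f); per-visit mean $%.0f\n",
                  ov$visit_type[i], ov$mean_total[i] / 1e6,
                  ov$se_total[i] / 1e6,
                  ifelse(is.na(ov$mean_per_visit[i]), NA,
                         ov$mean_per_visit[i])))
  }
  NextMethod()
  invisible(x)
}

#' Plot annual total-cost trends of a fitted estimator
#'
#' Base-graphics line plot of the mean annual total cost (millions of
#' base-year dollars) by visit type, the analogue of the study's annual
#' trend figure.
#'
#' @param x a [national_cost_mc()] fit (must include the `year`
#'   stratifier).
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the trend table plotted.
#' @export
plot.national_cost_mc <- function(x, ...) {
  tr <- trend_table(x, by = "visit_type")
  wide <- dcast(tr, year ~ group, value.var = "mean_total")
  grp_cols <- setdiff(names(wide), "year")
  graphics::matplot(wide$year, as.matrix(wide[, ..grp_cols]) / 1e6,
                    type = "b", pch = 19, lty = 1,
                    xlab = "Year", ylab = "Total cost (millions, base-year $)",
                    ...)
  graphics::legend("topleft", legend = grp_cols, col = seq_along(grp_cols),
                   pch = 19, lty = 1, bty = "n")
  invisible(tr)
}
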