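## Direct healthcare-cost accounting and ratio-based indirect costs.
##
## Costing is prevalence-based: every obesity-related prevalent case-year
## accrues the disease's annual unit cost. No discounting by default (a
## discount-rate knob exists); report tables round to 3 significant
## figures while full precision is kept internally.

#' Annual direct healthcare costs from a tally
#'
#' `cost(disease, year)` = obesity-related prevalent cases at
#' whole-population scale x annual unit cost, in euro millions.
#'
#' @param tally an `annual_tally` that has been through
#'   [obesity_attributable_tally()].
#' @param unit_costs named vector of euro per prevalent case per year; one
#'   entry per tallied disease.
#' @param discount_rate annual discount rate applied from the first tally
#'   year (default 0 - costs by calendar year, undiscounted).
#' @return object of class `cost_table`: `by_disease` (scenario, year,
#'   disease, cost_millions) and `totals` (scenario, year,
#'   total_millions).
#' @export
annual_direct_costs <- function(tally, unit_costs, discount_rate = 0) {
  stopifnot(inherits(tally, "annual_tally"))
  bd <- tally$by_disease
  if (!"prevalent_attrib" %in% names(bd)) {
    stop("tally lacks obesity-attributable columns; run ",
         "obesity_attributable_tally() first")
  }
  missing <- setdiff(unique(bd$disease), names(unit_costs))
  if (length(missing) > 0) {
    stop("missing unit cost for disease: ", paste(missing, collapse = ", "))
  }
  disc <- (1 + discount_rate)^-(bd$year - min(bd$year))
  cost <- bd$prevalent_attrib * tally$scale *
    unname(unit_costs[bd$disease]) * disc / 1e6
  by_disease <- data.frame(scenario = bd$scenario, year = bd$year,
                           disease = bd$disease, cost_millions = cost)
  totals <- stats::aggregate(cost_millions ~ scenario + year, by_disease, sum)
  names(totals)[3] <- "total_millions"
  structure(list(by_disease = by_disease, totals = totals,
                 seed = tally$seed, n_initial = tally$n_initial,
                 years = tally$years, scenario = tally$scenario),
            class = "cost_table")
}

#' @export
print.cost_table <- function(x, ...) {
  cat("Direct healthcare costs (EUR millions), scenario",
      x$scenario$id, "\n")
  t <- x$totals
  t$total_millions <- signif(t$total_millions, 3)
  print(utils::tail(t, 5), row.names = FALSE)
  invisible(x)
}

#' Report-style cost table (3 significant figures)
#'
#' @param costs a `cost_table`.
#' @return wide data.frame, diseases x years, rounded like a publication
#'   table; full precision stays in the `cost_table`.
#' @export
format_cost_table <- function(costs) {
  bd <- costs$by_disease
  wide <- stats::reshape(bd[, c("year", "disease", "cost_millions")],
                         idvar = "disease", timevar = "year",
                         direction = "wide")
  names(wide) <- sub("cost_millions.", "", names(wide), fixed = TRUE)
  num <- names(wide) != "disease"
  wide[num] <- lapply(wide[num], signif, digits = 3)
  tot <- c(disease = "total",
           lapply(wide[num], function(v) signif(sum(v), 3)))
  rbind(wide, tot)
}

#' Cost savings of an intervention scenario
#'
#' @param costs_0 baseline `cost_table`.
#' @param costs_k intervention `cost_table` from a common-random-numbers
#'   run (same seed, size and years).
#' @return data.frame `year, savings_millions` of total direct-cost
#'   differences (baseline minus intervention).
#' @export
cost_savings <- function(costs_0, costs_k) {
  if (!identical(costs_0$seed, costs_k$seed) ||
      !identical(costs_0$n_initial, costs_k$n_initial) ||
      !identical(costs_0$years, costs_k$years)) {
    stop("cost tables are not comparable: runs must share seed, n and years")
  }
  t0 <- costs_0$totals
  tk <- costs_k$totals
  m <- match(t0$year, tk$year)
  data.frame(year = t0$year,
             savings_millions = t0$total_millions - tk$total_millions[m])
}

#' Indirect costs from a published direct:indirect ratio
#'
#' Scales direct healthcare costs by the ratio of published indirect to
#' direct obesity costs. Defaults are the Irish 2009 estimates of EUR 399
#' million direct and EUR 729 million indirect.
#'
#' @param direct direct costs in euro millions (vectorised).
#' @param ratio_numerator published indirect costs (EUR millions).
#' @param ratio_denominator published direct costs (EUR millions, > 0).
#' @return indirect cost estimate in euro millions.
#' @export
indirect_from_ratio <- function(direct, ratio_numerator = 729,
                                ratio_denominator = 399) {
  assert_that(ratio_denominator > 0, "ratio denominator must be positive")
  direct * ratio_numerator / ratio_denominator
}
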