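## Intervention scenarios, obesity attribution (PAF) and cases avoided.

#' Define an intervention scenario
#'
#' Scenario 0: obesity trends continue unabated (multiplier 1). Scenario 1:
#' population BMI reduced by 1% (multiplier 0.99). Scenario 2: population
#' BMI reduced by 5% (multiplier 0.95). The reduction is a multiplicative
#' shift of each individual's continuous BMI from the start year onward.
#'
#' @param id scenario id in 0, 1, 2 (other ids allowed for custom runs).
#' @param bmi_multiplier multiplier in (0, 1\]; defaults to the standard
#'   multiplier for ids 0-2.
#' @param start_year first year the multiplier applies.
#' @return object of class `scenario_def`.
#' @export
scenario_def <- function(id, bmi_multiplier = NULL, start_year = -Inf) {
  if (is.null(bmi_multiplier)) {
    std <- c(`0` = 1.00, `1` = 0.99, `2` = 0.95)
    if (!as.character(id) %in% names(std)) {
      stop("no standard multiplier for scenario id ", id,
           "; supply bmi_multiplier")
    }
    bmi_multiplier <- std[[as.character(id)]]
  }
  assert_that(bmi_multiplier > 0 && bmi_multiplier <= 1,
              "multiplier must be in (0, 1]")
  if (id == 0) assert_that(bmi_multiplier == 1,
                           "scenario 0 must have multiplier 1")
  structure(list(id = id, bmi_multiplier = bmi_multiplier,
                 start_year = start_year),
            class = "scenario_def")
}

#' Apply a scenario's BMI reduction to continuous BMI values
#'
#' @param bmi latent continuous BMI values (kg/m^2).
#' @param scenario a [scenario_def()].
#' @param year calendar year; the multiplier applies only from the
#'   scenario's start year.
#' @return list with adjusted `bmi` and re-derived `category` labels.
#' @export
apply_scenario <- function(bmi, scenario, year) {
  mult <- if (year >= scenario$start_year) scenario$bmi_multiplier else 1
  adj <- bmi * mult
  list(bmi = adj, category = bmi_category(adj))
}

#' Population attributable fraction (Levin formula)
#'
#' `PAF = (sum_k p_k RR_k - 1) / (sum_k p_k RR_k)` with normal weight as
#' the reference category. Converts total-population disease tallies into
#' the obesity-related share.
#'
#' @param p_cat length-3 category proportions (summing to 1) or a matrix
#'   with 3 columns.
#' @param rr length-3 relative risks `(1, RR_overweight, RR_obese)`.
#' @return PAF value(s) in \[0, 1) when all RR >= 1.
#' @export
attributable_fraction <- function(p_cat, rr) {
  rr <- unname(rr)
  assert_that(all(rr >= 0), "relative risks must be >= 0")
  assert_that(length(rr) == 3 && rr[1] == 1, "rr must be (1, RR_ow, RR_ob)")
  p <- if (is.matrix(p_cat)) p_cat else matrix(p_cat, ncol = 3)
  assert_that(all(abs(rowSums(p) - 1) < 1e-6), "proportions must sum to 1")
  s <- drop(p %*% rr)
  (s - 1) / s
}

#' Convert a total-population tally into obesity-related outputs
#'
#' Applies the year-specific PAF (from the realised BMI category shares of
#' the simulated population and each disease's relative risks) to the
#' prevalence and cumulative-incidence columns of an [annual_tally].
#'
#' @param tally an `annual_tally`.
#' @param diseases the disease definitions or `disease_hazards` carrying
#'   the relative risks.
#' @return the tally with added columns `paf`, `prevalent_attrib`,
#'   `prevalent_attrib_per_100k`, `cum_incidence_attrib`,
#'   `cum_incidence_attrib_per_100k` in `by_disease`.
#' @export
obesity_attributable_tally <- function(tally, diseases) {
  stopifnot(inherits(tally, "annual_tally"))
  rr_list <- lapply(diseases, `[[`, "rr")
  names(rr_list) <- vapply(diseases, `[[`, "", "name")
  bd <- tally$by_disease
  by <- tally$by_year
  shares <- as.matrix(by[match(bd$year, by$year),
                         c("p_normal", "p_overweight", "p_obese")])
  paf <- numeric(nrow(bd))
  for (nm in unique(bd$disease)) {
    sel <- bd$disease == nm
    paf[sel] <- attributable_fraction(shares[sel, , drop = FALSE],
                                      rr_list[[nm]])
  }
  bd$paf <- paf
  bd$prevalent_attrib <- bd$prevalent * paf
  bd$prevalent_attrib_per_100k <- bd$prevalent_per_100k * paf
  bd$cum_incidence_attrib <- bd$cum_incidence * paf
  bd$cum_incidence_attrib_per_100k <- bd$cum_incidence_per_100k * paf
  tally$by_disease <- bd
  tally
}

.check_comparable <- function(t0, tk) {
  if (!identical(t0$seed, tk$seed) || !identical(t0$n_initial, tk$n_initial)
      || !identical(t0$years, tk$years)) {
    stop("tallies are not comparable: runs must share seed, n and years")
  }
}

#' Cumulative incident cases avoided relative to the baseline scenario
#'
#' Both tallies must come from runs sharing seed, size and years (common
#' random numbers), so the difference isolates the intervention effect.
#'
#' @param tally_0 baseline (scenario 0) `annual_tally`.
#' @param tally_k intervention `annual_tally`.
#' @param attributed use obesity-attributable columns if present.
#' @return data.frame per (year, disease): `avoided_per_100k` (cumulative
#'   incidence per 100,000 of the start population) and `avoided_total`
#'   (whole-population counts via the population scale factor).
#' @export
cases_avoided <- function(tally_0, tally_k, attributed = FALSE) {
  .check_comparable(tally_0, tally_k)
  col <- if (attributed) "cum_incidence_attrib_per_100k" else
    "cum_incidence_per_100k"
  raw <- if (attributed) "cum_incidence_attrib" else "cum_incidence"
  b0 <- tally_0$by_disease
  bk <- tally_k$by_disease
  key0 <- paste(b0$year, b0$disease)
  keyk <- paste(bk$year, bk$disease)
  m <- match(key0, keyk)
  data.frame(year = b0$year, disease = b0$disease,
             scenario = tally_k$scenario$id,
             avoided_per_100k = b0[[col]] - bk[[col]][m],
             avoided_total = (b0[[raw]] - bk[[raw]][m]) * tally_0$scale)
}

#' Run a set of scenarios under common random numbers
#'
#' @param cfg a [sim_config()].
#' @param dist,hazards,population,mortality as in [run_simulation()].
#' @param scenario_ids integer ids (default 0, 1, 2).
#' @param scenario_start first year the BMI reduction applies (default:
#'   the simulation start year).
#' @param attribute apply [obesity_attributable_tally()] to each run.
#' @return named list of `annual_tally` objects (`"scenario_0"` etc.).
#' @export
run_scenarios <- function(cfg, dist, hazards, population, mortality,
                          scenario_ids = 0:2,
                          scenario_start = cfg$start_year,
                          attribute = TRUE) {
  out <- lapply(scenario_ids, function(k) {
    sc <- scenario_def(k, start_year = scenario_start)
    t <- run_simulation(cfg, dist, hazards, population, mortality, sc)
    if (attribute) t <- obesity_attributable_tally(t, hazards)
    t
  })
  names(out) <- paste0("scenario_", scenario_ids)
  out
}
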