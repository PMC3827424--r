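#' Specification for the synthetic-data generator
#'
#' Defines the "truth" from which synthetic survey series, population
#' structures and disease tables are drawn: a three-category multinomial
#' logit in calendar year with additive age-group offsets per sex (the
#' simplest model consistent with a constrained categorical trend
#' regression), a population age structure, all-cause mortality hazards and
#' a set of chronic-disease definitions. Defaults emulate an Irish-style
#' adult survey series: sparse survey years, multinomial sampling noise and
#' a rising obesity trend.
#'
#' @param seed integer master seed; per-purpose streams are derived from it
#'   with [derive_seed()].
#' @param survey_years calendar years with a cross-sectional survey
#'   (at least 2).
#' @param age_groups data.frame from [make_age_groups()].
#' @param trend per-sex list of logit-scale truth parameters; each sex has
#'   `intercept` and `slope` (length-2, overweight and obese logits vs the
#'   normal-weight reference, per-year units, year centred at `year_ref`)
#'   and `age_offsets` (length `nrow(age_groups)`, first entry 0, added to
#'   both non-reference logits).
#' @param year_ref centring year for the trend (default 2010).
#' @param n_per_cell survey sample size per (year, sex, age-group) cell.
#' @param population data.frame `sex, age, count` for single-year ages.
#' @param mortality data.frame `sex, age, hazard` all-cause mortality
#'   (per person-year).
#' @param diseases list of [disease_definition()] objects.
#' @return an object of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1L,
                           survey_years = c(1998, 2001, 2002, 2007, 2011),
                           age_groups = default_age_groups(),
                           trend = default_bmi_trend(),
                           year_ref = 2010,
                           n_per_cell = 1200L,
                           population = default_population(),
                           mortality = default_mortality(),
                           diseases = default_diseases()) {
  assert_that(n_per_cell >= 1, "sample sizes must be >= 1")
  assert_that(all(mortality$hazard >= 0), "mortality hazards must be >= 0")
  assert_that(all(population$count >= 0), "population counts must be >= 0")
  for (s in SEXES) {
    tr <- trend[[s]]
    assert_that(length(tr$intercept) == 2 && length(tr$slope) == 2,
                "trend needs length-2 intercept and slope per sex")
    assert_that(length(tr$age_offsets) == nrow(age_groups),
                "one age offset per age group required")
  }
  structure(list(seed = as.integer(seed), survey_years = sort(survey_years),
                 age_groups = age_groups, trend = trend, year_ref = year_ref,
                 n_per_cell = as.integer(n_per_cell), population = population,
                 mortality = mortality, diseases = diseases),
            class = "generator_spec")
}

#' @export
print.generator_spec <- function(x, ...) {
  cat("Synthetic-data generator spec\n")
  cat("  survey years:", paste(x$survey_years, collapse = ", "), "\n")
  cat("  age groups:  ", paste(x$age_groups$label, collapse = ", "), "\n")
  cat("  n per cell:  ", x$n_per_cell, "\n")
  cat("  diseases:    ", paste(vapply(x$diseases, `[[`, "", "name"),
                               collapse = ", "), "\n")
  cat("  seed:        ", x$seed, "\n")
  invisible(x)
}

#' Default adult age groups (decadal, 20+)
#' @return an age-group table; the oldest group is open-ended in practice
#'   (older ages are clamped into it).
#' @export
default_age_groups <- function() {
  make_age_groups(seq(20, 70, 10), seq(29, 79, 10))
}

#' Default BMI trend truth parameters
#'
#' Calibrated once (numerically, against the default population weights)
#' so the population-weighted 2010 adult marginals are 39/37/24% for males
#' and 43/33/24% for females (normal/overweight/obese) and the trend
#' carries overweight+obesity to 89% of males and 85% of females by 2030
#' (obesity 48% and 57%) - the shape of published Irish projections. Age
#' offsets put middle-aged and older groups at higher BMI than ages 20-29.
#' @return per-sex list of truth parameters.
#' @export
default_bmi_trend <- function() {
  offsets <- c(0, 0.35, 0.55, 0.70, 0.75, 0.60)
  list(
    male = list(intercept = c(overweight = -0.4788, obese = -0.9117),
                slope = c(overweight = 0.0695, obese = 0.0990),
                age_offsets = offsets),
    female = list(intercept = c(overweight = -0.6939, obese = -1.0123),
                  slope = c(overweight = 0.0455, obese = 0.0970),
                  age_offsets = offsets)
  )
}

#' Default synthetic adult population structure
#'
#' Roughly 3.4 million adults aged 20-100 split evenly by sex, with counts
#' declining smoothly in age and faster after 65.
#' @return data.frame `sex, age, count`.
#' @export
default_population <- function() {
  ages <- 20:100
  w <- exp(-0.015 * (ages - 20)) * exp(-0.055 * pmax(0, ages - 65))
  per_sex <- round(w / sum(w) * 1.7e6)
  do.call(rbind, lapply(SEXES, function(s) {
    data.frame(sex = s, age = ages, count = per_sex)
  }))
}

#' Default all-cause mortality hazards
#'
#' Gompertz-shaped hazards per person-year; males carry a 1.45x excess.
#' @return data.frame `sex, age, hazard`.
#' @export
default_mortality <- function() {
  ages <- 20:100
  base <- exp(-10.3 + 0.092 * ages)
  do.call(rbind, lapply(SEXES, function(s) {
    mult <- if (s == "male") 1.45 else 1.0
    data.frame(sex = s, age = ages, hazard = base * mult)
  }))
}

#' Define one chronic disease for the simulation
#'
#' @param name disease label.
#' @param fatal does the disease carry excess (case-fatality) mortality?
#' @param schedule_kind `"incidence"` (rates per person-year) or
#'   `"prevalence"` (proportions, to be converted to incidence by the
#'   illness-death equations before simulation).
#' @param schedule data.frame `sex, age, value` over single-year ages.
#' @param rr length-3 relative risks `(normal = 1, overweight, obese)` of
#'   incidence relative to normal weight.
#' @param case_fatality excess death hazard per person-year among prevalent
#'   cases (0 for non-fatal diseases); typically derived from n-year
#'   survival via [survival_to_excess_hazard()].
#' @param annual_unit_cost direct healthcare cost in euro per prevalent
#'   case per year.
#' @return an object of class `disease_definition`.
#' @export
disease_definition <- function(name, fatal, schedule_kind, schedule, rr,
                               case_fatality = 0, annual_unit_cost = 0) {
  schedule_kind <- match.arg(schedule_kind, c("incidence", "prevalence"))
  rr <- unname(rr)
  assert_that(length(rr) == 3 && rr[1] == 1, "rr must be (1, RR_ow, RR_ob)")
  assert_that(all(rr >= 0), "relative risks must be >= 0")
  assert_that(all(schedule$value >= 0), "rates/proportions must be >= 0")
  if (schedule_kind == "prevalence") {
    assert_that(all(schedule$value < 1), "prevalence must be in [0,1)")
  }
  assert_that(annual_unit_cost >= 0, "negative unit cost rejected")
  if (!fatal) assert_that(case_fatality == 0,
                          "non-fatal disease must have zero case fatality")
  structure(list(name = name, fatal = fatal, schedule_kind = schedule_kind,
                 needs_conversion = schedule_kind == "prevalence",
                 schedule = schedule,
                 rr = c(normal = 1, overweight = rr[2], obese = rr[3]),
                 case_fatality = case_fatality,
                 annual_unit_cost = annual_unit_cost),
            class = "disease_definition")
}

## helper: age-exponential schedule over both sexes
.age_schedule <- function(fun, male_mult = 1) {
  ages <- 20:100
  do.call(rbind, lapply(SEXES, function(s) {
    mult <- if (s == "male") male_mult else 1
    data.frame(sex = s, age = ages, value = pmin(fun(ages) * mult, 0.999))
  }))
}

#' Default disease set
#'
#' Five definitions covering the six modelled conditions (coronary heart
#' disease and stroke are pooled, as are the obesity-related cancer sites):
#' CHD & stroke and cancer enter as incidence with excess case fatality
#' from 5-year survival; hypertension, type 2 diabetes and knee
#' osteoarthritis enter as prevalence flagged for illness-death conversion.
#' Relative risks are typical published overweight/obese comorbidity risks;
#' unit costs are annual direct costs per prevalent case in euro.
#' @return list of `disease_definition` objects.
#' @export
default_diseases <- function() {
  list(
    disease_definition(
      "chd_stroke", fatal = TRUE, schedule_kind = "incidence",
      schedule = .age_schedule(function(a) 0.001 * exp(0.075 * (a - 40)),
                               male_mult = 1.3),
      rr = c(1, 1.35, 1.80),
      case_fatality = survival_to_excess_hazard(0.75, 5),
      annual_unit_cost = 9000),
    disease_definition(
      "cancer", fatal = TRUE, schedule_kind = "incidence",
      schedule = .age_schedule(function(a) 0.0004 * exp(0.07 * (a - 40))),
      rr = c(1, 1.12, 1.35),
      case_fatality = survival_to_excess_hazard(0.55, 5),
      annual_unit_cost = 700),
    disease_definition(
      "hypertension", fatal = FALSE, schedule_kind = "prevalence",
      schedule = .age_schedule(function(a) stats::plogis(-4.0 + 0.055 * a)),
      rr = c(1, 1.70, 2.60), annual_unit_cost = 300),
    disease_definition(
      "type2_diabetes", fatal = FALSE, schedule_kind = "prevalence",
      schedule = .age_schedule(function(a) stats::plogis(-6.5 + 0.07 * a)),
      rr = c(1, 2.40, 6.00), annual_unit_cost = 1600),
    disease_definition(
      "knee_osteoarthritis", fatal = FALSE, schedule_kind = "prevalence",
      schedule = .age_schedule(function(a) stats::plogis(-7.5 + 0.07 * a)),
      rr = c(1, 1.80, 3.50), annual_unit_cost = 900)
  )
}

#' True BMI category proportions under a generator spec
#'
#' @param spec a [generator_spec()].
#' @param year calendar year (vectorised).
#' @param sex `"male"` or `"female"`.
#' @param group_idx age-group row index (vectorised, recycled with `year`).
#' @return matrix with columns `normal`, `overweight`, `obese`.
#' @export
true_category_props <- function(spec, year, sex, group_idx) {
  tr <- spec$trend[[sex]]
  yc <- year - spec$year_ref
  off <- tr$age_offsets[group_idx]
  softmax3(tr$intercept[1] + tr$slope[1] * yc + off,
           tr$intercept[2] + tr$slope[2] * yc + off)
}

#' Generate a synthetic cross-sectional BMI survey series
#'
#' For every (survey year, sex, age group) the truth proportions are
#' produced by the spec's logit trends and the observed proportions drawn
#' as multinomial counts over the cell's sample size.
#'
#' @param spec a [generator_spec()]; must contain at least two distinct
#'   survey years (a single year leaves the trend unidentifiable).
#' @return data.frame with columns `year, sex, age_lo, age_hi, category,
#'   proportion, n` (three rows per cell) and attribute `truth` holding the
#'   noise-free proportions in the same layout.
#' @export
generate_survey_series <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (length(unique(spec$survey_years)) < 2) {
    stop("at least 2 distinct survey years required: trend unidentifiable")
  }
  set.seed(derive_seed(spec$seed, "survey"))
  grid <- expand.grid(g = seq_len(nrow(spec$age_groups)), sex = SEXES,
                      year = spec$survey_years, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    year <- grid$year[i]; sex <- grid$sex[i]; g <- grid$g[i]
    p <- true_category_props(spec, year, sex, g)[1, ]
    counts <- stats::rmultinom(1, spec$n_per_cell, p)[, 1]
    data.frame(year = year, sex = sex,
               age_lo = spec$age_groups$age_lo[g],
               age_hi = spec$age_groups$age_hi[g],
               category = BMI_CATEGORIES,
               proportion = counts / spec$n_per_cell,
               true_proportion = unname(p),
               n = spec$n_per_cell, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  truth <- out
  truth$proportion <- truth$true_proportion
  out$true_proportion <- NULL
  attr(out, "truth") <- truth
  out
}

#' Generate the disease definition tables
#'
#' @param spec a [generator_spec()] with a non-empty disease set.
#' @return list of `disease_definition` objects; prevalence-based diseases
#'   carry `needs_conversion = TRUE` (to be run through
#'   [prevalence_to_incidence()]).
#' @export
generate_disease_tables <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (length(spec$diseases) == 0) stop("disease set must be non-empty")
  spec$diseases
}

#' Write synthetic inputs to CSV files plus a manifest
#'
#' @param spec a [generator_spec()].
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
write_synthetic_inputs <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  survey <- generate_survey_series(spec)
  attr(survey, "truth") <- NULL
  files <- c(survey = file.path(dir, "survey.csv"),
             population = file.path(dir, "population.csv"),
             mortality = file.path(dir, "mortality.csv"))
  utils::write.csv(survey, files["survey"], row.names = FALSE)
  utils::write.csv(spec$population, files["population"], row.names = FALSE)
  utils::write.csv(spec$mortality, files["mortality"], row.names = FALSE)
  for (d in spec$diseases) {
    f <- file.path(dir, paste0("disease_", d$name, ".csv"))
    sched <- d$schedule
    sched$kind <- d$schedule_kind
    utils::write.csv(sched, f, row.names = FALSE)
    files <- c(files, f)
  }
  manifest <- list(
    seed = spec$seed, survey_years = spec$survey_years,
    year_ref = spec$year_ref, n_per_cell = spec$n_per_cell,
    age_groups = spec$age_groups$label,
    diseases = lapply(spec$diseases, function(d) {
      list(name = d$name, fatal = d$fatal, schedule_kind = d$schedule_kind,
           rr = as.list(d$rr), case_fatality = d$case_fatality,
           annual_unit_cost = d$annual_unit_cost)
    }))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(c(files, file.path(dir, "manifest.yaml")))
}
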