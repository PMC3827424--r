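## Small fixtures shared across test files. Everything is generated in code.

## Compact generator spec: 2 age groups, adjustable years / noise / trend.
small_spec <- function(seed = 1, years = c(2000, 2005, 2010),
                       n_per_cell = 10000,
                       slope_ow = 0.03, slope_ob = 0.05,
                       int_ow = -0.2, int_ob = -0.8,
                       diseases = default_diseases()) {
  ag <- make_age_groups(c(20, 50), c(49, 79))
  trend <- list(
    male = list(intercept = c(overweight = int_ow, obese = int_ob),
                slope = c(overweight = slope_ow, obese = slope_ob),
                age_offsets = c(0, 0.4)),
    female = list(intercept = c(overweight = int_ow - 0.1,
                                obese = int_ob - 0.1),
                  slope = c(overweight = slope_ow, obese = slope_ob),
                  age_offsets = c(0, 0.4)))
  generator_spec(seed = seed, survey_years = years, age_groups = ag,
                 trend = trend, n_per_cell = n_per_cell,
                 diseases = diseases)
}

## Flat projected distribution: same proportions every year/sex/group.
flat_distribution <- function(years, p = c(1 / 3, 1 / 3, 1 / 3),
                              age_groups = make_age_groups(20, 100)) {
  grid <- expand.grid(g = seq_len(nrow(age_groups)), sex = SEXES_TEST,
                      year = years, stringsAsFactors = FALSE)
  out <- data.frame(year = grid$year, sex = grid$sex,
                    age_lo = age_groups$age_lo[grid$g],
                    age_hi = age_groups$age_hi[grid$g],
                    p_normal = p[1], p_overweight = p[2], p_obese = p[3])
  class(out) <- c("projected_distribution", "data.frame")
  out
}

SEXES_TEST <- c("male", "female")

## Uniform population concentrated at one age (suppresses 20-year entrants
## when age != 20), with zero-hazard mortality table over 20:100.
point_population <- function(age = 30, count = 1000) {
  do.call(rbind, lapply(SEXES_TEST, function(s) {
    data.frame(sex = s, age = 20:100,
               count = ifelse(20:100 == age, count, 0))
  }))
}

zero_mortality <- function() {
  do.call(rbind, lapply(SEXES_TEST, function(s) {
    data.frame(sex = s, age = 20:100, hazard = 0)
  }))
}

## One synthetic disease with constant incidence and optional fatality.
constant_disease <- function(name = "d1", i = 0.1, fatal = FALSE,
                             case_fatality = 0, rr = c(1, 1, 1),
                             unit_cost = 1000) {
  sched <- do.call(rbind, lapply(SEXES_TEST, function(s) {
    data.frame(sex = s, age = 20:100, value = i)
  }))
  disease_definition(name, fatal = fatal, schedule_kind = "incidence",
                     schedule = sched, rr = rr,
                     case_fatality = case_fatality,
                     annual_unit_cost = unit_cost)
}

## disease_hazards object built directly (bypassing calibration) with a
## single category-constant incidence.
direct_hazards <- function(i = 0.1, rr = c(1, 1, 1), fatal = FALSE,
                           case_fatality = 0, name = "d1",
                           unit_cost = 1000) {
  inc <- array(0, dim = c(2, 81, 3),
               dimnames = list(SEXES_TEST, 20:100,
                               c("normal", "overweight", "obese")))
  for (k in 1:3) inc[, , k] <- i * rr[k]
  h <- list(list(name = name, fatal = fatal, case_fatality = case_fatality,
                 annual_unit_cost = unit_cost,
                 rr = c(normal = 1, overweight = rr[2], obese = rr[3]),
                 incidence = inc))
  names(h) <- name
  class(h) <- "disease_hazards"
  h
}
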