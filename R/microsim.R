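## Stage 2: individual-level Monte Carlo simulation of BMI trajectories,
## disease onset, survival and death.
##
## Within-cohort BMI consistency: each person carries a persistent uniform
## rank in (0,1). Every simulated year the rank is mapped through that
## year's (sex, age-group) category distribution via the quantile of a
## lognormal BMI model whose parameters reproduce the projected category
## proportions. As long as the projected obesity share rises, a fixed rank
## can only move up the categories, never back - the cohort keeps its
## relative BMI position while marginals track the stage-1 projection.

#' Lognormal BMI parameters matching category proportions
#'
#' Solves (in closed form) for the lognormal (meanlog, sdlog) such that
#' P(BMI < 25) = `p_normal` and P(BMI < 30) = `p_normal + p_overweight`.
#' Needed so that percentage BMI reductions are well-defined on a
#' continuous scale.
#'
#' @param p_normal,p_overweight category proportions (vectorised).
#' @return list with vectors `meanlog`, `sdlog`.
#' @export
bmi_lognormal_params <- function(p_normal, p_overweight) {
  eps <- 1e-10
  q1 <- pmin(pmax(p_normal, eps), 1 - 2 * eps)
  q2 <- pmin(pmax(p_normal + p_overweight, q1 + eps), 1 - eps)
  z1 <- stats::qnorm(q1)
  z2 <- stats::qnorm(q2)
  sdlog <- log(BMI_CUT_OBESE / BMI_CUT_OVERWEIGHT) / (z2 - z1)
  meanlog <- log(BMI_CUT_OVERWEIGHT) - sdlog * z1
  list(meanlog = meanlog, sdlog = sdlog)
}

#' Simulation configuration
#'
#' @param n_individuals simulated persons at the start year (default
#'   100,000 - a desk-scale stand-in for full national Monte Carlo runs;
#'   per-100,000 outputs converge as 1/sqrt(n)).
#' @param start_year,end_year simulation window (annual steps).
#' @param seed integer seed; the microsimulation stream is derived from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 100000L, start_year = 2010L,
                       end_year = 2030L, seed = 1L) {
  assert_that(start_year < end_year, "start_year must precede end_year")
  assert_that(n_individuals >= 1, "need at least one individual")
  structure(list(n_individuals = as.integer(n_individuals),
                 start_year = as.integer(start_year),
                 end_year = as.integer(end_year),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Assign BMI to persons from the projected distribution
#'
#' Maps each person's persistent uniform rank through the lognormal BMI
#' quantile of their (year, sex, age-group) stratum, applies any scenario
#' multiplier, and re-derives the WHO category from the continuous value.
#' With multiplier 1 the category equals the category whose
#' cumulative-proportion interval contains the rank (the lognormal is
#' anchored at the 25 and 30 kg/m2 cut-offs).
#'
#' @param rank persistent uniform ranks in (0,1).
#' @param sex integer codes (1 = male, 2 = female).
#' @param ages current ages.
#' @param year calendar year.
#' @param lookup stratum lookup built by [build_dist_lookup()].
#' @param multiplier scenario BMI multiplier (default 1).
#' @return list with vectors `bmi` and `category` (integer 1/2/3 =
#'   normal/overweight/obese).
#' @export
assign_bmi <- function(rank, sex, ages, year, lookup, multiplier = 1) {
  gidx <- age_group_index(pmin(ages, lookup$max_age), lookup$age_groups)
  yi <- match(year, lookup$years)
  if (is.na(yi)) stop("missing stratum: year ", year, " not in distribution")
  ml <- lookup$meanlog[cbind(yi, sex, gidx)]
  sl <- lookup$sdlog[cbind(yi, sex, gidx)]
  if (anyNA(ml)) {
    bad <- which(is.na(ml))[1]
    stop("missing stratum: year ", year, ", sex ", SEXES[sex[bad]],
         ", age ", ages[bad])
  }
  bmi <- stats::qlnorm(rank, ml, sl) * multiplier
  category <- 1L + (bmi >= BMI_CUT_OVERWEIGHT) + (bmi >= BMI_CUT_OBESE)
  list(bmi = bmi, category = category)
}

#' Precompute the stratum lookup for a projected distribution
#'
#' @param dist a `projected_distribution` covering all simulated years.
#' @return list with arrays `meanlog`, `sdlog` indexed
#'   \[year, sex, age group\].
#' @export
build_dist_lookup <- function(dist) {
  years <- sort(unique(dist$year))
  age_groups <- make_age_groups(sort(unique(dist$age_lo)),
                                sort(unique(dist$age_hi)))
  G <- nrow(age_groups)
  meanlog <- array(NA_real_, c(length(years), 2, G))
  sdlog <- array(NA_real_, c(length(years), 2, G))
  props <- array(NA_real_, c(length(years), 2, G, 3))
  for (si in 1:2) {
    d <- dist[dist$sex == SEXES[si], ]
    yi <- match(d$year, years)
    gi <- match(d$age_lo, age_groups$age_lo)
    pars <- bmi_lognormal_params(d$p_normal, d$p_overweight)
    meanlog[cbind(yi, si, gi)] <- pars$meanlog
    sdlog[cbind(yi, si, gi)] <- pars$sdlog
    for (k in 1:3) {
      props[cbind(yi, si, gi, k)] <-
        d[[c("p_normal", "p_overweight", "p_obese")[k]]]
    }
  }
  list(years = years, age_groups = age_groups, meanlog = meanlog,
       sdlog = sdlog, props = props, max_age = 100L)
}

## Internal population container: parallel vectors + onset-year matrix.
.init_population <- function(n, population, start_year) {
  pop <- population[population$age >= 20, ]
  prob <- pop$count / sum(pop$count)
  pick <- sample.int(nrow(pop), n, replace = TRUE, prob = prob)
  sex <- ifelse(pop$sex[pick] == "male", 1L, 2L)
  age <- pop$age[pick]
  list(sex = sex, birth_year = start_year - age,
       rank = stats::runif(n), alive = rep(TRUE, n))
}

#' Advance the population one simulated year
#'
#' For every alive person: diseases not yet present are contracted with
#' probability `1 - exp(-i_k(a))` for the person's BMI category; prevalent
#' fatal diseases kill with probability `1 - exp(-f)`; background
#' mortality applies with probability `1 - exp(-m(a))`. Uniform draws are
#' made for every person slot (dead included) in a fixed order, so runs
#' sharing a seed stay draw-aligned across scenarios (common random
#' numbers).
#'
#' @param state list with vectors `sex`, `alive`, `category`, `ages`, and
#'   matrix `onset` (persons x diseases, NA = never contracted).
#' @param hazards a `disease_hazards` object.
#' @param mort_mat matrix \[2, ages 20..100\] of background mortality.
#' @param year calendar year (recorded on new onsets).
#' @return updated `state` plus `events`: per-disease counts of new cases
#'   and deaths, and other-cause deaths.
#' @export
simulate_year <- function(state, hazards, mort_mat, year) {
  n <- length(state$alive)
  D <- length(hazards)
  a_idx <- pmin(pmax(state$ages, 20L), 100L) - 19L
  new_cases <- integer(D)
  disease_deaths <- integer(D)
  ## incidence draws (one per person per disease, fixed order)
  for (d in seq_len(D)) {
    u <- stats::runif(n)
    i_haz <- hazards[[d]]$incidence[cbind(state$sex, a_idx, state$category)]
    at_risk <- state$alive & is.na(state$onset[, d])
    contract <- at_risk & u < 1 - exp(-i_haz)
    state$onset[contract, d] <- year
    new_cases[d] <- sum(contract)
  }
  ## disease (case-fatality) deaths for fatal conditions
  for (d in seq_len(D)) {
    if (!hazards[[d]]$fatal) next
    u <- stats::runif(n)
    has <- state$alive & !is.na(state$onset[, d])
    die <- has & u < 1 - exp(-hazards[[d]]$case_fatality)
    disease_deaths[d] <- sum(die)
    state$alive[die] <- FALSE
  }
  ## background (other-cause) mortality
  u <- stats::runif(n)
  m <- mort_mat[cbind(state$sex, a_idx)]
  die <- state$alive & u < 1 - exp(-m)
  state$alive[die] <- FALSE
  state$events <- list(new_cases = new_cases,
                       disease_deaths = disease_deaths,
                       other_deaths = sum(die))
  state
}

#' Run the full microsimulation for one scenario
#'
#' Initialises persons from the population structure at the start year
#' with persistent uniform ranks, then per year: updates each person's BMI
#' and category from the projected distribution (applying the scenario's
#' BMI multiplier from its start year), runs disease incidence and
#' mortality, ages everyone and adds new 20-year-old entrants keeping the
#' inflow stationary. Deterministic given the seed.
#'
#' @param cfg a [sim_config()].
#' @param dist a `projected_distribution` covering `start_year:end_year`
#'   for both sexes and all age groups.
#' @param hazards a `disease_hazards` object from
#'   [prepare_disease_hazards()].
#' @param population data.frame `sex, age, count` (whole-population scale;
#'   used for initial sampling and for the per-person scale factor).
#' @param mortality data.frame `sex, age, hazard`.
#' @param scenario a [scenario_def()]; default scenario 0 (no change).
#' @return an `annual_tally` (see [annual_tally]).
#' @export
run_simulation <- function(cfg, dist, hazards, population, mortality,
                           scenario = scenario_def(0)) {
  stopifnot(inherits(cfg, "sim_config"))
  lookup <- build_dist_lookup(dist)
  years <- cfg$start_year:cfg$end_year
  miss <- setdiff(years, lookup$years)
  if (length(miss) > 0) {
    stop("projected distribution missing years: ", paste(miss, collapse = ", "))
  }
  mort_mat <- matrix(NA_real_, 2, 81, dimnames = list(SEXES, 20:100))
  for (si in 1:2) {
    m <- mortality[mortality$sex == SEXES[si], ]
    mort_mat[si, ] <- m$hazard[match(20:100, m$age)]
  }
  if (anyNA(mort_mat)) stop("mortality table must cover ages 20-100")

  set.seed(derive_seed(cfg$seed, "microsim"))
  st <- .init_population(cfg$n_individuals, population, cfg$start_year)
  D <- length(hazards)
  st$onset <- matrix(NA_integer_, cfg$n_individuals, D)
  n_initial <- cfg$n_individuals
  ## stationary inflow: expected persons per single birth cohort at age 20
  pop20 <- population[population$age == 20, ]
  entrants_per_year <- as.integer(round(cfg$n_individuals *
                                          sum(pop20$count) /
                                          sum(population$count)))
  p_male20 <- pop20$count[pop20$sex == "male"] / sum(pop20$count)

  disease_names <- vapply(hazards, `[[`, "", "name")
  cum_cases <- numeric(D)
  tally <- vector("list", length(years))
  cat_shares <- vector("list", length(years))

  for (yi in seq_along(years)) {
    year <- years[yi]
    if (yi > 1 && entrants_per_year > 0) {
      n_new <- entrants_per_year
      sex_new <- ifelse(stats::runif(n_new) < p_male20, 1L, 2L)
      st$sex <- c(st$sex, sex_new)
      st$birth_year <- c(st$birth_year, rep(year - 20L, n_new))
      st$rank <- c(st$rank, stats::runif(n_new))
      st$alive <- c(st$alive, rep(TRUE, n_new))
      st$onset <- rbind(st$onset, matrix(NA_integer_, n_new, D))
    }
    st$ages <- year - st$birth_year
    ## deterministic truncation of extreme old age
    aged_out <- sum(st$alive & st$ages > 100)
    st$alive[st$ages > 100] <- FALSE
    mult <- if (!is.null(scenario) && year >= scenario$start_year)
      scenario$bmi_multiplier else 1
    bm <- assign_bmi(st$rank, st$sex, st$ages, year, lookup, mult)
    st$category <- bm$category
    st <- simulate_year(st, hazards, mort_mat, year)
    cum_cases <- cum_cases + st$events$new_cases
    alive_n <- sum(st$alive)
    prevalent <- colSums(st$alive & !is.na(st$onset))
    tally[[yi]] <- data.frame(
      scenario = scenario$id, year = year, disease = disease_names,
      prevalent = prevalent,
      prevalent_per_100k = prevalent / alive_n * 1e5,
      cum_incidence = cum_cases,
      cum_incidence_per_100k = cum_cases / n_initial * 1e5,
      deaths = st$events$disease_deaths, row.names = NULL)
    sh <- tabulate(st$category[st$alive], 3) / alive_n
    cat_shares[[yi]] <- data.frame(
      scenario = scenario$id, year = year, n_alive = alive_n,
      entrants = if (yi > 1) entrants_per_year else 0L,
      disease_deaths = sum(st$events$disease_deaths),
      other_deaths = st$events$other_deaths, aged_out = aged_out,
      p_normal = sh[1], p_overweight = sh[2], p_obese = sh[3])
  }
  structure(list(by_disease = do.call(rbind, tally),
                 by_year = do.call(rbind, cat_shares),
                 scenario = scenario, n_initial = n_initial,
                 seed = cfg$seed,
                 years = years,
                 scale = sum(population$count) / n_initial),
            class = "annual_tally")
}

#' Annual microsimulation tally
#'
#' @description
#' Result container of [run_simulation()]: `by_disease` holds, per
#' (scenario, year, disease), prevalent cases (raw and per 100,000 alive),
#' cumulative incident cases since the start year (raw and per 100,000 of
#' the start-year population) and disease deaths; `by_year` holds the
#' alive count, other-cause deaths and realised BMI category shares;
#' `scale` converts per-person counts to whole-population counts.
#'
#' @name annual_tally
NULL

#' @export
print.annual_tally <- function(x, ...) {
  cat("Annual tally, scenario", x$scenario$id, "-", length(x$years),
      "years,", x$n_initial, "initial persons\n")
  last <- x$by_disease[x$by_disease$year == max(x$years), ]
  print(last[, c("disease", "prevalent_per_100k", "cum_incidence_per_100k")],
        row.names = FALSE)
  invisible(x)
}
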