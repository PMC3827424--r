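## Illness-death machinery: forward prevalence projection from incidence,
## inversion of prevalence back to incidence, survival-to-hazard conversion
## and relative-risk calibration of category-specific incidence.
##
## The system is the chronic-disease (zero-remission) illness-death model:
##   S'(a) = -(i(a) + m(a)) S(a)
##   C'(a) =  i(a) S(a) - (m(a) + f(a)) C(a)
## with S susceptible, C cases, i incidence, m all-cause background
## mortality and f excess case fatality; prevalence p(a) = C / (S + C).

## One step of length dt with hazards held constant: exact solution of the
## linear system (no Euler error; substeps change nothing for piecewise-
## constant hazards).
.illness_death_step <- function(S, C, i, f, m, dt = 1) {
  S2 <- S * exp(-(i + m) * dt)
  d <- i - f
  growth <- ifelse(abs(d) < 1e-12, i * dt, i * (1 - exp(-d * dt)) / d)
  C2 <- exp(-(m + f) * dt) * (C + S * growth)
  list(S = S2, C = C2)
}

.expand_hazard <- function(h, ages, what) {
  if (length(h) == 1) h <- rep(h, length(ages))
  assert_that(length(h) == length(ages),
              paste(what, "must be scalar or one value per age"))
  assert_that(all(is.finite(h)) && all(h >= 0),
              paste(what, "hazards must be finite and >= 0"))
  h
}

#' Project prevalence forward from incidence (illness-death model)
#'
#' Solves the zero-remission illness-death system over single-year ages
#' with hazards held constant within each year (exact within-year
#' solution).
#'
#' @param i incidence hazard per person-year: scalar or vector over `ages`.
#' @param f excess case-fatality hazard: scalar or vector.
#' @param m background all-cause mortality hazard: scalar or vector.
#' @param ages integer ages (default 20:100).
#' @param p0 prevalence at the first age (default 0).
#' @param n_substeps sub-annual integration steps per year (default 1;
#'   e.g. 12 for monthly). With piecewise-constant hazards the result is
#'   step-size independent.
#' @return data.frame `age, prevalence`.
#' @export
illness_death_forward <- function(i, f = 0, m = 0, ages = 20:100, p0 = 0,
                                  n_substeps = 1) {
  i <- .expand_hazard(i, ages, "incidence")
  f <- .expand_hazard(f, ages, "case fatality")
  m <- .expand_hazard(m, ages, "mortality")
  assert_that(p0 >= 0 && p0 < 1, "p0 must be in [0, 1)")
  n <- length(ages)
  prev <- numeric(n)
  S <- 1 - p0; C <- p0
  prev[1] <- p0
  dt <- 1 / n_substeps
  for (k in seq_len(n - 1)) {
    for (s in seq_len(n_substeps)) {
      st <- .illness_death_step(S, C, i[k], f[k], m[k], dt)
      S <- st$S; C <- st$C
    }
    prev[k + 1] <- C / (S + C)
  }
  data.frame(age = ages, prevalence = prev)
}

#' Invert a prevalence schedule to incidence (DisMod-style)
#'
#' Recovers, age by age, the non-negative incidence hazard whose one-step
#' forward illness-death projection matches the observed next-age
#' prevalence. Ages where the observed prevalence declines faster than
#' case fatality and mortality can explain (which would need negative
#' incidence under zero remission) are clamped to 0 and reported.
#'
#' @param p prevalence schedule: vector over `ages`, values in \[0, 1).
#' @param f,m excess case-fatality and background mortality hazards
#'   (scalar or vector over `ages`).
#' @param ages integer ages matching `p`.
#' @return data.frame `age, incidence` for ages `ages[-length(ages)]`, with
#'   attribute `clamped_ages` listing infeasible ages.
#' @export
prevalence_to_incidence <- function(p, f = 0, m = 0, ages = 20:100) {
  assert_that(all(p >= 0 & p < 1), "prevalence must be in [0, 1)")
  f <- .expand_hazard(f, ages, "case fatality")
  m <- .expand_hazard(m, ages, "mortality")
  assert_that(length(p) == length(ages), "one prevalence per age required")
  n <- length(ages)
  inc <- numeric(n - 1)
  clamped <- integer(0)
  one_step_prev <- function(i, pa, fa, ma) {
    st <- .illness_death_step(1 - pa, pa, i, fa, ma, 1)
    st$C / (st$S + st$C)
  }
  for (k in seq_len(n - 1)) {
    target <- p[k + 1]
    g <- function(i) one_step_prev(i, p[k], f[k], m[k]) - target
    if (g(0) >= 0) {
      ## next-age prevalence at or below what pure survivorship implies
      if (g(0) > 1e-12) clamped <- c(clamped, ages[k])
      inc[k] <- 0
      next
    }
    hi <- 0.1
    while (g(hi) < 0 && hi < 64) hi <- hi * 2
    if (g(hi) < 0) {
      clamped <- c(clamped, ages[k])
      inc[k] <- hi
      next
    }
    inc[k] <- stats::uniroot(g, c(0, hi), tol = 1e-12)$root
  }
  out <- data.frame(age = ages[-n], incidence = inc)
  attr(out, "clamped_ages") <- clamped
  out
}

#' Convert n-year survival to a constant excess hazard
#'
#' Under a constant-hazard assumption, an observed proportion `s` surviving
#' `horizon_n` years implies an excess death hazard of `-log(s)/horizon_n`
#' per person-year.
#'
#' @param s n-year survival proportion in (0, 1\].
#' @param horizon_n the survival horizon in years (> 0).
#' @return excess hazard per person-year.
#' @export
survival_to_excess_hazard <- function(s, horizon_n) {
  assert_that(horizon_n > 0, "horizon must be positive")
  assert_that(all(s > 0 & s <= 1),
              "survival must be in (0, 1]: s = 0 implies infinite hazard")
  -log(s) / horizon_n
}

#' Calibrate BMI-category-specific incidence from population incidence
#'
#' Splits a total-population incidence schedule into per-category hazards
#' consistent with the relative risks and the baseline category mix:
#' `i_ref(a) = i_pop(a) / sum_k p_k(a) RR_k`, `i_k(a) = RR_k i_ref(a)`.
#' The mixture identity `sum_k p_k i_k = i_pop` then holds exactly.
#'
#' @param i_pop population incidence hazard: vector over ages.
#' @param rr length-3 relative risks `(1, RR_overweight, RR_obese)`.
#' @param p_cat matrix (ages x 3) of baseline category proportions with
#'   rows summing to 1.
#' @return matrix (ages x 3) of per-category incidence hazards with
#'   columns `normal, overweight, obese`.
#' @export
calibrate_category_incidence <- function(i_pop, rr, p_cat) {
  rr <- unname(rr)
  assert_that(length(rr) == 3 && rr[1] == 1, "rr must be (1, RR_ow, RR_ob)")
  assert_that(all(rr >= 0), "relative risks must be >= 0")
  p_cat <- as.matrix(p_cat)
  assert_that(nrow(p_cat) == length(i_pop),
              "category proportions and incidence must share ages")
  denom <- drop(p_cat %*% rr)
  if (any(denom <= 0)) stop("sum of p_k * RR_k is zero: cannot calibrate")
  i_ref <- i_pop / denom
  out <- cbind(normal = i_ref, overweight = rr[2] * i_ref,
               obese = rr[3] * i_ref)
  out
}

## Build simulation-ready hazards for every disease: run the prevalence ->
## incidence conversion where flagged, then calibrate category-specific
## incidence against the baseline-year BMI distribution.
#' Prepare per-category disease hazards for the microsimulation
#'
#' For each disease: prevalence schedules are converted to incidence with
#' [prevalence_to_incidence()] (using the disease's case fatality and the
#' supplied background mortality), then population incidence is split into
#' BMI-category-specific hazards with [calibrate_category_incidence()]
#' using the baseline-year projected BMI distribution.
#'
#' @param diseases list of [disease_definition()] objects.
#' @param dist a `projected_distribution` covering the baseline year.
#' @param mortality data.frame `sex, age, hazard`.
#' @param baseline_year year whose category mix anchors the calibration.
#' @param ages single-year ages covered (default 20:100).
#' @return list of class `disease_hazards`: per disease, `name`, `fatal`,
#'   `case_fatality`, `annual_unit_cost`, `rr`, and `incidence` — an array
#'   `[sex, age, category]` of hazards per person-year.
#' @export
prepare_disease_hazards <- function(diseases, dist, mortality,
                                    baseline_year, ages = 20:100) {
  age_groups <- make_age_groups(sort(unique(dist$age_lo)),
                                sort(unique(dist$age_hi)))
  base <- dist[dist$year == baseline_year, ]
  if (nrow(base) == 0) stop("baseline year ", baseline_year, " not in dist")
  out <- lapply(diseases, function(d) {
    inc <- array(0, dim = c(2, length(ages), 3),
                 dimnames = list(SEXES, ages, BMI_CATEGORIES))
    for (s in SEXES) {
      sched <- d$schedule[d$schedule$sex == s, ]
      v <- sched$value[match(ages, sched$age)]
      if (anyNA(v)) stop("disease ", d$name, ": schedule must cover ages")
      m <- mortality$hazard[mortality$sex == s][match(
        ages, mortality$age[mortality$sex == s])]
      if (d$schedule_kind == "prevalence") {
        conv <- prevalence_to_incidence(v, f = d$case_fatality, m = m,
                                        ages = ages)
        i_pop <- c(conv$incidence, conv$incidence[length(conv$incidence)])
      } else {
        i_pop <- v
      }
      gidx <- age_group_index(ages, age_groups)
      bs <- base[base$sex == s, ]
      ord <- match(age_groups$age_lo, bs$age_lo)
      p_cat <- as.matrix(bs[ord, c("p_normal", "p_overweight", "p_obese")])
      inc[s, , ] <- calibrate_category_incidence(i_pop, d$rr,
                                                 p_cat[gidx, , drop = FALSE])
    }
    list(name = d$name, fatal = d$fatal, case_fatality = d$case_fatality,
         annual_unit_cost = d$annual_unit_cost, rr = d$rr, incidence = inc)
  })
  names(out) <- vapply(diseases, `[[`, "", "name")
  class(out) <- "disease_hazards"
  out
}
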