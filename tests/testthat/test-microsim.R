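test_that("lognormal BMI parameters reproduce the category proportions", {
  ps <- rbind(c(0.4, 0.35), c(0.2, 0.4), c(0.1, 0.3), c(0.6, 0.3))
  for (k in seq_len(nrow(ps))) {
    par <- bmi_lognormal_params(ps[k, 1], ps[k, 2])
    expect_equal(plnorm(25, par$meanlog, par$sdlog), ps[k, 1],
                 tolerance = 1e-9)
    expect_equal(plnorm(30, par$meanlog, par$sdlog), ps[k, 1] + ps[k, 2],
                 tolerance = 1e-9)
  }
})

test_that("rank-to-category assignment respects cumulative intervals", {
  dist <- flat_distribution(2010, p = c(0.2, 0.4, 0.4))
  lookup <- build_dist_lookup(dist)
  out <- assign_bmi(c(0.10, 0.25, 0.65), sex = c(1L, 1L, 2L),
                    ages = c(30, 40, 55), year = 2010, lookup)
  expect_identical(out$category, c(1L, 2L, 3L))
  expect_true(out$bmi[1] < 25 && out$bmi[2] >= 25 && out$bmi[2] < 30 &&
                out$bmi[3] >= 30)
  expect_error(assign_bmi(0.5, 1L, 30, 2011, lookup), "missing stratum")
})

test_that("fixed ranks never move down categories as obesity rises", {
  years <- 2010:2030
  ag <- make_age_groups(20, 100)
  dist <- do.call(rbind, lapply(years, function(y) {
    ## both cut-point quantiles decrease in time
    pn <- 0.4 - 0.01 * (y - 2010)
    pb <- 0.3 + 0.012 * (y - 2010)
    data.frame(year = y, sex = SEXES_TEST, age_lo = 20, age_hi = 100,
               p_normal = pn, p_overweight = 1 - pn - pb, p_obese = pb)
  }))
  lookup <- build_dist_lookup(dist)
  ranks <- seq(0.01, 0.99, length.out = 199)
  prev <- rep(1L, length(ranks))
  for (y in years) {
    cur <- assign_bmi(ranks, rep(1L, length(ranks)),
                      rep(40, length(ranks)), y, lookup)$category
    expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("realized category frequencies match the distribution", {
  dist <- flat_distribution(2010, p = c(0.5, 0.3, 0.2))
  lookup <- build_dist_lookup(dist)
  n <- 100000
  set.seed(99)
  ranks <- runif(n)
  cat <- assign_bmi(ranks, rep(1L, n), rep(50, n), 2010, lookup)$category
  freq <- tabulate(cat, 3) / n
  for (k in 1:3) {
    p <- c(0.5, 0.3, 0.2)[k]
    expect_lt(abs(freq[k] - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("zero hazards leave the population unchanged", {
  n <- 500
  state <- list(sex = rep(1:2, n / 2), alive = rep(TRUE, n),
                category = rep(2L, n), ages = rep(45L, n),
                onset = matrix(NA_integer_, n, 1))
  hz <- direct_hazards(i = 0)
  mort <- matrix(0, 2, 81, dimnames = list(SEXES_TEST, 20:100))
  set.seed(1)
  out <- simulate_year(state, hz, mort, 2010)
  expect_true(all(out$alive))
  expect_true(all(is.na(out$onset)))
  expect_identical(out$events$new_cases, 0L)
  expect_identical(out$events$other_deaths, 0L)
})

test_that("with equal relative risks incidence is category-independent", {
  n <- 100000
  set.seed(7)
  state <- list(sex = rep(1L, n), alive = rep(TRUE, n),
                category = sample(1:3, n, replace = TRUE),
                ages = rep(50L, n), onset = matrix(NA_integer_, n, 1))
  hz <- direct_hazards(i = 0.05, rr = c(1, 1, 1))
  mort <- matrix(0, 2, 81, dimnames = list(SEXES_TEST, 20:100))
  out <- simulate_year(state, hz, mort, 2010)
  cases <- tapply(!is.na(out$onset[, 1]), state$category, sum)
  atrisk <- tabulate(state$category, 3)
  tab <- rbind(cases, atrisk - cases)
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("doubled obese hazard doubles obese incidence", {
  n <- 200000
  set.seed(8)
  state <- list(sex = rep(1L, n), alive = rep(TRUE, n),
                category = rep(c(1L, 3L), n / 2),
                ages = rep(50L, n), onset = matrix(NA_integer_, n, 1))
  hz <- direct_hazards(i = 0.05, rr = c(1, 1, 2))
  mort <- matrix(0, 2, 81, dimnames = list(SEXES_TEST, 20:100))
  out <- simulate_year(state, hz, mort, 2010)
  r_norm <- sum(!is.na(out$onset[state$category == 1, 1])) / (n / 2)
  r_ob <- sum(!is.na(out$onset[state$category == 3, 1])) / (n / 2)
  ## probability ratio (1-exp(-2i))/(1-exp(-i)) = 1.9754 at i = 0.05
  expected <- (1 - exp(-0.1)) / (1 - exp(-0.05))
  se <- sqrt(r_ob * (1 - r_ob) / (n / 2)) / r_norm * 3
  expect_lt(abs(r_ob / r_norm - expected), 3 * 0.05 + se)
})

test_that("simulation is deterministic given the seed", {
  dist <- flat_distribution(2010:2014)
  cfg <- sim_config(2000, 2010, 2014, seed = 5)
  hz <- direct_hazards(i = 0.05, fatal = TRUE, case_fatality = 0.1)
  pop <- point_population(40)
  mort <- default_mortality()
  t1 <- run_simulation(cfg, dist, hz, pop, mort)
  t2 <- run_simulation(cfg, dist, hz, pop, mort)
  expect_identical(t1$by_disease, t2$by_disease)
  expect_identical(t1$by_year, t2$by_year)
  t3 <- run_simulation(sim_config(2000, 2010, 2014, seed = 6), dist, hz,
                       pop, mort)
  expect_false(identical(t1$by_disease, t3$by_disease))
})

test_that("person counts are conserved year over year", {
  spec <- small_spec(seed = 3)
  dist <- flat_distribution(2010:2020, p = c(0.4, 0.35, 0.25))
  cfg <- sim_config(5000, 2010, 2020, seed = 2)
  hz <- direct_hazards(i = 0.03, fatal = TRUE, case_fatality = 0.2)
  t <- run_simulation(cfg, dist, hz, default_population(),
                      default_mortality())
  by <- t$by_year
  dd <- tapply(t$by_disease$deaths, t$by_disease$year, sum)
  expect_equal(as.numeric(unname(dd)), as.numeric(by$disease_deaths))
  prev_alive <- cfg$n_individuals
  for (k in seq_len(nrow(by))) {
    expect_identical(by$n_alive[k],
                     prev_alive + by$entrants[k] - by$disease_deaths[k] -
                       by$other_deaths[k] - by$aged_out[k])
    prev_alive <- by$n_alive[k]
  }
  ## cumulative incidence never decreases
  for (d in unique(t$by_disease$disease)) {
    expect_true(all(diff(
      t$by_disease$cum_incidence[t$by_disease$disease == d]) >= 0))
  }
})

test_that("per-100,000 outputs scale as raw counts over person-years", {
  dist <- flat_distribution(2010:2012)
  cfg <- sim_config(3000, 2010, 2012, seed = 3)
  hz <- direct_hazards(i = 0.1)
  t <- run_simulation(cfg, dist, hz, point_population(40), zero_mortality())
  bd <- t$by_disease
  by <- t$by_year
  expect_equal(bd$prevalent_per_100k,
               bd$prevalent / by$n_alive[match(bd$year, by$year)] * 1e5)
  expect_equal(bd$cum_incidence_per_100k, bd$cum_incidence / 3000 * 1e5)
})

test_that("replicate-seed dispersion shrinks like one over root n", {
  dist <- flat_distribution(2010:2015)
  hz <- direct_hazards(i = 0.08)
  pop <- point_population(40)
  mort <- zero_mortality()
  final_prev <- function(n, seed) {
    t <- run_simulation(sim_config(n, 2010, 2015, seed), dist, hz, pop, mort)
    t$by_disease$prevalent_per_100k[t$by_disease$year == 2015]
  }
  seeds <- 1:16
  s_small <- sd(vapply(seeds, function(s) final_prev(1000, s), 0))
  s_big <- sd(vapply(seeds, function(s) final_prev(4000, s), 0))
  ratio <- s_small / s_big   # expected 2 under 1/sqrt(n) scaling
  expect_gt(ratio, 2 / 1.5)
  expect_lt(ratio, 2 * 1.5)
})
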