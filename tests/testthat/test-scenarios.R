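test_that("scenario definitions enforce their invariants", {
  s0 <- scenario_def(0)
  expect_identical(s0$bmi_multiplier, 1)
  expect_identical(scenario_def(1)$bmi_multiplier, 0.99)
  expect_identical(scenario_def(2)$bmi_multiplier, 0.95)
  expect_error(scenario_def(0, bmi_multiplier = 0.9), "multiplier 1")
  expect_error(scenario_def(3, bmi_multiplier = 1.2), "\\(0, 1\\]")
  expect_error(scenario_def(5), "supply bmi_multiplier")
})

test_that("BMI reduction shifts values and re-derives categories", {
  sc <- scenario_def(2, start_year = 2015)
  out <- apply_scenario(30.5, sc, 2020)
  expect_equal(out$bmi, 28.975)
  expect_identical(out$category, "overweight")
  ## identity before the start year
  pre <- apply_scenario(30.5, sc, 2014)
  expect_equal(pre$bmi, 30.5)
  expect_identical(pre$category, "obese")
})

test_that("attributable fraction follows the Levin formula", {
  expect_identical(attributable_fraction(c(0.3, 0.4, 0.3), c(1, 1, 1)), 0)
  paf <- attributable_fraction(c(0.3, 0.4, 0.3), c(1, 1.5, 2.5))
  expect_equal(paf, 0.65 / 1.65, tolerance = 1e-9)
  ## limiting case: everyone obese at RR 2 -> PAF 0.5
  expect_equal(attributable_fraction(c(0, 0, 1), c(1, 1, 2)), 0.5)
  expect_error(attributable_fraction(c(0.3, 0.4, 0.3), c(1, -1, 2)), ">= 0")
  ## PAF in [0,1) whenever RR >= 1, equals 0 iff the mixture sum is 1
  set.seed(11)
  for (k in 1:50) {
    p <- rgamma(3, 1); p <- p / sum(p)
    rr <- c(1, 1 + rexp(1), 1 + rexp(1))
    v <- attributable_fraction(p, rr)
    expect_true(v >= 0 && v < 1)
  }
})

test_that("scenario 0 reproduces the unadjusted run bit for bit", {
  dist <- flat_distribution(2010:2014)
  cfg <- sim_config(2000, 2010, 2014, seed = 4)
  hz <- direct_hazards(i = 0.05, rr = c(1, 1.5, 2))
  pop <- point_population(40)
  mort <- zero_mortality()
  t_plain <- run_simulation(cfg, dist, hz, pop, mort)
  t_s0 <- run_simulation(cfg, dist, hz, pop, mort,
                         scenario_def(0, start_year = 2010))
  expect_identical(t_plain$by_disease[names(t_plain$by_disease) != "scenario"],
                   t_s0$by_disease[names(t_s0$by_disease) != "scenario"])
})

test_that("obese share falls monotonically with the BMI multiplier", {
  dist <- flat_distribution(2010:2016, p = c(0.35, 0.35, 0.30))
  cfg <- sim_config(4000, 2010, 2016, seed = 9)
  hz <- direct_hazards(i = 0.02, rr = c(1, 1.3, 1.8))
  pop <- point_population(45)
  mort <- zero_mortality()
  runs <- lapply(0:2, function(k) {
    run_simulation(cfg, dist, hz, pop, mort,
                   scenario_def(k, start_year = 2010))
  })
  ob <- lapply(runs, function(t) t$by_year$p_obese)
  expect_true(all(ob[[3]] <= ob[[2]] + 1e-12))
  expect_true(all(ob[[2]] <= ob[[1]] + 1e-12))
})

test_that("cases avoided: self-difference is zero, dominance holds and
           metadata mismatches are rejected", {
  dist <- flat_distribution(2010:2018, p = c(0.35, 0.35, 0.30))
  cfg <- sim_config(5000, 2010, 2018, seed = 12)
  hz <- direct_hazards(i = 0.04, rr = c(1, 1.5, 2.5))
  pop <- point_population(45)
  mort <- zero_mortality()
  runs <- lapply(0:2, function(k) {
    run_simulation(cfg, dist, hz, pop, mort,
                   scenario_def(k, start_year = 2010))
  })
  zero <- cases_avoided(runs[[1]], runs[[1]])
  expect_true(all(zero$avoided_per_100k == 0))
  av1 <- cases_avoided(runs[[1]], runs[[2]])
  av2 <- cases_avoided(runs[[1]], runs[[3]])
  expect_true(all(av1$avoided_per_100k >= 0))
  expect_true(all(av2$avoided_per_100k >= av1$avoided_per_100k))
  other <- run_simulation(sim_config(5000, 2010, 2018, seed = 13), dist,
                          hz, pop, mort, scenario_def(1, start_year = 2010))
  expect_error(cases_avoided(runs[[1]], other), "not comparable")
})

test_that("attribution identity: attributed tally equals total times PAF", {
  dist <- flat_distribution(2010:2013, p = c(0.3, 0.4, 0.3))
  cfg <- sim_config(3000, 2010, 2013, seed = 6)
  hz <- direct_hazards(i = 0.05, rr = c(1, 1.5, 2.5))
  t <- run_simulation(cfg, dist, hz, point_population(40), zero_mortality())
  ta <- obesity_attributable_tally(t, hz)
  bd <- ta$by_disease
  by <- ta$by_year
  shares <- as.matrix(by[match(bd$year, by$year),
                         c("p_normal", "p_overweight", "p_obese")])
  paf <- unname(attributable_fraction(shares, c(1, 1.5, 2.5)))
  expect_identical(bd$prevalent_attrib, bd$prevalent * paf)
  expect_identical(bd$cum_incidence_attrib, bd$cum_incidence * paf)
  expect_true(all(bd$paf >= 0 & bd$paf < 1))
})
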