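test_that("fit matches an independent multinomial-regression fit", {
  skip_if_not_installed("nnet")
  spec <- small_spec(seed = 5, years = c(2000, 2004, 2008), n_per_cell = 2000)
  obs <- generate_survey_series(spec)
  fit <- fit_category_trends(obs, "male")
  ## independent route: nnet::multinom on the same counts
  d <- obs[obs$sex == "male", ]
  wide <- reshape(d[, c("year", "age_lo", "category", "proportion", "n")],
                  idvar = c("year", "age_lo", "n"), timevar = "category",
                  direction = "wide")
  Y <- as.matrix(wide[, paste0("proportion.",
                               c("normal", "overweight", "obese"))]) * wide$n
  df <- data.frame(yc = wide$year - mean(range(wide$year)),
                   age = factor(wide$age_lo))
  ref <- nnet::multinom(Y ~ yc + age, data = df, trace = FALSE,
                        maxit = 500, reltol = 1e-12)
  pref <- predict(ref, type = "probs")
  pmine <- obesitysim:::.model_props(
    fit, wide$year, match(wide$age_lo, fit$age_groups$age_lo))
  expect_lt(max(abs(pref - pmine)), 1e-4)
})

test_that("fitted likelihood is at least the truth's likelihood", {
  spec <- small_spec(seed = 9, years = seq(2000, 2010, 2), n_per_cell = 3000)
  obs <- generate_survey_series(spec)
  fit <- fit_category_trends(obs, "female")
  ## evaluate the same likelihood at the generating parameters
  tr <- spec$trend$female
  truth_coef <- c(tr$intercept[1] + tr$slope[1] * (fit$year_center -
                                                     spec$year_ref),
                  tr$slope[1], tr$age_offsets[2],
                  tr$intercept[2] + tr$slope[2] * (fit$year_center -
                                                     spec$year_ref),
                  tr$slope[2], tr$age_offsets[2])
  dat <- obesitysim:::.survey_counts(obs, "female", fit$age_groups)
  X <- obesitysim:::.trend_design(dat$year, dat$group_idx, 2,
                                  fit$year_center)
  ll_truth <- -obesitysim:::.multinom_negll(truth_coef, X, dat$Y)
  expect_gte(fit$loglik, ll_truth - 1e-8)
})

test_that("a single replicate recovers the generating slope", {
  spec <- small_spec(seed = 21, years = seq(2000, 2010, 2),
                     n_per_cell = 10000, slope_ob = 0.05)
  obs <- generate_survey_series(spec)
  fit <- fit_category_trends(obs, "male")
  est <- fit$coef["ob:year"]
  se <- sqrt(diag(fit$vcov))["ob:year"]
  expect_lt(abs(est - 0.05), 1.96 * se + 0.01)
})

test_that("constant proportions give near-zero year slopes", {
  spec <- small_spec(seed = 4, slope_ow = 0, slope_ob = 0,
                     n_per_cell = 20000)
  obs <- generate_survey_series(spec)
  for (s in c("male", "female")) {
    fit <- fit_category_trends(obs, s)
    se <- sqrt(diag(fit$vcov))
    expect_lt(abs(fit$coef["ow:year"]), 3 * se["ow:year"])
    expect_lt(abs(fit$coef["ob:year"]), 3 * se["ob:year"])
  }
})

test_that("degenerate inputs are rejected with informative errors", {
  spec <- small_spec(seed = 5)
  obs <- generate_survey_series(spec)
  ## fewer than two distinct years
  expect_error(fit_category_trends(obs[obs$year == 2000, ], "male"),
               ">= 2 distinct")
  ## a category absent everywhere: separation
  obs2 <- obs
  obs2$proportion[obs2$category == "obese"] <- 0
  expect_error(fit_category_trends(obs2, "male"), "separation")
})

test_that("zero-weight cells leave the fit unchanged", {
  spec <- small_spec(seed = 6)
  obs <- generate_survey_series(spec)
  fit1 <- fit_category_trends(obs, "male")
  ghost <- obs[obs$year == 2000 & obs$sex == "male", ]
  ghost$n <- 0
  fit2 <- fit_category_trends(rbind(obs, ghost), "male")
  expect_equal(fit1$coef, fit2$coef, tolerance = 1e-6)
})

test_that("projections sum to one and rise monotonically under a
           positive obese slope", {
  spec <- small_spec(seed = 7, slope_ob = 0.06, n_per_cell = 20000)
  obs <- generate_survey_series(spec)
  fit <- fit_category_trends(obs, "male")
  proj <- project_distribution(fit, 1995:2030)
  sums <- proj$p_normal + proj$p_overweight + proj$p_obese
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_gt(fit$coef["ob:year"], 0)
  for (g in unique(proj$age_lo)) {
    p <- proj$p_obese[proj$age_lo == g]
    expect_true(all(diff(p) > 0))
  }
  ## backcast years flagged
  expect_true(all(1995:1999 %in% attr(proj, "backcast")))
})

test_that("bootstrap bands contain the point estimate and widen with
           extrapolation distance", {
  spec <- small_spec(seed = 8, years = seq(1998, 2010, 3), n_per_cell = 2000)
  obs <- generate_survey_series(spec)
  fit <- fit_category_trends(obs, "male")
  pb <- projection_confidence_limits(fit, c(2010, 2030), n_boot = 500,
                                     seed = 2)
  expect_true(all(pb$lo_obese <= pb$p_obese & pb$p_obese <= pb$hi_obese))
  for (g in unique(pb$age_lo)) {
    w10 <- with(pb[pb$year == 2010 & pb$age_lo == g, ], hi_obese - lo_obese)
    w30 <- with(pb[pb$year == 2030 & pb$age_lo == g, ], hi_obese - lo_obese)
    expect_gt(w30, w10)
  }
  expect_warning(projection_confidence_limits(fit, 2030, n_boot = 50,
                                              seed = 2), "n_boot")
})

test_that("outlier filter flags a gross perturbation and partitions obs", {
  spec <- small_spec(seed = 10, years = seq(1998, 2010, 2),
                     n_per_cell = 4000)
  obs <- generate_survey_series(spec)
  ## perturb one male cell's obese share to 0.99 against a ~0.2-0.4 trend
  cell <- which(obs$sex == "male" & obs$year == 2004 & obs$age_lo == 20)
  stopifnot(length(cell) == 3)
  obs$proportion[cell] <- c(0.005, 0.005, 0.99)
  filt <- filter_outliers(obs)
  expect_equal(nrow(filt$kept) + nrow(filt$removed), nrow(obs))
  expect_true(all(cell %in% which(
    paste(obs$year, obs$sex, obs$age_lo) %in%
      paste(filt$removed$year, filt$removed$sex, filt$removed$age_lo))))
  ## clean large-n data: only a small share of cells flagged
  clean <- generate_survey_series(small_spec(seed = 30,
                                             years = seq(1990, 2010, 2),
                                             n_per_cell = 10000))
  f2 <- filter_outliers(clean)
  expect_lt(nrow(f2$removed) / nrow(clean), 0.25)
})

test_that("outlier filter needs at least three survey years per sex", {
  spec <- small_spec(seed = 11, years = c(2000, 2010))
  obs <- generate_survey_series(spec)
  expect_error(filter_outliers(obs), "3 survey years")
})
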