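## Stage 1: constrained categorical BMI-trend regression.
##
## The model is a three-category multinomial logit, linear in calendar year
## with additive age-group offsets, fitted per sex by maximum likelihood on
## the observed category counts (proportion x n). Predicted proportions sum
## to 1 by construction, which is how the 100% constraint is enforced.

## Build the design matrix for one sex: intercept, centred year, age dummies
## (first group is the reference), optional year x age interaction.
.trend_design <- function(year, group_idx, n_groups, year_center,
                          interaction = FALSE) {
  yc <- year - year_center
  X <- cbind(intercept = 1, year = yc)
  if (n_groups > 1) {
    for (g in 2:n_groups) {
      X <- cbind(X, as.numeric(group_idx == g))
      colnames(X)[ncol(X)] <- paste0("age", g)
    }
    if (interaction) {
      for (g in 2:n_groups) {
        X <- cbind(X, yc * as.numeric(group_idx == g))
        colnames(X)[ncol(X)] <- paste0("year:age", g)
      }
    }
  }
  X
}

## Multinomial negative log-likelihood and analytic gradient.
## par = c(beta_overweight, beta_obese), Y = counts matrix (cells x 3,
## columns normal/overweight/obese), X = design matrix.
.multinom_negll <- function(par, X, Y) {
  p <- ncol(X)
  eta1 <- drop(X %*% par[1:p])
  eta2 <- drop(X %*% par[(p + 1):(2 * p)])
  P <- softmax3(eta1, eta2)
  -sum(Y * log(pmax(P, 1e-300)))
}

.multinom_grad <- function(par, X, Y) {
  p <- ncol(X)
  eta1 <- drop(X %*% par[1:p])
  eta2 <- drop(X %*% par[(p + 1):(2 * p)])
  P <- softmax3(eta1, eta2)
  n_cell <- rowSums(Y)
  g1 <- -colSums(X * (Y[, 2] - n_cell * P[, 2]))
  g2 <- -colSums(X * (Y[, 3] - n_cell * P[, 3]))
  c(g1, g2)
}

## Reshape long survey rows for one sex into a cells x 3 count matrix.
.survey_counts <- function(obs, sex, age_groups, weight_by_n = TRUE) {
  obs <- obs[obs$sex == sex, ]
  if (nrow(obs) == 0) stop("no observations for sex ", sex)
  key <- interaction(obs$year, obs$age_lo, drop = TRUE)
  cells <- unique(data.frame(year = obs$year, age_lo = obs$age_lo,
                             key = as.character(key)))
  n_use <- if (weight_by_n) obs$n else rep(round(mean(obs$n)), nrow(obs))
  Y <- matrix(0, nrow(cells), 3,
              dimnames = list(NULL, BMI_CATEGORIES))
  for (i in seq_len(nrow(obs))) {
    r <- match(as.character(key)[i], cells$key)
    Y[r, obs$category[i]] <- Y[r, obs$category[i]] +
      obs$proportion[i] * n_use[i]
  }
  g <- age_group_index(cells$age_lo, age_groups)
  list(year = cells$year, group_idx = g, Y = Y)
}

#' Remove survey outliers outside 95% prediction limits
#'
#' Operationalises outlier removal "outside 95% confidence limits" as: for
#' each (sex, category), fit a preliminary binomial-logit trend in year with
#' age-group offsets, form 95% prediction limits on the logit scale that
#' combine the fit's standard error with the cell's binomial sampling
#' variance (approximated as 1/(n p(1-p)) on the logit scale), and flag
#' observations falling outside. A flagged category row removes its whole
#' (year, sex, age-group) cell so the remaining data keep the sum-to-one
#' structure. One pass only; the caller refits on `kept`.
#'
#' @param obs long survey data.frame (see [generate_survey_series()]).
#' @param level prediction-limit coverage (default 0.95).
#' @return list with elements `kept` and `removed`; their union is `obs`.
#' @export
filter_outliers <- function(obs, level = 0.95) {
  for (s in unique(obs$sex)) {
    if (length(unique(obs$year[obs$sex == s])) < 3) {
      stop("need >= 3 survey years per sex for outlier screening (sex ", s, ")")
    }
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  obs$.row <- seq_len(nrow(obs))
  flagged <- rep(FALSE, nrow(obs))
  for (s in unique(obs$sex)) {
    for (cat in BMI_CATEGORIES) {
      idx <- which(obs$sex == s & obs$category == cat)
      d <- obs[idx, ]
      y <- round(d$proportion * d$n)
      agegrp <- factor(d$age_lo)
      yc <- d$year - mean(unique(d$year))
      fit <- suppressWarnings(stats::glm(
        cbind(y, d$n - y) ~ yc + agegrp, family = stats::binomial()))
      pr <- stats::predict(fit, type = "link", se.fit = TRUE)
      phat <- stats::plogis(pr$fit)
      samp_var <- 1 / (d$n * pmax(phat * (1 - phat), 1e-8))
      half <- z * sqrt(pr$se.fit^2 + samp_var)
      lo <- stats::plogis(pr$fit - half)
      hi <- stats::plogis(pr$fit + half)
      flagged[idx] <- d$proportion < lo | d$proportion > hi
    }
  }
  ## flagging any category row drops the whole survey cell
  cell <- interaction(obs$year, obs$sex, obs$age_lo, drop = TRUE)
  bad_cell <- unique(cell[flagged])
  rm_idx <- cell %in% bad_cell
  kept <- obs[!rm_idx, ]
  removed <- obs[rm_idx, ]
  for (s in unique(obs$sex)) {
    if (!any(kept$sex == s)) {
      stop("all observations removed for sex ", s, ": degenerate data")
    }
  }
  kept$.row <- NULL
  removed$.row <- NULL
  list(kept = kept, removed = removed)
}

#' Fit the constrained categorical BMI-trend model for one sex
#'
#' Maximises the multinomial log-likelihood of the observed category counts
#' under a logit-linear structure in calendar year with additive age-group
#' offsets (normal weight is the reference category). Because predictions
#' go through the inverse multinomial-logit link, the three fitted
#' proportions total 100% at any year by construction.
#'
#' @param obs long survey data.frame.
#' @param sex `"male"` or `"female"`.
#' @param age_groups age-group table used to code the offsets; defaults to
#'   the groups present in `obs`.
#' @param weight_by_n weight surveys by their sample size (default TRUE);
#'   when FALSE all cells get the mean sample size.
#' @param interaction include year x age-group interaction terms.
#' @return an object of class `category_trend_model` with elements `coef`,
#'   `vcov`, `loglik`, `deviance`, `n_obs`, `reference`, `year_center`,
#'   `age_groups`, `sex`.
#' @export
fit_category_trends <- function(obs, sex, age_groups = NULL,
                                weight_by_n = TRUE, interaction = FALSE) {
  sex <- match.arg(sex, SEXES)
  if (is.null(age_groups)) {
    u <- sort(unique(obs$age_lo[obs$sex == sex]))
    hi <- sort(unique(obs$age_hi[obs$sex == sex]))
    age_groups <- make_age_groups(u, hi)
  }
  years <- unique(obs$year[obs$sex == sex])
  if (length(years) < 2) stop("need >= 2 distinct survey years")
  dat <- .survey_counts(obs, sex, age_groups, weight_by_n)
  tot <- colSums(dat$Y)
  if (any(tot <= 0)) {
    stop("category '", BMI_CATEGORIES[which(tot <= 0)[1]],
         "' absent in all cells for sex ", sex, ": separation")
  }
  year_center <- mean(range(dat$year))
  X <- .trend_design(dat$year, dat$group_idx, nrow(age_groups), year_center,
                     interaction)
  p <- ncol(X)
  ## moment start: empirical log-ratios per cell regressed is overkill;
  ## start from pooled log-odds with zero slopes/offsets
  start <- rep(0, 2 * p)
  start[1] <- log(tot[2] / tot[1])
  start[p + 1] <- log(tot[3] / tot[1])
  opt <- stats::optim(start, .multinom_negll, gr = .multinom_grad,
                      X = X, Y = dat$Y, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12),
                      hessian = TRUE)
  nm <- c(paste0("ow:", colnames(X)), paste0("ob:", colnames(X)))
  coef <- stats::setNames(opt$par, nm)
  vcov <- tryCatch(solve(opt$hessian), error = function(e) {
    MASS::ginv(opt$hessian)
  })
  dimnames(vcov) <- list(nm, nm)
  ## saturated log-lik for deviance
  Phat <- dat$Y / rowSums(dat$Y)
  ll_sat <- sum(dat$Y * log(pmax(Phat, 1e-300)))
  structure(list(sex = sex, coef = coef, vcov = vcov,
                 loglik = -opt$value, deviance = 2 * (ll_sat + opt$value),
                 n_obs = nrow(dat$Y), reference = "normal",
                 year_center = year_center, age_groups = age_groups,
                 interaction = interaction,
                 survey_years = sort(years),
                 converged = opt$convergence == 0),
            class = "category_trend_model")
}

#' @export
print.category_trend_model <- function(x, ...) {
  cat("Categorical BMI trend model (", x$sex, "), reference: ", x$reference,
      "\n", sep = "")
  cat("  cells:", x$n_obs, " deviance:", format(x$deviance, digits = 4), "\n")
  print(round(x$coef, 4))
  invisible(x)
}

## Predicted category proportions for vectors of years / age-group indices
## given a coefficient vector (enables bootstrap re-projection).
.model_props <- function(model, year, group_idx, coef = model$coef) {
  X <- .trend_design(year, group_idx, nrow(model$age_groups),
                     model$year_center, model$interaction)
  p <- ncol(X)
  softmax3(drop(X %*% coef[1:p]), drop(X %*% coef[(p + 1):(2 * p)]))
}

#' Project BMI category proportions over years and age groups
#'
#' @param model a fitted [fit_category_trends()] model.
#' @param years calendar years to evaluate (backcasts before the first
#'   survey year are allowed and flagged in the `backcast` attribute).
#' @param age_groups age-group table (defaults to the model's).
#' @return data.frame of class `projected_distribution` with columns
#'   `year, sex, age_lo, age_hi, p_normal, p_overweight, p_obese`.
#' @export
project_distribution <- function(model, years, age_groups = model$age_groups) {
  stopifnot(inherits(model, "category_trend_model"))
  grid <- expand.grid(g = seq_len(nrow(age_groups)), year = years)
  gidx <- age_group_index(age_groups$age_lo[grid$g], model$age_groups)
  P <- .model_props(model, grid$year, gidx)
  out <- data.frame(year = grid$year, sex = model$sex,
                    age_lo = age_groups$age_lo[grid$g],
                    age_hi = age_groups$age_hi[grid$g],
                    p_normal = P[, 1], p_overweight = P[, 2],
                    p_obese = P[, 3])
  attr(out, "backcast") <- sort(unique(years[years < min(model$survey_years)]))
  class(out) <- c("projected_distribution", "data.frame")
  out
}

#' Parametric-bootstrap confidence limits for projected proportions
#'
#' Draws coefficient vectors from the estimated multivariate-normal
#' coefficient distribution, re-projects each draw, and takes per-cell
#' 2.5/97.5 percentiles. Operating on the coefficient scale keeps every
#' band inside \[0, 1\] and bands widen with distance from the data
#' centroid.
#'
#' @inheritParams project_distribution
#' @param n_boot number of bootstrap draws; values below 200 trigger a
#'   warning but still run.
#' @param seed integer seed for the bootstrap stream.
#' @param level coverage level (default 0.95).
#' @return a `projected_distribution` with additional `lo_*` / `hi_*`
#'   columns per category; bands are guaranteed to contain the point
#'   estimate.
#' @export
projection_confidence_limits <- function(model, years,
                                         age_groups = model$age_groups,
                                         n_boot = 1000, seed = 1,
                                         level = 0.95) {
  if (n_boot < 200) warning("n_boot < 200: confidence limits will be noisy")
  set.seed(derive_seed(seed, "bootstrap"))
  out <- project_distribution(model, years, age_groups)
  draws <- MASS::mvrnorm(n_boot, model$coef, model$vcov)
  grid <- expand.grid(g = seq_len(nrow(age_groups)), year = years)
  gidx <- age_group_index(age_groups$age_lo[grid$g], model$age_groups)
  arr <- array(NA_real_, c(nrow(grid), 3, n_boot))
  for (b in seq_len(n_boot)) {
    arr[, , b] <- .model_props(model, grid$year, gidx, coef = draws[b, ])
  }
  a <- (1 - level) / 2
  qs <- apply(arr, c(1, 2), stats::quantile, probs = c(a, 1 - a), names = FALSE)
  pt <- as.matrix(out[, c("p_normal", "p_overweight", "p_obese")])
  for (k in 1:3) {
    cat_name <- BMI_CATEGORIES[k]
    out[[paste0("lo_", cat_name)]] <- pmin(qs[1, , k], pt[, k])
    out[[paste0("hi_", cat_name)]] <- pmax(qs[2, , k], pt[, k])
  }
  out
}
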