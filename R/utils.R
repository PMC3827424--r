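#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

## WHO adult BMI cut-offs (kg/m^2): normal < 25, overweight 25-29.99, obese >= 30
BMI_CUT_OVERWEIGHT <- 25
BMI_CUT_OBESE <- 30

BMI_CATEGORIES <- c("normal", "overweight", "obese")
SEXES <- c("male", "female")

#' Derive an independent child seed for a named RNG purpose
#'
#' One global seed drives independent per-purpose streams (survey noise,
#' population sampling, microsimulation, bootstrap), so e.g. changing the
#' number of microsimulation draws never alters the synthetic survey.
#'
#' @param seed integer master seed.
#' @param purpose one of `"survey"`, `"population"`, `"microsim"`,
#'   `"bootstrap"`, `"generic"`.
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, purpose = "generic") {
  offsets <- c(survey = 101L, population = 211L, microsim = 307L,
               bootstrap = 401L, generic = 0L)
  if (!purpose %in% names(offsets)) {
    stop("unknown RNG purpose: ", purpose)
  }
  (as.integer(seed) %% 1000000L) * 1009L + offsets[[purpose]]
}

#' Build an age-group table from closed ranges
#'
#' @param age_lo,age_hi integer vectors of equal length; ranges must be
#'   non-overlapping, ordered and start at 20 or later.
#' @return a data.frame with columns `age_lo`, `age_hi`, `label`.
#' @export
make_age_groups <- function(age_lo, age_hi) {
  stopifnot(length(age_lo) == length(age_hi), all(age_lo >= 20),
            all(age_hi >= age_lo))
  if (length(age_lo) > 1 && any(diff(age_lo) <= 0)) {
    stop("age groups must be ordered and non-overlapping")
  }
  data.frame(age_lo = as.integer(age_lo), age_hi = as.integer(age_hi),
             label = paste0(age_lo, "-", age_hi))
}

## Map single-year ages to age-group row index; ages above the last group's
## upper bound are clamped into the last group (open-ended oldest group).
age_group_index <- function(ages, age_groups) {
  idx <- findInterval(ages, age_groups$age_lo)
  idx[idx < 1L] <- NA_integer_
  idx
}

## Row-wise softmax over (0, eta_ow, eta_ob) -> 3-category proportions
softmax3 <- function(eta_ow, eta_ob) {
  m <- pmax(0, eta_ow, eta_ob)
  e0 <- exp(-m)
  e1 <- exp(eta_ow - m)
  e2 <- exp(eta_ob - m)
  s <- e0 + e1 + e2
  cbind(normal = e0 / s, overweight = e1 / s, obese = e2 / s)
}

## BMI category from continuous BMI values
bmi_category <- function(bmi) {
  ifelse(bmi >= BMI_CUT_OBESE, "obese",
         ifelse(bmi >= BMI_CUT_OVERWEIGHT, "overweight", "normal"))
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
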