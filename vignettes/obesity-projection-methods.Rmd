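---
title: "Projecting obesity-related disease burden: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting obesity-related disease burden: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obesitysim)
```

`obesitysim` implements a two-stage projection of the health and economic
consequences of population BMI trends, of the kind used in national
obesity forecasting exercises. Stage 1 fits a constrained categorical
regression to
sparse cross-sectional BMI survey series and projects the proportions of
adults in the WHO categories (normal < 25, overweight 25–29.99,
obese ≥ 30 kg/m²) to a horizon year. Stage 2 is an individual-level Monte
Carlo microsimulation that carries a synthetic population through time,
assigns each person a BMI trajectory consistent with the stage-1
projections, and simulates incidence of, survival with, and death from six
obesity-related chronic conditions (coronary heart disease & stroke,
obesity-related cancers, hypertension, type 2 diabetes, knee
osteoarthritis). Intervention scenarios reduce every individual's BMI by a
fixed percentage; outputs are obesity-attributable prevalence, cumulative
incidence, and direct healthcare costs, with indirect costs extrapolated
from a published direct:indirect ratio.

## Stage 1: the categorical trend model

For each sex, category proportions follow a three-category multinomial
logit, linear in calendar year, with additive age-group offsets:

$$
p_k(y, g) = \frac{\exp(\alpha_k + \beta_k (y - \bar y) + \gamma_{kg})}
                 {\sum_{k'} \exp(\alpha_{k'} + \beta_{k'} (y - \bar y) +
                  \gamma_{k'g})},
$$

with normal weight as the reference category
($\alpha = \beta = \gamma = 0$). The model is the simplest categorical
trend regression that satisfies the "proportions total 100%" constraint by
construction rather than by post-hoc renormalisation: any projected cell
sums to 1 to machine precision. The likelihood is the multinomial
likelihood of the observed category counts (proportion × cell sample
size), maximised by BFGS with an analytic gradient; the coefficient
covariance is the inverse observed information.

Design choices where the design was genuinely open:

* **Functional form.** "Non-linear multivariate regression" admits many
  forms; the multinomial logit linear in year is the standard categorical
  trend model and makes the generator's truth recoverable, so parameter
  recovery is a well-posed test.
* **Survey weighting.** Surveys are weighted by their sample size $n$
  (cells with larger $n$ carry more information); a flag
  (`weight_by_n = FALSE`) disables this, since some published series do
  not report comparable $n$.
* **Age.** Age enters as fixed offsets shared across years. An age × year
  interaction is identifiable only on dense series, so it is optional
  (`interaction = TRUE`) and off by default.
* **Sexes** are fitted independently throughout.

### Outlier screening

Survey points are screened against 95% prediction limits from a
preliminary per-(sex, category) binomial-logit trend fit. The limit
variance combines the fit's standard error on the logit scale with the
cell's binomial sampling variance, approximated on the logit scale by
$1/(n \hat p (1 - \hat p))$. A flagged category row removes its whole
(year, sex, age-group) cell, preserving the sum-to-one structure of what
remains. One filter–refit pass only: iterating the filter to convergence
can empty sparse strata. The reference distribution for such a rule is
not uniquely determined by the phrase "outside 95% confidence limits";
this choice is one defensible operationalisation, and on clean synthetic
data it flags roughly the nominal share of cells.

### Confidence limits

Projection bands come from a parametric bootstrap: coefficient vectors are
drawn from the estimated multivariate normal coefficient distribution,
re-projected, and summarised by per-cell 2.5/97.5 percentiles. Working on
the coefficient scale keeps every band inside [0, 1] (a delta-method band
on the proportion scale need not be) and bands widen with distance from
the data centroid, as extrapolation uncertainty should. Bands are clipped
to contain the point estimate, which matters only at extreme quantiles of
small bootstrap samples. The default 1,000 draws is cheap; below 200 the
percentiles are too noisy and the function warns.

## Converting epidemiological inputs

Some conditions are observed as prevalence, not incidence (in the
motivating application: hypertension, type 2 diabetes and knee
osteoarthritis). The zero-remission illness–death system

$$
S'(a) = -(i + m) S, \qquad C'(a) = i S - (m + f) C, \qquad
p(a) = \frac{C}{S + C}
$$

links incidence $i$, background mortality $m$ and excess case fatality
$f$ to prevalence $p$. `illness_death_forward()` integrates this system
over single-year ages using the exact solution with hazards held constant
within each year — not forward Euler — so refining the step (e.g. monthly)
changes nothing for piecewise-constant hazards, and the constant-hazard
closed form $p(a) = 1 - e^{-i(a - 20)}$ (when $f = m = 0$) is reproduced
to machine precision. `prevalence_to_incidence()` inverts the system age
step by age step with a bracketed root search (tolerance 1e-12) for the
non-negative $i(a)$ whose one-step projection matches the next observed
prevalence; a declining prevalence that no zero-remission model can
explain is clamped to $i = 0$ and the ages reported. Initial prevalence
at the youngest age is configurable and defaults to 0, the natural choice
for conditions rare before age 20.

Excess case fatality is derived from $n$-year survival under a constant
hazard: $f = -\log(s)/n$. Remission is fixed at zero for all six
conditions: the simulated life course is contract, survive or die, with
no recovery.

Category-specific incidence is calibrated from population incidence and
relative risks by
$i_{\text{ref}} = i_{\text{pop}} / \sum_k p_k RR_k$,
$i_k = RR_k \, i_{\text{ref}}$, using the baseline-year projected
category mix, so the mixture identity
$\sum_k p_k i_k = i_{\text{pop}}$ holds exactly.

## Stage 2: the microsimulation

Each simulated person carries sex, birth year and a **persistent uniform
rank** in (0, 1) drawn once at entry. Every simulated year the rank is
mapped through the quantile function of that year's (sex, age-group) BMI
distribution. This is the minimal construction that keeps an individual's
BMI status consistent within their cohort over time — a person at the 80th
BMI percentile stays at the 80th percentile — while the marginals follow
the stage-1 projection exactly. When the projected obesity share rises, a
fixed rank can only move up categories, never back.

The continuous BMI scale is a per-stratum lognormal whose two parameters
are solved in closed form from the two cut-point constraints
$P(\mathrm{BMI} < 25) = p_{\text{normal}}$ and
$P(\mathrm{BMI} < 30) = p_{\text{normal}} + p_{\text{overweight}}$. A
continuous scale is needed only so that percentage BMI reductions are
well-defined; any two-parameter right-skewed family anchored at the two
cut-offs would serve, and the lognormal is the conventional choice for
adult BMI.

Annual discrete time; hazards convert to probabilities by
$1 - e^{-h}$. The within-year event order is BMI update → disease
incidence → disease (case-fatality) death → other-cause death; the order
is a fixed constant and its effect is second order in the hazards.
Diseases evolve conditionally independently given BMI category. Each year
a fixed number of 20-year-old entrants joins (the expected size of a
single birth cohort in the supplied population structure), keeping the
inflow stationary; persons over age 100 leave the simulation. A person
cannot contract the same disease twice.

**Common random numbers.** Scenario runs share the seed, and uniform
draws are made every year for every person slot (dead persons included)
in a fixed order, so the draw streams stay aligned across scenarios.
Scenario contrasts (cases avoided, cost savings) are therefore
within-person differences with very low Monte Carlo variance, and the
scenario-dominance property holds person by person for disease onset.
One caveat is intrinsic to competing mortality, not to the random-number
scheme: a person who dies earlier under the baseline scenario can leave
an extra *prevalent* case of another disease in the intervention arm, so
raw prevalent counts can differ by a person or two in the "wrong"
direction. The obesity-attributable outputs — the model's actual outputs,
since the attributable fraction is itself strictly smaller under a BMI
reduction — are dominated as expected.

**Scenarios.** "Population BMI decreases by x%" is read as a
multiplicative shift of each individual's continuous BMI from the
scenario start year onward (scenario 1: ×0.99, scenario 2: ×0.95); the
alternative reading (shifting the prevalence of obesity by x%) is not
built, since it is ill-defined without a continuous scale. Categories are
re-derived from the shifted BMI, so a reduction changes outcomes only
through genuine category crossings.

**Attribution.** All simulation inputs are total-population figures;
outputs are converted to obesity-related figures with the Levin
population-attributable fraction
$\mathrm{PAF} = (\sum_k p_k RR_k - 1)/\sum_k p_k RR_k$, evaluated per
disease and year from the realised category shares of the simulated
population.

## Costing

Costing is prevalence-based: every obesity-attributable prevalent
case-year accrues the disease's annual unit cost (euro per case per
year), scaled to the whole population and reported in € millions by
calendar year. First-year cost premiums for incident cases are not
modelled. No discounting by default (costs are reported by calendar
year); a discount-rate knob exists. Indirect costs are a single ratio
extrapolation: direct costs × (published indirect / published direct),
defaulting to the Irish 2009 estimates of €729m indirect on €399m direct.
Report tables round to 3 significant figures; full precision is kept
internally.

## The synthetic-data generator

No national BMI survey microdata are bundled; the generator produces
inputs with the statistical structure the analysis assumes, so every
stage is testable offline.

* **Survey series**: truth proportions from the same multinomial-logit
  family stage 1 fits, observed cells drawn as multinomial counts. The
  default preset uses five survey years (1998, 2001, 2002, 2007, 2011 —
  the sparse, irregular spacing typical of national series), six decadal
  age groups from 20, and 1,200 respondents per cell. The default trend
  was calibrated once, numerically, so the population-weighted marginals
  match published Irish-style anchors: roughly 37% overweight / 24% obese
  in 2010, rising to 89% (males) and 85% (females) overweight-or-obese by
  2030 with obesity at 48% and 57% respectively.
* **Population and mortality**: ~3.4 million adults with a smoothly
  declining age structure; Gompertz all-cause mortality with a male
  excess.
* **Diseases**: five definitions covering the six conditions (CHD &
  stroke pooled, cancer sites pooled). CHD & stroke and cancer enter as
  incidence with excess fatality from 5-year survival (0.75 and 0.55);
  hypertension, type 2 diabetes and knee osteoarthritis enter as
  prevalence flagged for illness–death conversion — mirroring which
  inputs are typically only available as prevalence. Relative risks are
  field-typical published values (e.g. type 2 diabetes 2.4/6.0 for
  overweight/obese); unit costs are round annual figures (e.g. €9,000
  per CHD & stroke case-year).
* **Reproducibility**: one master seed drives independent per-purpose
  streams (survey noise, microsimulation, bootstrap), so changing the
  simulation size never changes the synthetic survey. Same seed, same
  spec is bit-identical.

What the generator does **not** emulate: self-report versus measured BMI
bias, survey design effects (clustering, post-stratification weights),
secular trends in disease risk independent of BMI, migration, and any
particular country's true cost structure (the default unit costs give a
different disease cost mix than any specific national costing — in
particular, cardiovascular disease does not dominate costs to the degree
some national analyses report). Tests passing on synthetic data therefore
validate the machinery — constraint satisfaction, parameter recovery,
conversion identities, dominance, determinism — not the realism of any
particular national projection.

## Problem sizes and runtime

Defaults are desk-scale: 50,000–100,000 simulated individuals stand in
for full national-scale Monte Carlo runs (per-100,000 outputs converge as
$1/\sqrt{n}$, and the test suite checks that scaling). The full default
pipeline (three scenarios, 21 years, bootstrap bands) runs in seconds;
parameter-recovery and coverage simulations in the test suite use 100–200
replicates.

## Known limitations

* Childhood BMI is out of scope; the adult projection conditions on an
  entry cohort at age 20 whose BMI follows the projected distribution.
* Disease interactions (e.g. diabetes raising CHD risk) are not
  modelled; conditions are independent given BMI.
* The outlier rule and the lognormal BMI family are defensible
  conventions, not identified features of the data.
* Cumulative incidence is normalised to the start-year population, so
  late-horizon values mix cohorts with entrants; this matches the
  standard "per 100,000 of baseline population" reporting convention.
* The indirect-cost ratio is a single national estimate applied uniformly
  over time; it inherits all the uncertainty of its source.
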