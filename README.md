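# obesitysim

Two-stage projection of the health and economic burden of population
obesity trends, for epidemiologists and health-economic modellers who need
a tested, reproducible version of the two-stage obesity projection
pipeline used in national burden-of-disease forecasting:

1. **Stage 1 — BMI trend projection.** A constrained categorical
   regression (three-category multinomial logit in calendar year with
   age-group offsets, fitted per sex by maximum likelihood on survey
   counts) projects the proportions of adults who are normal weight
   (< 25 kg/m²), overweight (25–29.99) and obese (≥ 30) to a horizon
   year. Proportions sum to 100% by construction; bands come from a
   parametric bootstrap of the coefficients.
2. **Stage 2 — chronic-disease microsimulation.** An individual-level
   Monte Carlo model carries a population through time. Each person holds
   a persistent uniform BMI rank mapped through the year-specific
   projected distribution (so BMI status within a cohort is consistent
   over time), and contracts, survives or dies from six obesity-related
   conditions — CHD & stroke, obesity-related cancers, hypertension,
   type 2 diabetes, knee osteoarthritis — with category-specific hazards
   calibrated from population incidence and relative risks:
   `i_ref = i_pop / Σ p_k RR_k`, `i_k = RR_k · i_ref`.

Around the core: illness–death (DisMod-style) conversion of prevalence
inputs to incidence under zero remission (`S' = −(i+m)S`,
`C' = iS − (m+f)C`), excess case fatality from n-year survival
(`f = −log(s)/n`), Levin attributable fractions
(`PAF = (Σ p_k RR_k − 1)/Σ p_k RR_k`) converting total-population tallies
to obesity-related outputs, intervention scenarios that multiply every
individual's BMI by 0.99 (scenario 1) or 0.95 (scenario 2) versus an
unabated scenario 0 under common random numbers, prevalence-based direct
costing in € millions, and indirect costs extrapolated by a published
direct:indirect ratio (€399m : €729m). A synthetic-data generator
produces Irish-style sparse survey series, population structures and
disease tables so the whole pipeline is testable without any restricted
national dataset.

See `vignettes/obesity-projection-methods.Rmd` for the full model
account.

## Worked example

```r
library(obesitysim)

spec <- generator_spec(seed = 1)          # Irish-like synthetic preset
cfg  <- pipeline_config(generator = spec, n_individuals = 50000,
                        seed = 1, out_dir = "run1")
bundle <- run_pipeline(cfg)
rep <- render_reports(bundle)
cat(rep$summary_lines, sep = "\n")
```

```
obesitysim pipeline summary
Horizon 2030; 50000 simulated individuals; seed 1
Overweight+obese at 2030: female 85.8%, male 87.6%
Obesity-related direct costs at 2030 (scenario 0): EUR 891 million
scenario_1: direct-cost saving at 2030 EUR 29 million
scenario_2: direct-cost saving at 2030 EUR 154 million
```

The first line is the stage-1 projection: the population-weighted share
of adults overweight or obese at the 2030 horizon, by sex. The cost line
is the stage-2 output: obesity-attributable direct healthcare costs
(prevalent cases × annual unit cost, whole-population scale) if trends
continue unabated; the savings lines compare the 1% and 5% BMI-reduction
scenarios against it under common random numbers.

```r
format_cost_table(bundle$costs$scenario_0)[, c("disease", "2010", "2030")]
#>              disease   2010   2030
#>           chd_stroke 35.300 409.00
#>               cancer  0.364   3.38
#>         hypertension  5.050 105.00
#>       type2_diabetes 15.500 315.00
#>  knee_osteoarthritis  2.910  59.40
#>                total 59.100 892.00

subset(bundle$avoided$scenario_2, year == 2030)[, c("disease", "avoided_per_100k")]
#>              disease avoided_per_100k
#>           chd_stroke            578.8
#>               cancer             99.2
#>         hypertension           2089.1
#>       type2_diabetes           1723.2
#>  knee_osteoarthritis            585.0
```

Costs are € millions per calendar year (3 significant figures in report
tables); avoided cases are cumulative obesity-related incident cases per
100,000 of the 2010 population that scenario 2 prevents by 2030. All
outputs are "obesity-related": total-population tallies scaled by the
year- and disease-specific attributable fraction.

A thin CLI wrapper with verbs `generate` / `project` / `simulate` /
`report` lives at `inst/scripts/obesitysim-cli.R`:

```sh
Rscript inst/scripts/obesitysim-cli.R report --n 50000 --seed 1 --out run1
```

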