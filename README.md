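# inductmod

An hourly-cycle Markov cohort model of labour induction from a hospital
resource-use perspective, comparing the misoprostol vaginal insert (MVI)
with the dinoprostone vaginal insert (DVI) in a parity-stratified cohort
of induced women.

Maternity units weighing induction methods need more than efficacy: a
product that shortens labour changes how many midwife shifts, examination
and monitoring events, and labour-suite bed hours a year of inductions
consumes. `inductmod` is for health-economics and midwifery-workforce
analysts who want those quantities from a transparent, fully testable
model rather than a spreadsheet.

## The model

For each stratum (arm × parity) the time to vaginal delivery is a
cumulative-incidence (sub-distribution) function with caesarean section as
a competing outcome,

    F_vd(t) = m · G(t | shape, scale),    m = 1 − Pr(caesarean),

where the two-parameter CDF `G` (Weibull by default; log-logistic and
piecewise-exponential available) is calibrated so that `F_vd` passes
*exactly* through the stratum's printed 12-hour and 24-hour
vaginal-delivery proportions (bisection on the shape, scale in closed
form, tolerance 1e-10). An hourly Markov trace then moves the cohort with
the conditional increments

    p_vd(t) = (F_vd(t+1) − F_vd(t)) / (1 − F_vd(t) − F_cs(t)),

through pre-active labour, a two-stage active labour (second stage capped
at one hour), delivery, inpatient stay and discharge. Downstream modules
convert state occupancy into midwife minutes (vaginal examinations,
vital-signs monitoring, oxytocin set-up), shifts, bed hours and days, ward
capacity, births-per-midwife ratios and expected adverse-event counts,
with a ±50 % deterministic sensitivity analysis, a continuous-monitoring
scenario, and a seeded individual-level micro-simulation that
cross-validates the deterministic trace within Monte-Carlo error.

## Worked example

```r
library(inductmod)

report <- run_pipeline(default_config(), mode = "base")
report$comparison
#> <comparison_result>
#>   hours to vaginal delivery: 37236 (DVI) vs 28800 (MVI); 8435 h saved (22.7%)
#>   per induction: 26.7 -> 20.6 h (saving 6.0 h)
#>   vaginal delivery within 12 h: 10.5% -> 21.7% (+107%); within 24 h: 35.0% -> 49.9% (+43%)
#>   prolonged labour (>24 h): 65% (DVI) vs 50% (MVI)
#>   midwife shifts: 183.8 (DVI) vs 150.7 (MVI); 33.1 saved (18.0%)
#>   bed hours: 37934 vs 29499; 8435 saved (351 bed days, 22.2%)
#>   additional inductions accommodated: 399; births per midwife: 33.0 -> 25.7
```

Reading this: switching the whole annual cohort of 1397 inductions from
DVI to MVI saves 8435 hours of time-to-vaginal-delivery per year (6.0 h
per induction), roughly doubles the share of women delivering vaginally
within 12 hours, frees about 33 eight-hour midwife shifts and 351 bed
days in the labour and delivery suite, and would let the same ward absorb
399 additional inductions. Adverse events move the other way:

```r
report$adverse_events$total_counts   #  DVI  MVI
#>  36 140
```

a 3.9-fold increase in treatment-related adverse events (+0.07 per
woman), dominated by uterine tachysystole. Sensitivity and scenario modes:

```r
run_pipeline(default_config(), mode = "dsa")$sensitivity       # ±50 % grid
run_pipeline(default_config(), mode = "scenario")$scenario     # continuous monitoring
run_pipeline(default_config(), mode = "validate")              # micro-simulation check
```

Configurations are YAML; the packaged base case ships at
`system.file("extdata", "basecase.yaml", package = "inductmod")` and
`load_config()` validates any edited copy before a run. A thin CLI
(`inst/scripts/inductmod-cli.R`) exposes `calibrate`, `run`, `dsa`,
`scenario`, `simulate` and `validate` subcommands.

The methods vignette (`vignettes/induction-resource-model.Rmd`) documents
the model's assumptions, every default with its rationale, the numerical
conventions, and the known limitation that two printed anchor proportions
per stratum under-determine the distribution tails, which makes the
hour-denominated annual savings conservative relative to analyses built on
the full (unpublished) individual-level curves.

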