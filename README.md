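# edsim — emergency-department patient flow, from arrivals to bed counts

`edsim` is an R package for capacity planning in hospital emergency
departments (EDs). It is written for health-systems analysts who need to
answer a concrete question — *how many stabilization beds does this ED need
before bed availability stops driving patient length of stay (LOS)?* — and
for methodologists who want the full experimental machinery behind such an
answer: demand modelling, forecast evaluation, discrete-event simulation
(DES), warm-up analysis and replication sizing, in one pipeline.

## What is inside

**Arrival model.** Hourly arrivals are a nonhomogeneous Poisson process
with rate

λ(t) ∝ hw(h) · wd(d) · sm(s) · hm^[holiday]

composed from hour-of-day weights (60% of daily volume on 17:00–24:00,
peak 20:00–23:00, trough 04:00–06:00), weekday weights (weekend days carry
19% of weekly volume each vs 13% for weekdays), season multipliers (fall
13% below winter) and a holiday uplift (holiday/normal hourly-rate ratio
5.45/3.31), renormalized so a non-holiday year averages 75 arrivals/day.
3-hourly weather covariates (seasonal sinusoid temperature, anticorrelated
humidity) complete the synthetic dataset.

**Forecasting toolkit.** Causal mean-arrival-rate feature (running mean of
past counts in the same hour × day-type slot), MAPE/MAE metrics
(zero-actual hours excluded from MAPE), a fit/predict model contract with
adapters for the usual learners, a 10-fold evaluation harness, exhaustive
wrapper feature selection (all 2^k − 1 subsets, cross-validated MAE), and
the recorded stateful-LSTM configuration (300 hidden units, Adam,
learning rate 5e-4, min–max scaling, ordered 80/20 split).

**ED simulation.** A discrete-event kernel (binary-heap event list, FIFO
capacitated resources, joint seize, UNIF/TRIA/constant/EXP samplers)
drives the patient route: triage UNIF(2,4) (ambulances skip it) → ED
physician TRIA(5,8,15) → lab/X-ray TRIA(15,30,45) with p = 0.7 → attending
specialty exam with p = 0.5 (split 22/17/13/11/37%, possible second lab
visit) → stabilization holding one **bed** and one attending jointly for
TRIA(30,60,120) → admitted (10%) or discharged. Common random numbers
across bed scenarios come from pre-drawing all patient-level randomness.

**Experiments.** Welch warm-up detection (cross-replication averaging,
day-scale smoothing window, 5% tolerance band), the sequential
replication-sizing procedure (δ(n, α) = t·√(s²/n), stop at δ/X̄ ≤ γ′), a
bed-capacity sweep with confidence intervals, and a 1% marginal-improvement
rule for the optimum bed count.

## A worked example

```r
library(edsim)

# one synthetic year of hourly ED arrivals
obs <- generate_observations(calendar_config(), horizon = 365 * 24, seed = 42)
arrival_report(obs)
#> <arrival_report> 8760 hours
#>   daily mean     : 77.12 arrivals/day
#>   weekend share  : 37.3%
#>   evening share  : 59.6% (hours 17-23)
#>   hourly rate    : holiday 5.26 vs normal 3.13 (ratio 1.68)
```

The report echoes the generator's calibration: ~75 arrivals/day plus the
holiday uplift, ~36–37% of arrivals on weekends, ~60% in the evening, and a
holiday/normal rate ratio near 1.65.

```r
# sweep the stabilization-bed capacity: 5 replications x 7500 h each,
# 29 h warm-up, common random numbers across scenarios
sweep <- bed_sweep(ed_config(), beds = 7:14, replications = 5,
                   hours = 7500, seed = 1)
as.data.frame(sweep)[, 1:4]
#>   beds n_reps mean_los    los_ci
#> 1    7      5 154.9503 1.4884202
#> 2    8      5 139.5931 1.0369957
#> 3    9      5 130.7928 0.7016364
#> 4   10      5 125.7338 0.5456607
#> 5   11      5 123.0085 0.4521822
#> 6   12      5 121.7000 0.3601642
#> 7   13      5 121.1232 0.2857556
#> 8   14      5 120.8855 0.2371037

find_optimum_beds(sweep)   # smallest b where bed b+1 improves LOS < 1%
#> [1] 12
autoplot(sweep)            # LOS and bed-queue curves vs bed count
```

Mean LOS falls steeply from 7 to 10 beds (155 → 126 min, driven almost
entirely by bed-queue waiting) and flattens beyond; the 1% marginal rule
declares saturation at 11–12 beds under the default synthetic demand. The
per-replication table is available via `tidy(sweep)`, a one-row summary via
`glance(sweep)`.

```r
# how many replications does a 10% relative precision need?
plan <- sequential_replications(
  function(i) collect_stats(run_one(i))$mean_los,  # your run function
  n0 = 2, alpha = 0.05, gamma_prime = 0.10)

# forecast-error harness on the synthetic year
tab <- build_feature_table(obs)
kfold_evaluate(model_mean_rate(), tab, k = 10, seed = 1)
```

## Layout

```
R/                  implementation (generator, features, selection,
                    forecasting, DES engine, ED model, experiments, I/O)
tests/testthat/     unit, property and acceptance tests
scripts/acceptance.R  headline-number reproduction script
vignettes/ed-capacity-planning.Rmd  methods vignette (models, defaults,
                    design decisions, limitations)
inst/cli/edsim.R    thin command-line wrapper (generate/features/select/
                    forecast/simulate/sweep/run-all)
```

The methods vignette documents every modelling assumption and default —
including where the synthetic conditions make particular reference
quantities irreproducible and why — and is the right place to start before
trusting any number the package prints.
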