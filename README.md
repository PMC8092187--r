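# stopsignal

Simulation and analysis of adaptive **stop-signal task (SST)** experiments in
R: session design, race-model cohort simulation, integration-method SSRT
estimation, consensus quality control, and cohort-level statistics.

## The scientific problem

The stop-signal task is the workhorse paradigm for measuring *response
inhibition*. Participants make speeded two-choice responses to go stimuli
(here: classifying food and control pictograms by colour), but on a minority
of trials (25%) a delayed stop-signal instructs them to withhold the
response. The stop-signal delay (SSD) is adapted by a 1-up/1-down staircase
(±50 ms, range 50–900 ms, start 200 ms, tracked separately per stimulus
category) that converges on ~50% stopping success.

Because the latency of stopping is unobservable, it is inferred under the
**independent horse-race model**: go and stop processes race, and a response
occurs iff the go process finishes before `SSD + T_stop`. The nonparametric
**integration method** recovers the stop-signal reaction time as

```
SSRT = Q_go( p(respond | signal) ) − mean(SSD)
```

where `Q_go` is the go-RT quantile at rank `ceil(p · n_go)` (go omissions
replaced by the participant's maximum go RT before ranking) and `mean(SSD)`
averages all of the category's stop trials. Smaller SSRT = better inhibitory
control. Research questions of the kind this package targets: does a gamified
task variant preserve the association between SSRT and health covariates such
as BMI (overweight = BMI ≥ 25 kg/m²)?

Since raw data from such studies are typically not public, the package ships
a **synthetic cohort generator**: ex-Gaussian go finishing times, truncated
Gaussian stop latencies, go-omission and choice-error lapses, and additive
covariate effects (task condition, overweight, age) on person-level means,
calibrated by a transparent configuration object.

## Worked example

```r
library(stopsignal)

res <- run_pipeline(run_config(seed = 42))

res$report$qc$n_included
#> [1] 98

subset(res$anova_ssrt, effect %in% c("age", "group", "overweight"))
#>       effect numDF denDF         F            p
#> 1        age     1    93  38.86766 1.316731e-08
#> 2      group     1    93 106.98207 0.000000e+00
#> 3 overweight     1    93  22.21347 8.533225e-06

res$report$group_means
#>         group mean_go_rt_ms  ssrt_ms
#> 1    gamified      816.8008 397.5445
#> 2 nongamified      647.1641 300.5177

res$correlation
#> r = 0.083, 95% CI [-0.058, 0.220], N = 196, p = 0.2494
```

Reading the output: a 100-person two-arm cohort was simulated (48 gamified /
52 nongamified, ~30% overweight); QC kept 98 participants (2 implausible
self-reported heights). The mixed model (random intercept per subject;
`value ~ age + group × overweight × stimulus`, containment df) recovers the
simulated condition effect on SSRT (gamified ≈ 398 ms vs nongamified ≈
300 ms) and the overweight effect; the BMI–SSRT product-moment correlation
over 196 participant × category records is small and positive, as the default
calibration (overweight shifts SSRT by +35 ms) implies.

The a-priori power analysis for a one-sided correlation test uses the exact
sampling distribution of r under bivariate normality:

```r
required_n_correlation(rho = 0.35, alpha = 0.05, power = 0.80, sided = "one")
#> [1] 49
required_n_correlation(rho = 0.35, sided = "one", method = "fisher")
#> [1] 50   # the common Fisher-z closed form is slightly conservative
```

## Command line

Every pipeline stage is exposed as a subcommand over plain CSV/JSON schemas
(see `?write_trial_log`, `?run_config`):

```sh
Rscript inst/cli/sst.R run      --out out/ --seed 42
Rscript inst/cli/sst.R simulate --out sim/ --seed 1
Rscript inst/cli/sst.R estimate --trials sim/trials.csv --out estimates.csv
Rscript inst/cli/sst.R qc       --trials sim/trials.csv \
                                --participants sim/participants.csv --out qc/
Rscript inst/cli/sst.R analyze  --estimates qc/estimates.csv \
                                --participants sim/participants.csv \
                                --out report.json
Rscript inst/cli/sst.R power    --rho 0.35 --alpha 0.05 --power 0.8 --sided one
```

A run is reproducible from the JSON config plus a seed alone; every report
carries the seed and an order-stable configuration hash.

## Documentation

The methods vignette (`vignettes/stop-signal-methods.Rmd`) describes the
generative model, estimator conventions, QC rules, statistical choices and
their limitations in detail.
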