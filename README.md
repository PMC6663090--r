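# weathercrime

Causal analysis of weather effects on daily crime counts, for
criminologists, environmental epidemiologists, and anyone who wants the
weather–crime relationship expressed as an experiment rather than a
regression slope.

The package reconstructs *hypothetical randomized experiments* from daily
weather and crime-incident tables.  Days are segmented by heat-index class
(Negative [−18, 0] °C, Mild (0, 24] °C, High (24, 35] °C, plus a rain/dry
experiment), assigned binary exposure arms by the threshold rule
W_i = 1{Z_i > T} (T = class-mean heat index; 0 mm for rain), and matched
one-to-one on a caliper around the estimated propensity score — without
ever reading an outcome column.  The estimand is the finite-population
average exposure effect over the N matched days,

    AEE = (1/N) Σ [Y_i(1) − Y_i(0)] = Ȳ(1) − Ȳ(0),

where Y_i(1), Y_i(0) are the day's potential crime counts under exposure
and control.  The missing half of each pair is multiply imputed from
per-arm Bayesian negative-binomial regressions (NB2, log link; priors
β₀ ~ N(0,5), slopes ~ N(0,2.5), φ ~ Half-Cauchy(0,5); 20,000 MCMC
iterations with 10,000 burn-in by default), giving a posterior for the
AEE with an equal-tailed 95% interval.  A synthetic-data generator stores
*both* potential outcomes per day, so the whole pipeline can be validated
against exact ground truth.

## Worked example

Generate a confounded synthetic city (exposure follows the heat-index
threshold rule, so warm-season days are over-represented in the exposed
arm), run the design and analysis stages, and compare against the stored
truth:

```r
library(weathercrime)

cfg   <- synthetic_config(n_days = 600, seed = 7)   # tau = 0.2 by default
synth <- generate_synthetic(cfg)
spec  <- synthetic_experiment(cfg)                  # models matched to the generator
rc    <- run_config(study = synth$study, experiments = list(SynthHI = spec),
                    mcmc = nb_mcmc(2000, 1000, chains = 2),
                    imputations = 500, seed = 7)
bundle <- run_experiment(rc, "SynthHI")
```

The run logs each stage:

```
[exposure] threshold = 13.071; 195 exposed, 173 control, 232 excluded
[design] propensity model ~Summer + Winter + Weekend + Friday + Wind + Rain; 48 outlying day(s) trimmed
[design] matched 92 pairs (caliper 0.3678), 84 unmatched exposed
[design] balance: max |SMD| after matching = 0.159
[outcome] per-arm NB fits: max split-Rhat = 1.006 (sampler: independence)
[aee] AEE = 3.189 [1.590; 4.903], N = 184 matched days
```

Matching repairs the seasonal confounding — the Summer standardized mean
difference drops from 1.44 before matching to 0.00 after — and the
posterior brackets the exact matched-set truth while the naive
difference-in-means is badly biased:

```r
bundle$aee
#> AEE (violent): 3.19 [1.59; 4.90] over N = 184 matched days
truth_aee(synth, c(bundle$matched$pairs$exposed_date,
                   bundle$matched$pairs$control_date))
#> [1] 3.423913
bundle$naive_estimate
#> [1] 6.283029
absolute_change(bundle$aee, 30)$change   # 30 exposed-for-control days
#> [1] 95.66875
```

So ~3.2 additional violent crimes per day (truth 3.42), versus a naive
estimate of 6.28; over 30 days that is roughly 96 additional crimes.
`absolute_change(1.88, 30)$change` reproduces the familiar 56.4
back-of-envelope for a printed per-day effect of 1.88.

Real data enter through `read_weather()` / `read_crimes()` (CSV, with
configurable column maps for NOAA-style and city-portal-style schemas),
`build_study_table()`, and `boston_experiments()`, which ships the four
experiment definitions with their selected propensity-score and outcome
formulas.  `run_all()` executes the whole catalog; a thin command-line
wrapper with `prepare` / `simulate` / `design` / `estimate` / `run-all`
subcommands lives at `inst/cli/weathercrime.R`.

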