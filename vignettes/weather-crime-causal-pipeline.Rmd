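---
title: "Estimating weather effects on daily crime counts by matched design and Bayesian imputation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating weather effects on daily crime counts by matched design and Bayesian imputation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Does apparent temperature — or rainfall — change how many violent crimes a
city records in a day?  Associational regressions answer a different
question: they describe how crime counts co-vary with weather after
"controlling" for confounders, and they extrapolate freely across days whose
covariate profiles never co-occur.  `weathercrime` instead treats each
calendar day as a unit in a hypothetical randomized experiment.  Every day
$i$ has two potential outcomes: $Y_i(1)$, the crime count it would have
produced under exposure (for instance a heat index above the threshold), and
$Y_i(0)$ under control.  Only one of the two is observed.  The estimand is
the finite-population average exposure effect over the $N$ analyzed days,

$$\mathrm{AEE} = \frac{1}{N}\sum_{i=1}^{N}\bigl[Y_i(1) - Y_i(0)\bigr]
             = \bar Y(1) - \bar Y(0),$$

and inference proceeds by imputing the missing half of each pair from a
Bayesian model.  Interpretation is deliberately restricted to the days that
survive the design stage — no dose–response curve, no extrapolation beyond
the support of the matched data.

The package assumes SUTVA at the day level: a day's crime count depends on
its own weather exposure, not on other days' exposures.

## Exposure design

Days are segmented into heat-index classes — Negative $[-18, 0]$ °C, Mild
$(0, 24]$ °C, High $(24, 35]$ °C — and a fourth experiment contrasts rainy
with dry days.  Within a class, the exposure indicator is
$W_i = \mathbf{1}\{Z_i > T\}$ where $Z_i$ is the day's heat index and $T$ is
the class mean heat index (exactly 0 mm for the rain experiment).  Ties go
to control, since the inequality is strict.  `boston_experiments()` ships
the catalog; `pin_thresholds = TRUE` pins the rounded cuts $-4$, $12$,
$27$ °C instead of data-derived class means, which is useful when
reproducing published subgroup labels exactly.

The heat index is computed from air and dew-point temperature via the NWS
procedure: relative humidity from the Magnus saturation-vapor-pressure
ratio, the simple low-temperature formula first, and the Rothfusz
regression with the dry-air ($RH < 13\%$) and high-humidity ($RH > 85\%$)
adjustment terms once the simple value reaches 80 °F.  Computation is in
Fahrenheit internally, Celsius at the interface.

## The design stage is outcome-blind

The design stage reconstructs a randomized experiment while never reading a
crime count; `design_table()` physically drops the outcome columns, so the
blindness is enforced by the interface rather than by discipline.

1. **Propensity estimation.** Logistic regression of $W$ on background
   covariates (season flags, Friday, Weekend, first/fifteenth/last day of
   month, snow, holidays, events, wind; rain occurrence in the heat
   experiments, heat index in the rain experiment).  Per-experiment
   formulas ship with the catalog; `stepwise_aic()` re-derives one by
   bidirectional stepwise search from the intercept model when asked.
   A model with zero residual deviance has perfectly separated the arms —
   no maximum-likelihood estimate exists — and is rejected with advice to
   reduce the formula.  Constant columns are dropped with a warning.
2. **Overlap trimming.** Controls whose estimated score falls outside the
   exposed score range are discarded as outlying days, and vice versa, in
   one pass over the original ranges.  We deliberately do *not* iterate
   these rules to a fixed point: with near-separated cells (say, one
   warm-season control at the top of the score range) iteration cascades —
   removing a single boundary day unravels an entire covariate cell and can
   empty an arm.  One pass is also what the overlap-assessment step of a
   matched design classically does.
3. **Caliper matching.** Greedy one-to-one nearest-neighbor matching
   without replacement on the logit score scale.  Exposed days are
   processed in descending score order (hardest-to-match first), each
   taking the closest remaining control within the caliper; equidistant
   candidates are broken by a seeded draw so results are reproducible.
   The default caliper is $0.2$ standard deviations of the logit score,
   the Rosenbaum–Rubin convention; it is a tuning constant, not an
   estimate, and is exposed in the configuration.
4. **Balance diagnostics.** Standardized mean differences per covariate,
   with the pooled standard deviation computed once on the pre-matching
   sample and reused afterwards so before/after values share a scale.
   The exposure variable itself (heat index in the heat experiments, rain
   in the rain experiment) is excluded from the report — it defines the
   arms and is imbalanced by construction.  A post-matching
   $|\mathrm{SMD}|$ above the configurable threshold (default 0.1)
   triggers a prominent warning; the run continues, because residual
   imbalance is further adjusted by the outcome models.

## Outcome models and imputation

Within the matched sample, each arm gets its own Bayesian
negative-binomial regression,

$$Y_i^{\mathrm{obs}} \sim \mathrm{NB}(\mu_i, \phi),\qquad
  \mu_i = \exp(\beta^\top X_i),$$

in the NB2 parameterization ($\mathrm{Var} = \mu + \mu^2/\phi$), with
weakly informative priors $\beta_0 \sim N(0,5)$, slopes $\sim N(0,2.5)$
applied to standardized continuous covariates (binary covariates
unscaled; the standardization is stored and reapplied at prediction
time, and can be turned off), and $\phi \sim$ Half-Cauchy$(0,5)$.
Fitting the two arms separately keeps the imputation of exposed days'
missing outcomes untouched by control-day data and vice versa.

The default budget is 20,000 iterations with 10,000 burn-in split over
4 chains, retaining 10,000 draws.  The sampler is an independence
Metropolis–Hastings kernel: a multivariate-$t$ proposal built from the
Laplace approximation at the joint posterior mode of $(\beta, \log\phi)$.
For log-concave-like posteriors of this size the proposal is close to the
target, acceptance sits around 70–80%, and the retained draws are nearly
independent — which is what makes the reduced-budget simulation studies
below affordable.  If acceptance drops below 10% the fit falls back to a
random-walk kernel with the same covariance.  Split-$\hat R$ and an
autocorrelation-based effective sample size are reported for every
parameter; any $\hat R > 1.05$ flags the fit with a warning.  With zero
data rows the "posterior" is the prior and is sampled directly.

Outcome-covariate sets can be chosen by leave-one-out cross-validation:
`loo_select()` scores candidates by PSIS-LOO (Pareto-smoothed importance
sampling, with the Zhang–Stephens generalized-Pareto tail fit), falls
back to exact leave-one-out refits for observations whose tail shape
$\hat k$ exceeds 0.7, and breaks ties toward fewer terms, then input
order.

Imputation replication $r$ uses parameter draw $r$ — no re-sampling of
parameters — the standard simulation scheme for finite-population
estimands: for a control day, $Y_i(1) \sim \mathrm{NB}(\exp(\beta_t^{(r)\top}
X_i), \phi_t^{(r)})$ from the exposed-arm posterior, and symmetrically for
exposed days.  Observed potential outcomes are carried through unchanged
in every replication.  Each replication yields one AEE value; the
posterior summary is the mean (median available by configuration) and the
equal-tailed 95% percentile interval.  Equal-tailed rather than
highest-density is an assumption, chosen as the common default convention;
the full draw vector is returned so either can be recomputed.

## Synthetic data with stored ground truth

`generate_synthetic()` draws a Boston-like daily series: a sinusoidal
annual temperature cycle (mean 10.5 °C, amplitude 13.5 °C, peak near day
200, daily noise SD 3.5 °C) with an exponential dew-point offset (mean
4 °C), season-dependent rain occurrence (~30–35%), gamma wind, and
calendar covariates derived by the same builder the real-data path uses.
Both potential outcomes are drawn and stored per day:
$Y_i(0) \sim \mathrm{NB2}(\exp(\alpha + \gamma^\top X_i), \phi)$ and
$Y_i(1)$ with $\tau$ added to the log mean.  Defaults: baseline
$\alpha = \log 18$ daily violent crimes, seasonal and calendar effects
$\gamma$ (Summer $+0.25$, Winter $-0.20$, Weekend $+0.10$, Friday
$+0.05$, Wind $-0.01$ per unit), dispersion $\phi = 10$, exposure effect
$\tau = 0.2$ — a realistic 22% multiplicative increase.  Aggravated
assaults are a binomial thinning (rate 0.25) of the violent counts, so
they never exceed them; larceny is an independent NB series.

Exposure realization has two modes.  `"threshold"` applies the same
class-mean rule the design stage uses, so exposure depends on the heat
index and therefore on season — confounding is ON and the naive
difference in observed means is biased.  `"randomized"` flips a fair
coin per day — confounding OFF.  `truth_aee()` evaluates the exact
finite-population AEE of any day subset, which is precisely the estimand
the pipeline targets after matching.

What the generator does *not* emulate: weather autocorrelation beyond
the seasonal cycle, spatial structure in incidents (zip areas are
uniform-multinomial), reporting artifacts (duplicate or late-filed
incidents), and long-term crime trends.  Passing the validation studies
therefore shows the estimator is correct under its own assumptions — it
does not certify those assumptions for any particular city's data.

## Validation studies

Two simulation studies back the test suite; sizes were chosen to make
the estimator's properties visible while keeping a default test run
comfortably interactive.

* **Recovery and bias reduction** — 20 confounded datasets of 1,200 days
  ($\tau = 0.2$), pipeline at a reduced budget of 2,000 iterations /
  1,000 burn-in with 1,000 imputations.  The posterior mean should land
  within 3 posterior SDs of the matched-set truth in at least 18 of 20,
  and beat the naive difference-in-means in absolute error in at least
  15 of 20.
* **Coverage** — 100 confounded datasets of 600 days, 500 imputations,
  same reduced budget.  Empirical coverage of the equal-tailed 95%
  interval must be statistically compatible with 0.95 (binomial test,
  $\alpha = 0.01$).  A representative run gives 94%.

```{r}
library(weathercrime)
cfg <- synthetic_config(n_days = 600, seed = 7)
synth <- generate_synthetic(cfg)
spec <- synthetic_experiment(cfg)
rc <- run_config(study = synth$study, experiments = list(SynthHI = spec),
                 mcmc = nb_mcmc(2000, 1000, chains = 2),
                 imputations = 500, seed = 7)
bundle <- run_experiment(rc, "SynthHI")
bundle$aee
truth_aee(synth, c(bundle$matched$pairs$exposed_date,
                   bundle$matched$pairs$control_date))
```

## Numerical and design notes

* Ties $Z_i = T$ are controls (strict inequality), and the Mild/High
  class bounds are half-open on the left, so the three classes partition
  the heat-index axis.
* Negative precipitation being impossible, "dry" is defined as exactly
  0 mm and "rainy" as strictly positive.
* Missing weather days are excluded and logged, never imputed: exposure
  is a design quantity, not a modeling target.
* Incident timestamps are attributed to days by their local date
  (configurable time zone, default America/New_York).
* One global seed fans out deterministically to the matching, per-arm
  MCMC, and imputation stages, so identical configurations reproduce
  bit-identical results and partial reruns are consistent.
* The linear predictor is capped at 30 on the log scale before
  exponentiation to keep early MCMC proposals from overflowing.
* Aggravated assaults count both in their own exploratory outcome and in
  the violent-crime total; conservation holds as violent + larceny +
  ignored = total incidents.

## Limitations

Greedy caliper matching is order-dependent and not optimal matching; the
package makes the order explicit and seeded rather than pretending
otherwise.  The caliper width, matching order, and replacement policy
are conventions, not estimates.  Per-zip summaries are descriptive means
only — no zip-level causal effects are estimated.  The Bayesian
intervals are calibrated under the NB2 outcome model; gross
misspecification of the outcome distribution (for example strong
zero-inflation) is outside the model family and would need a different
likelihood.
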