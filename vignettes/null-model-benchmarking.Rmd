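---
title: "Benchmarking adaptive harvest management forecasts against ecological null models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking adaptive harvest management forecasts against ecological null models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahmnull)
```

## The problem

Adaptive harvest management (AHM) of midcontinent mallards sets annual
harvest regulations by carrying a small set of mechanistic population
models, forecasting next spring's breeding abundance with each, and
updating a probability weight on each model by Bayes' theorem when the
new survey estimate arrives. Directional movement of those weights is
often read as learning about the underlying biology. That reading is only
safe if at least one candidate actually forecasts well: if every model is
misspecified, the weights merely identify the best of a bad bunch.

`ahmnull` operationalizes a benchmark for that situation. It runs the AHM
candidate set side by side with *ecological null models* — models that
preserve a basic pattern of the system but contain none of the vital-rate
mechanisms — and scores every model on out-of-sample, one-step-ahead
forecasts. A mechanistic model that cannot out-forecast a null provides
no evidence that its mechanism matters.

## The candidate models

### The AHM balance equation

Spring abundance \(N_t\) (millions of birds) is projected one year ahead
through an age–sex structured balance equation:

\[
N_{t+1} = \gamma_S N_t \Big[\, m\,S_{t,am} + (1-m)\big(S_{t,af} +
\gamma_R R_t\,(S_{t,jf} + S_{t,jm}\,\phi^{sum}_f/\phi^{sum}_m)\big) \Big]
\]

with \(m\) the male proportion of the breeding population, \(S_{t,\cdot}\)
annual survival of adult/juvenile males/females, \(R_t\) the reproductive
rate (young per adult female), and \(\gamma_S,\gamma_R\) optional bias
corrections (defaults 1). Recruitment is nested inside the female share so
recruits scale with the number of adult females; published renderings of
the equation are typographically ambiguous on this grouping, and this form
follows the standard agency usage.

Survival responds to the kill rate \(K = h/(1-c)\) (harvest rate \(h\)
inflated by crippling loss \(c\)) under two hypotheses:

* **additive** (\(S_a\)): \(S = s_0(1-K)\);
* **compensatory** (\(S_c\)): the completely-compensatory threshold form
  \(S = s_0\) for \(K \le 1-s_0\), else \(S = 1-K\).

Reproduction is linear in abundance and standardized wetland availability,
truncated at zero: \(R_t = \max(0,\, a_0 + a_1 N_t + a_2 W^{std}_t)\).
The **weak** and **strong** density-dependence hypotheses share this form
and differ only in the magnitude of \(a_1\) (package defaults −0.05 and
−0.15 per million birds; these and all other submodel coefficients are
illustrative synthetic values, not official agency estimates, and are
fully configurable). Crossing the two survival with the two reproduction
hypotheses gives the four candidates `SaRw`, `SaRs`, `ScRw`, `ScRs`.

Each AHM forecast is wrapped in a lognormal predictive distribution whose
median is the balance-equation output and whose log-scale sd is the
process noise (`process_sd`, default 0.05); when the abundance series
carries survey SEs the most recent SE is added on the variance scale of
the log-normal approximation.

### The ecological null models

* **Population persistence**: \(N_{t+1} = N_t + \varepsilon_t\),
  \(\varepsilon_t \sim N(0,\sigma^2)\). The predictive mean is exactly the
  last observation; \(\sigma\) is the sample sd of all one-step
  differences in the history (additive, on the millions scale, matching
  the model's additive error form). This is the "tomorrow resembles
  today" benchmark borrowed from meteorology.
* **Wetland-driven growth**: \(N_{t+1} = \lambda_t N_t\),
  \(\log \lambda_t = r_{eq} + \beta W^{std}_t + \varepsilon_t\) with the
  equilibrium growth rate \(r_{eq}\) fixed at 0 (no intercept is
  estimated). The regression of log growth on standardized wetlands is fit
  by a conjugate normal–inverse-gamma model
  (\(\beta \mid \sigma^2 \sim N(0, 100\,\sigma^2)\),
  \(\sigma^2 \sim IG(0.01, 0.01)\) by default), so the posterior
  predictive — a Student-t on the log scale — carries parameter
  uncertainty into scoring and weight updating. A plug-in least-squares
  fit would understate forecast spread, which matters because the
  predictive density drives the Bayes weights.

The log-scale Student-t has no finite moments after exponentiation, so
forecast records store abundance-scale mean/sd from a variance-matched
normal approximation of the log-scale t; weight updating always evaluates
the exact t density. Until the wetland model has three growth
observations its forecast defers to persistence (the two models then have
identical information sets, and degenerate two-point fits are avoided).

## Wetland standardization

The wetland covariate is standardized to mean 0, sd 1 (sample sd, n−1
denominator throughout). Two conventions are provided because the
forecasting context makes the choice consequential:

* **recursive** (pipeline default): the z-score for year *t* uses the
  mean/sd of years ≤ *t* only, so a forecast made at *t* never sees
  future pond counts. Years with fewer than two observations of history
  (or a zero expanding sd) are `NA` and simply cannot support a
  wetland-dependent forecast.
* **fixed baseline**: constants computed once over a stated window,
  mimicking a published-constants workflow. A zero baseline sd is a hard
  error.

The synthetic-data generator uses the fixed whole-series convention for
the truth it simulates (a generator may legitimately know its own series),
and the recovery tests fit with the same convention so the regressor
matches the generating one; the forecasting pipeline stays recursive.

## Evaluation design

`run_one_step_ahead()` produces, for every target year in the evaluation
window and every model, a forecast built strictly from data through the
previous year (an expanding window; the no-look-ahead property is tested
by mutating future data and asserting bitwise-identical forecasts).
Skill is scored on the predictive mean — RMSE-type scores are minimized
by the mean, so scoring the median would handicap the asymmetric
lognormal forecasts:

* **NRMSE** = RMSE / mean(observed): accuracy, balancing bias and
  precision, unit-free;
* **NMSD** = mean(predicted − observed) / mean(observed): signed
  systematic bias, the tell-tale of misspecification. The sign convention
  (predicted − observed) makes chronic underprediction negative.

Benchmark ratios divide each model's |NMSD| (and NRMSE) by the designated
null's; "k times better" claims are magnitude-based because NMSD is
signed. Scores use only years where every compared model has a forecast
and an observation exists (gap years — e.g. a missed survey — are
forecast but never scored, and a year whose information set ends in a gap
is skipped rather than bridged by interpolation).

Model weights start uniform (0.25 across the four AHM models: complete
structural uncertainty) and are updated each scored year by Bayes'
theorem using each model's predictive density at the observation,
accumulated in log space. Sequential updating equals a single batch
update with the product of densities, and the suite checks this identity
to 1e-10. The model-averaged AHM forecast for year *y* uses the weights
available at the *start* of year *y* (posterior through *y*−1) — the
information a decision-maker would actually hold when issuing the
forecast. Weights may collapse to ~0 with no floor by default; degenerate
sd-0 forecasts are handled as point masses with a loud warning.

## The synthetic-data generator

Because the real survey series is an external download, the package
generates study data with the statistical structure the analysis assumes:

* latent abundance propagated by any candidate model (the four AHM
  models, persistence, or wetland-growth) with multiplicative lognormal
  process noise (`process_sd` 0.05);
* a stationary AR(1) pond series on the log scale (median 4 million
  ponds, autocorrelation 0.7, innovation sd 0.25), initialized from its
  stationary distribution;
* i.i.d. truncated-normal harvest rates per age–sex class (means 10/7/15/10%
  for adult male/adult female/juvenile male/juvenile female, sd 0.02,
  truncated to [0, 0.35)); there is no harvest-policy feedback on
  density, so the real system's confounding between harvest rate and
  abundance is deliberately absent;
* multiplicative lognormal observation error with CV 0.05, emulating the
  survey's reported precision (additive normal available).

Default submodel values (survival in the absence of hunting 0.85/0.75/
0.80/0.70 by class, crippling loss 0.2, reproduction intercepts 1.00 weak
/ 1.75 strong, wetland slope 0.2, male proportion 0.55, summer-survival
ratio 0.9) put the deterministic equilibria of the weak and strong models
at roughly 9.5 and 8.2 million birds under mean harvest — the scale of
the real breeding population. Simulations start at 8 million.

What passing tests on these data do and do not show: they demonstrate
that the pipeline's estimation, scoring and weight updating are correct
and self-consistent (the generating model is identified, known
coefficients are recovered, nulls beat structurally mismatched
mechanisms). They do not validate the synthetic coefficient values
against the real system, and the generator omits known features of the
real data — density-linked harvest regulation, survey design changes,
age structure in observation error — so quantitative skill levels here do
not transfer to the USFWS series.

## Numerical choices and edge cases

* Latent abundance leaving [1e-3, 1e3] million aborts a simulation,
  naming the year (unstable parameterization rather than silent overflow).
* A kill rate ≥ 1 (harvest rate too close to 1 for the crippling loss) is
  a hard error, as is a nonpositive balance-equation output.
* Persistence needs ≥ 2 years of history; with a single difference the
  forecast sd is that difference's absolute value.
* With every model's likelihood underflowing to zero at an observation,
  weight updating stops with a diagnostic rather than renormalizing noise.
* All randomness flows from one integer seed per scenario; sub-series
  (wetlands, harvest, process, observation) use fixed offsets of it so a
  stand-alone `simulate_wetlands()` call reproduces the wetlands embedded
  in a full bundle.

## Typical problem sizes

The shipped tests and the acceptance script use series of 30–100 years,
evaluation windows of 20–40 one-step-ahead forecasts, 20 replicates for
majority-vote learning checks and 50 replicates for coverage checks —
sizes at which the qualitative results (self-consistency of learning,
null-model advantage under structural mismatch, ±2-sd coverage of the
wetland coefficient) are stable across seeds.

## Known limitations

* Submodel coefficients are synthetic defaults; reproducing the official
  AHM weight trajectory would require the agency parameterizations and
  bias-correction values, which are inputs, not outputs, of this package.
* Only one-step-ahead forecasting is supported; harvest rates and pond
  counts are inputs (or simulated), never forecast.
* Scoring is for point forecasts (NRMSE/NMSD); probabilistic scores such
  as CRPS are out of scope, though every forecast record carries a full
  predictive distribution that would support them.
* Whether the official updating machinery folds survey observation error
  into the likelihood is configurable here (`use_obs_error`), not
  asserted.

## A worked run

```{r, eval = FALSE}
library(ahmnull)
spec <- scenario_spec(generator = "SaRw", n_years = 50, seed = 1)
bundle <- simulate_population(spec)
res <- run_pipeline(bundle, eval_years = c(1990, 2029))
as.data.frame(res$skill)
tail(res$weights, 1)
plot_forecasts(res)
```

On these data the generating model `SaRw` attains the lowest NRMSE and
essentially all of the final weight, while the persistence null shows the
smallest |NMSD| among the misspecified candidates — the package's
self-consistency checks in miniature.
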