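---
title: "Models and methods for delivery-care coverage trends, projections and inequalities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for delivery-care coverage trends, projections and inequalities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(delivcov)
library(dplyr)
```

delivcov estimates and projects national coverage of two delivery-care
indicators among adolescent mothers (aged 15–19) in low- and middle-income
countries: institutional delivery (INSD, the most recent live birth
delivered in a health facility) and skilled birth attendance (SBA, delivery
attended by a doctor, nurse or midwife). Inputs are sparse, irregular
survey series of the DHS/MICS type — a handful of coverage estimates per
country over 2000–2019 — and the package's job is to turn them into smooth
country trajectories with credible intervals out to 2030, plus the
inequality and individual-level determinant analyses that usually accompany
such coverage work.

This vignette documents the models, their assumptions, the numerical
choices, and what the synthetic-data validation does and does not
demonstrate.

## The hierarchical trend model

Each survey point is an observed proportion $\hat p_s$ with an effective
sample size $n_s$ (the raw denominator divided by a design effect, 2 by
default, reflecting cluster sampling). Writing $y_s = \hat p_s n_s$ for the
effective success count, the model for country $i$ in year $t$ is

$$
y_s \sim \mathrm{Binomial}(n_s,\, p_{i,t}), \qquad
\mathrm{logit}(p_{i,t}) = \alpha_i + \beta_i \frac{t - 2000}{10}
 + \gamma_{\mathrm{SDI}}\, z(\mathrm{SDI}_{i,t})
 + \gamma_{\mathrm{HRH}}\, z(\mathrm{HRH}_{i,t}),
$$

with country intercepts and decade slopes partially pooled,

$$
\alpha_i \sim N(\mu_\alpha, \sigma_\alpha^2), \qquad
\beta_i \sim N(\mu_\beta, \sigma_\beta^2).
$$

Time is centred at 2000 and scaled per decade so that slopes are
interpretable and the intercept is the log-odds of coverage in 2000. The
two country-year covariates — the Sociodemographic Index (SDI, a composite
development score in [0, 1]) and the Human Resources for Health density
(HRH, health workers per 1,000 population) — are z-scored against the
fitting set ($z(\cdot)$); the scaling is stored in the fit so projections
and reported coefficients are consistent. Because the effective count
$y_s$ need not be an integer, the binomial likelihood is used as a
quasi-likelihood on design-adjusted counts.

Priors are weakly informative: $N(0, 100^2)$ on the hyper-means and
covariate coefficients and half-Cauchy(0, 2.5) on $\sigma_\alpha,
\sigma_\beta$, with uniform(0, 10) and half-normal alternatives wired into
the sensitivity protocol. An optional third level
(`region_hierarchy = TRUE`) draws region-specific intercept means around a
global mean; it is off by default because the gain is small at 54 countries
and the pooling structure is a modelling choice, not a data requirement.

Urban/rural and wealth-quintile estimates reuse the same model fitted
independently per stratum (`fit_trend_strata()`): per-stratum tables demand
no cross-stratum constraint, and independent fits keep the stratum
estimates honest about their own data.

### Sampling

`fit_trend()` runs an adaptive Metropolis-within-Gibbs sampler (written in
C++): random-walk updates per country intercept and slope, conjugate Gibbs
draws for the hyper-means, log-scale random walks for the hyper-SDs, and
random-walk updates for the covariate coefficients. Proposal scales adapt
toward a 0.44 acceptance rate during burn-in only and are frozen
afterwards, so the post-burn-in chain is a valid fixed-kernel MCMC.

Two non-obvious moves matter in practice:

* **Covariate shear moves.** Within a country, a covariate trend is
  near-collinear with linear time, so $\gamma$ and the $(\alpha_i,
  \beta_i)$ are strongly correlated a posteriori. A plain random-walk
  sampler traverses that ridge very slowly. The sampler therefore also
  proposes joint moves that change $\gamma$ by $\delta$ while shifting
  every $\alpha_i, \beta_i$ by the compensating within-country
  least-squares projection of the covariate on $(1, t)$ — a volume-
  preserving shear along the confounded direction. This reduced the
  potential scale reduction factor on $\gamma$ from $\approx 1.3$ to
  $\approx 1.005$ at the reduced test settings.
* **Frozen blocks are frozen at truth.** When a block is excluded
  (`fit_slope = FALSE`, `use_covariates = FALSE`) its parameters are held
  at exactly zero, not at jittered starting values.

The default configuration is 10,000 iterations, three chains, thinning 10,
burn-in 500 (950 retained draws per chain). Chains start from data-informed
values — per-country empirical-logit regressions, with observed 0s and 1s
clamped to $[0.5/n, 1 - 0.5/n]$ before the logit — jittered by
$N(0, (0.1c)^2)$ for chain $c$. Fits are bit-reproducible given the seed.
Tests and examples in this package use reduced settings (typically 3,000
iterations, thinning 5) and 6–10 synthetic countries, sizes at which the
sampler's behaviour is already representative; the production defaults
match the full sampling plan.

### Projection and convergence

`project_coverage()` evaluates each retained draw's trajectory at the
requested years and summarises coverage as the posterior mean with the
2.5th/97.5th percentile credible interval, in percent. Covariates are
treated as fixed inputs; their uncertainty is not propagated. If the
covariate series stops short of the horizon, `extrapolate_covariates()`
(opt-in) extends each country linearly from its last ten observed years,
clipping SDI to [0, 1] and HRH to non-negative values.

Convergence is assessed with the classic Gelman-Rubin statistic
(`gelman_rubin()`): with $m$ chains of length $n$, $W$ the mean
within-chain variance and $B/n$ the variance of chain means,
$\widehat V = \frac{n-1}{n} W + B/n$ and
$\mathrm{PSRF} = \sqrt{\widehat V / W}$. The upper limit replaces the
between-chain term with its 97.5th percentile under an
$F(m-1,\, m(n-1))$ approximation to the between/within variance ratio.
Parameters whose upper limit exceeds 1.1 are flagged — a conventional
threshold, documented as such. A split-chain variant (`split = TRUE`)
also catches within-chain drift; the non-split form is the default because
it is the classic estimator this workflow historically used.

## Inequality metrics

The slope index of inequality (`sii()`) regresses quintile coverage on
ridit scores — the midpoints of each quintile's interval on the cumulative
wealth rank — by weighted least squares with the population shares as
weights. The SII is the fitted coverage difference between rank 1 and rank
0, in percentage points; positive values are pro-rich. Linear (not
logistic) regression on the ridits is the documented choice. The default
computes the SII on posterior-mean quintile coverages; `sii_draws()`
applies the same regression per posterior draw when a credible interval
for the SII itself is wanted.

`percentage_change()` implements both readings of "percentage change":
point difference (default) and change relative to the starting level —
the definition in published tables is ambiguous, so both are exposed and
the default is the additive one. `residence_gap()` reports urban minus
rural coverage and classifies gaps of 30 points or more as wide.

## The determinants model

`fit_determinants()` fits a Bayesian logistic regression of an individual
binary outcome (INSD or SBA) on household-head age and sex, maternal
education, parity, antenatal-care contacts, mass-media access, wealth
quintile and residence, with a random country intercept:

$$
\mathrm{logit}\, P(y_r = 1) = b_0 + x_r'b + u_{i(r)}, \qquad
u_i \sim N(0, \sigma^2_{u0}).
$$

Covariates are dummy-coded against the conventional reference levels
(head under 30, male head, no education, parity 1, no ANC visits, no media
access, poorest quintile, urban residence) giving 21 indicator columns.
All 54 countries are pooled in one model with country intercepts; age-group
analyses reuse the identical machinery on filtered inputs. Priors are
$N(0, 10^2)$ on fixed effects and half-Cauchy(0, 2.5) on
$\mathrm{sd}(u)$. The sampler exploits the sparsity of 0/1 design columns
(an update touches only the rows in that category) and adds a
likelihood-invariant shear between the intercept and the country effects
to decorrelate them. Perfectly separating levels are detected and reported
before sampling rather than left to diverge. `or_table()` reports
posterior-median odds ratios (switchable to means) with 95% credible
intervals, reference rows printing 1.00, and a final row for
$\sigma^2_{u0}$.

## The synthetic-data generator

Real DHS/MICS microdata cannot be redistributed, so validation rests on
`generator_spec()` and its generators, which emulate the *statistical
structure* the analysis assumes — never any real country's values. The
default spec mirrors the real study's shape: 54 countries in six regions,
four surveys each over 2000–2019 (≈216–224 points), roughly 2,000
respondents per survey with a design effect of 2 (effective n ≈ 1,000).
Country intercepts are drawn with hyper-mean −0.5 and SD 1.5 — spanning
coverages from a few percent to above 95% in 2000, as published country
tables do — and decade slopes with mean 1.0 and SD 0.6 on the logit scale.
Covariate series are smooth increasing power-law curves with
country-specific level, gain and curvature; the curvature matters, because
series that are all nearly linear in time make the slope/covariate
decomposition unidentifiable. Urban/rural strata sit ±0.4 logits around
the national trajectory and quintiles on a centred 0.4-logit-per-quintile
gradient. Individual records use fixed documented covariate marginals and
the log-odds effects in `default_determinant_truth()`.

What passing recovery tests on these data shows: the samplers target the
stated posteriors, intervals are calibrated under the model's own
assumptions, and every pipeline stage composes correctly. What they do not
show: robustness to the ways real surveys violate the model — comparability
breaks between survey programmes, recall bias in self-reports, design
effects that vary by country and year, and non-logistic trend shapes.
Countries whose true coverage is near saturation across the whole window
carry almost no slope information; their slope posteriors correctly shrink
to the hyper-mean, and recovery there is assessed through interval
coverage, not point error.

## Sensitivity protocol

`sensitivity_refit()` refits the trend model (a) without the country-level
covariates and (b) with the alternate hyper-SD prior (uniform(0, 10) by
default), and summarises each comparison as the median absolute difference
of posterior-mean coverage per year — the same summary statistic used to
report such checks in practice. On well-identified synthetic data both
perturbations move posterior means by well under a percentage point at the
2030 horizon.

## Published-table reporting

The packaged prediction table (`load_printed_predictions()`, checksummed
at load) carries the published national posterior means and 95% intervals
for 54 countries × {INSD, SBA} × {2000, 2018, 2030}, keyed by ISO3 code.
`count_above_threshold()` / `count_below_threshold()` implement the
headline country counts; comparisons use values as printed (one decimal),
and "reached 80%" maps to ≥ 80.0 — no printed cell in the relevant years
equals exactly 80.0, so the choice of strict versus weak inequality is
observationally irrelevant. `assemble_country_table()` lays trajectories
out in the conventional region-grouped, one-decimal format.

```{r counts}
preds <- load_printed_predictions()
count_above_threshold(preds, 2018, c("INSD", "SBA"), 80)$count
count_above_threshold(preds, 2030, c("INSD", "SBA"), 80)$count
count_below_threshold(preds, 2030, "SBA", 80)$countries[[1]]
```

## A worked synthetic example

```{r example}
spec <- generator_spec(n_countries = 6, surveys_per_country = 4, seed = 42)
truth <- generate_trajectories(spec)
surveys <- generate_surveys(truth, spec)
fit <- fit_trend(surveys, truth$covariates,
                 mcmc_config(n_iter = 3000, burn_in = 500, thin = 5, seed = 1))
glance(fit)
project_coverage(fit, years = c(2000, 2018, 2030)) |>
  assemble_country_table()
```

## Known limitations

* One outcome and one stratum per fit; INSD and SBA are modelled
  independently, as are strata — no borrowing across them.
* Covariates are fixed inputs; projection intervals understate total
  uncertainty to the extent that SDI/HRH forecasts are themselves
  uncertain.
* The time trend is linear on the logit scale; no splines or spatial
  correlation.
* No survey re-weighting beyond the effective-sample-size contract, no
  multiple imputation of missing covariates, and no survey weights in the
  determinants model.
* Random-walk Metropolis mixing degrades for very large country sets;
  the shear moves address the dominant correlations, but users should
  always inspect `psrf_table()` output.
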