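---
title: "Combining two surveys for county-level prevalence: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining two surveys for county-level prevalence: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

National health surveys measure smoking and cancer-screening behaviors
reliably at the national and state level, but county-level estimates are
needed for local cancer control planning. Two survey systems offer
complementary strengths. An in-person, area-sampled survey (NHIS-like)
covers households of every telephone status and has high response rates,
but by design samples only about a quarter of counties, with small county
samples. A telephone survey (BRFSS-like) interviews roughly tenfold more
respondents and reaches every county, but its sampling frame covers only
landline households and its estimates carry noncoverage and nonresponse
bias. Telephone status matters substantively: cell-only and no-phone
households smoke more and screen less than landline households, so a
landline-frame survey is biased for the full population.

`countysae` implements a small-area estimation (SAE) pipeline that
combines the two: design-based direct estimates feed a multivariate
Fay–Herriot-type hierarchical Bayes model whose posterior combines the
in-person survey's coverage with the telephone survey's volume.

## Direct estimation

For each county (and phone stratum) we compute the Hajek weighted
proportion $\hat p = \sum w_i y_i / \sum w_i$, the Kish design effect
$\mathrm{deff} = n \sum w_i^2 / (\sum w_i)^2$, the effective sample size
$n_\mathrm{eff} = n/\mathrm{deff}$, and the variance
$\mathrm{deff}\,\hat p(1-\hat p)/n$. The Kish-adjusted binomial variance
is used instead of full Taylor-linearized stratified-PSU estimation: the
model consumes only $(\hat p, \hat V, n_\mathrm{eff})$, unequal weighting
is the only design feature the synthetic data generate, and the PSU and
design-stratum labels are carried in the microdata so a linearized
estimator could be added without changing any interface. When
$\hat p \in \{0, 1\}$ the variance is floored at
$1/(4 n_\mathrm{eff} n)$ so no level-1 observation claims to be exact.

County-stratum cells with fewer than 2 respondents are dropped from the
model's level 1 (the estimate exists but its variance estimate is
unusable); the threshold is an argument of `assemble_level1()`.

## The transformed scale

Direct estimates enter the model through the arcsine-square-root
transform $y = \arcsin\sqrt{\hat p}$, whose asymptotic sampling variance
$1/(4 n_\mathrm{eff})$ does not depend on $\hat p$. Proportions of
exactly 0 or 1 are first shrunk by $1/(4n)$ toward one half (an
Anscombe-style guard) so the transformed value is finite and interior.
The level-1 covariance across the four components (three in-person
strata, one telephone) is taken diagonal: the stratum estimates use
disjoint respondents, and the two surveys are independent. This
diagonality assumption is isolated in `assemble_level1()`.

We use $1/(4 n_\mathrm{eff})$ rather than a Taylor variance pushed
through the delta method; for the Kish-adjusted binomial variance the two
coincide up to the factor $\hat p (1-\hat p)$ cancellation that motivates
the transform in the first place.

## The hierarchical model

With $i$ indexing counties and $s \in \{\text{landline}, \text{cell-only},
\text{no-phone}\}$ strata, the level-1 sampling model for the available
components is

$$y_{is} \sim N(\theta_{is}, v_{is}), \qquad
  z_i \sim N(\lambda\,\theta_{iL}, w_i),$$

where $z_i$ is the telephone survey's transformed county estimate and
$\lambda$ a single unknown factor measuring its proportionate bias
relative to the in-person landline truth — $\lambda$ acts
multiplicatively on the transformed scale, and one global $\lambda$ is
shared by all counties for a given outcome. The linking model is

$$\theta_i = B x_i + u_i, \qquad u_i \sim \mathrm{MVN}_3(0, \Sigma),$$

with county covariates $x_i$ (intercept included) and a full $3\times 3$
random-effect covariance, so information flows between strata within a
county as well as between counties. A county with no in-person sample —
the typical county — still gets a proper posterior for all three strata,
informed by its covariates, by $\Sigma$, and by its bias-adjusted
telephone estimate.

Priors are proper: $\mathrm{vec}(B) \sim N(\beta_0, \tau^2 I)$ with
default $\beta_0 = 0$, $\tau^2 = 4$; $\lambda \sim N(1, 0.25)$ truncated
to $(0,\infty)$, centering "no bias" as the default belief;
$\Sigma \sim \mathrm{IW}(5, 0.01 I)$. Two deliberate choices here:

* **$\tau^2 = 4$, not something enormous.** The transformed means live in
  $[0, \pi/2]$, so coefficients of standardized covariates beyond about
  $\pm 2$ are meaningless. A prior SD of 2 per coefficient is diffuse for
  every scientifically possible value, and — unlike an arbitrarily wide
  prior — it keeps the Markov chain for coefficients of a stratum with
  essentially no data (no-phone cells are rare at realistic in-person
  sample sizes) from wandering a scale the model cannot use.
* **$\lambda$ centered at 1.** The factor is unknown; equality of the
  two surveys is the natural origin.

## Gibbs sampler

All full conditionals are conjugate: $\theta_i$ multivariate normal
(computed for all counties at once through a closed-form $3\times 3$
Cholesky), $B$ normal, $\lambda$ normal truncated to positive values,
$\Sigma$ inverse-Wishart. Two blocking decisions matter:

* **$\lambda$ is drawn with $\theta$ integrated out.** The telephone data
  pin the product $\lambda\theta_{iL}$ tightly, so alternating
  $\lambda \mid \theta$ and $\theta \mid \lambda$ produces a random walk
  along a near-confounded ridge. Instead the sampler draws $\lambda$ from
  $p(\lambda \mid B, \Sigma, \text{data})$ — the county's landline mean
  given only its in-person components has a normal conditional, so the
  marginal likelihood of $z_i$ is
  $N(\lambda m_i,\ \lambda^2 s_i^2 + w_i)$, sampled by univariate slice
  sampling — and refreshes $\theta$ immediately afterwards. The pair is
  a valid joint block (partially collapsed Gibbs). In addition, a
  scaling Metropolis move proposes
  $(\lambda, \theta_L, B_L, \Sigma) \to
   (c\lambda, \theta_L/c, B_L/c, D\Sigma D)$ with $D =
  \mathrm{diag}(1/c, 1, 1)$ and log-symmetric $c$; the telephone
  likelihood and the level-2 quadratic are invariant under this map, so
  the move slides along the ridge in one step and the effective sample
  size for $\lambda$ rises several-fold. Chain starting points for
  $\lambda$ and $B$ are overdispersed so that scale-reduction
  diagnostics can detect chains stuck on the ridge.
* **$\theta$ is kept in $[0, \pi/2]^3$ by rejection** (falling back to
  clamping after 200 attempts), so the back-transform is always defined.
  The collapsed $\lambda$ step integrates an untruncated normal; this is
  exact whenever the box constraint carries negligible posterior mass,
  which holds for prevalences away from 0 and 1 — degenerate direct
  estimates are already guarded upstream.

Chains are independently seeded; Gelman–Rubin potential scale reduction
(threshold 1.1) and effective draw counts (threshold 400) are computed
for all hyperparameters with `coda`, and failures raise a warning and a
`converged = FALSE` flag — never a silent success. Coefficients of a
stratum with no level-1 data mix slowly (they are prior-dominated and
move only through the latent means); the diagnostics flag this, and
longer thinned chains are the remedy. Initialization: $B$ by least
squares of available transformed estimates on the covariates, $\theta$
at observed values where present (else $Bx_i$), $\lambda = 1$, $\Sigma$
at its prior mean.

## Composition and back-transformation

County prevalence combines the stratum means with the county's household
phone composition $\phi_i$, per posterior draw:
$\pi_i^{(g)} = \sum_s \phi_{is} \sin^2 \theta_{is}^{(g)}$. Applying the
composition and back-transform inside the draw loop (rather than to
posterior means) propagates the full posterior through the $\sin^2$
nonlinearity; the point estimate is the draw mean and the 95% interval
the equal-tailed 2.5/97.5 percentiles (linear-interpolation quantiles).
$\phi_i$ is treated as fixed at composition time — its estimation
uncertainty is not propagated, a stated limitation. Household shares
(not adult-population shares) are the default composition weights, as
they are the quantity the phone-status tabulations measure.

Compositions themselves are smoothed: observed county-by-stratum
household counts are shrunk toward a multinomial-logit regression on the
county covariates, with a single Dirichlet concentration $k$ estimated
by maximizing the Dirichlet-multinomial marginal likelihood, giving
$\hat\phi_i = (\text{counts}_i + k\,\hat p_i)/(n_i + k)$. Counties with
no in-person sample receive the regression prediction; a county with an
enormous sample keeps its empirical shares.

## Validation battery

Four numeric checks mirror how such models are validated in practice:

1. **Funnel ratios.** If the model holds, the telephone survey's direct
   estimate, divided by $\hat\lambda$ on the transformed scale and
   back-transformed, should match the modeled landline prevalence, and
   the ratios should converge to 1 as the telephone effective sample
   size grows. We summarize $|\log \text{ratio}|$ in effective-size bins
   ($\le 25$, 25–100, $> 100$) so the funnel is a testable number, not
   just a plot; both sides of the ratio are compared on the prevalence
   scale.
2. **National benchmarking.** Population-weighted aggregation of the
   county estimates should land near the in-person survey's national
   direct estimate — not the telephone survey's, whenever
   $\lambda \neq 1$.
3. **County summaries.** Min/quartile/median/max/mean/SD per outcome,
   for outlier detection and range-shrinkage checks.
4. **External correlation.** Inverse-variance-weighted Pearson
   correlation between county estimates and any external county rate
   table (e.g. registry mortality rates). No registry data ship with the
   package; the operation accepts any `county_id, rate, rate_variance`
   table.

## The synthetic data generator

The generator is first-class, tested code that encodes the study
conditions the model assumes:

* County true transformed means follow the level-2 model exactly
  ($\theta_i = B_\mathrm{true} x_i + u_i$, clipped to
  $[0.02, \pi/2 - 0.02]$ to rule out degenerate prevalences). Default
  intercepts put stratum prevalences at 17.7% / 27.3% / 30.9% — the
  landline / cell-only / no-phone current-smoking gradient — and the
  default random-effect SD (~0.063 transformed, with cross-stratum
  correlation 0.5) corresponds to a county prevalence SD of 5–6
  percentage points near $p = 0.25$.
* Phone compositions are additive-logistic-normal around the national
  shares 75.0 / 23.2 / 1.8, mean-corrected on the log-ratio scale so the
  across-county mean matches those shares, and loading on the county
  covariates (with residual noise) so that composition smoothing by
  regression has signal to recover. A logistic-normal, not a Dirichlet,
  precisely so composition can be regressed on covariates.
* The in-person survey samples 25% of counties uniformly at random;
  within a sampled county the respondent count is Poisson with mean 12
  — sampled PSUs get similar interviewer workloads, so no population
  scaling — and respondents split across strata by the county's
  composition. The telephone survey samples only the landline stratum,
  in every county, with Poisson counts proportional to county population
  (mean 120 for an average county, truncated at 2): tenfold the
  in-person volume, and enough spread in effective sample size to
  populate all three funnel bins.
* The telephone survey's outcomes are Bernoulli with success probability
  $\sin^2(\lambda_\mathrm{true}\,\theta_{iL})$, so its bias is exactly
  the model's multiplicative transformed-scale bias; the default
  $\lambda_\mathrm{true} = 0.9$.
* Weights are mean-1 lognormal with coefficient of variation 0.7, making
  the Kish design effect $\approx 1 + \mathrm{CV}^2 \approx 1.5$, in the
  range of real telephone surveys. Respondent age and sex are generated
  so outcome denominator filters (e.g. women 40+ for mammography) are
  exercised.

What the generator does **not** emulate: the real multistage area
PSU selection (non-sampled counties are chosen uniformly), state-level
stratification of the telephone survey, item nonresponse, measurement
error in the questionnaire items, and any spatial correlation between
neighboring counties. Passing tests therefore demonstrate that the
pipeline recovers the truth when the model's structural assumptions
hold, with realistic sample sizes and design effects — not that the
model is robust to frame or questionnaire features it does not
represent.

## Numerical choices and degenerate inputs

* Empty county samples yield *no* direct estimate record (absence, not
  zero); counties absent from both surveys are excluded from level 1
  with a logged reason.
* $\hat p \in \{0, 1\}$: variance floored, transform guarded (above).
* Singular posterior precision in the $\theta$ update names the county
  in its error.
* Zero-width credible intervals (degenerate draws) warn.
* All randomness flows from one flat seed, expanded into per-stage
  substreams (generation, in-person sampling, telephone sampling, MCMC),
  so any stage can be rerun in isolation and identical configuration
  reproduces byte-identical outputs.

## Problem sizes

The simulation studies in the test suite and the acceptance script use
200 counties with 3 covariates, about 600 in-person and 24,000 telephone
respondents, and 2 chains of 12,000 iterations (3,000 burn-in, thin 3)
for the main recovery study; kernel-level checks use 20,000 draws. These
sizes give Monte Carlo error comfortably inside the tolerances asserted
while keeping a full run in the tens of seconds on one core.

## Known limitations

* The prior-sampling (Geweke-style) check is run where the $[0,\pi/2]$
  box constraint is slack (coefficient prior centered mid-box), because
  under a binding constraint the truncated joint prior's moments are not
  the closed-form untruncated ones.
* $\hat\lambda$ inherits the small-sample bias of the arcsine transform
  in tiny in-person county-stratum cells (the transform's expectation is
  below the transformed truth for $p < 1/2$ at single-digit $n$); with
  default conditions this is well inside one posterior SD, but it grows
  if in-person county samples shrink further.
* Below roughly 100–150 counties (so only a few dozen with in-person
  samples), the cell-only and no-phone intercepts rest on a handful of
  2–4-respondent cells whose guarded degenerate proportions carry
  optimistic variances; stratum intercepts can then shift by several
  points and interval coverage degrades. This is a property of the
  study conditions (sparse in-person stratum cells), not of the
  sampler, and it disappears as the number of counties grows.
* One outcome is modeled at a time; no joint modeling across the 11
  outcomes, no spatial random effects, no covariate selection.
* Composition uncertainty is not propagated into the intervals.
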