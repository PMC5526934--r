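---
title: "Methods: demographic viability of boreal caribou under landscape disturbance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: demographic viability of boreal caribou under landscape disturbance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caribouViability)
```

## The problem

Boreal caribou are a late-seral forest specialist whose populations decline
as their ranges are burned, logged and roaded. The mechanism is largely
indirect: young, regenerating forest favours moose and deer, which sustain
more wolves and bears, and predation then falls disproportionately on
caribou (apparent competition). Management policy for threatened herds is
framed around a single landscape variable — the proportion of the range
disturbed, `D` — so the operational question is: *how much total disturbance
can a population withstand before it starts to decline?* This package
implements a demographic answer, and adds a second axis that mediates it:
forest productivity `P`, the proportion of a range's ecological districts
classed as potentially productive forest. Productive landscapes regenerate
faster (more forage, but a shorter window of predator-friendly early seral
conditions per unit of disturbance) and empirically support higher caribou
vital rates at a given disturbance level.

## Vital rates from monitoring data

**Survival.** Annual survival of collared adult females is estimated per
population and biological year (1 April–31 March, so that spring captures
do not truncate a winter of exposure) with the staggered-entry
Kaplan–Meier estimator:

$$\hat S = \prod_{t \in \text{deaths}} \left(1 - \frac{d_t}{n_t}\right),$$

where the risk set $n_t$ contains every female whose collar was active on
day $t$ — animals enter at their individual collaring dates and leave the
risk set at death or at their last known-alive location (right-censoring
for collar loss or non-predation mortality). Conventions, where the
estimator leaves room: tied deaths are one multiplicative step; a death and
a censoring on the same day count the death first (the conservative
standard); a population-year is kept only when at least six distinct
females were monitored. The per-year product over split histories is
identical to reading a pooled curve at 31 March, which is why the package
splits multi-year histories first (`split_biological_years()`) and then
treats each biological year independently.

**Recruitment.** Late-winter aerial surveys classify animals as calves,
adult females, adult males, or unclassified adults. Because surveys fly in
February–March, the calf cohort reflects reproduction and ~9 months of calf
survival under the *previous* year's conditions, so each observation is
paired with the disturbance of the year preceding the survey. Unclassified
adults are apportioned to females by the observed female fraction
$F/(F+M)$ when under 10% of adults are unclassified, and otherwise by an
assumed 65/35 female/male split (equivalently a 0.54 male-to-female
ratio — and consistent with the pooled sexed counts, 453 females of 699
adults ≈ 0.65). The recruitment index is $R = \text{calves} / \text{corrected
females}$, retained only when at least 50 individuals were observed.
"Individuals" is read as calves plus all adults; and exactly 10%
unclassified uses the 65/35 assumption (the observed-fraction rule applies
strictly below 10%).

## The two vital-rate models

Both rates are modelled on the logit scale with a population random
intercept $u_j \sim N(0, \sigma^2_{pop})$:

$$\text{logit}(S) = \beta_0 + \beta_D D + \beta_P P + u_j,
\qquad
\text{logit}(R) = \beta_0 + \beta_D D_{t-1} + \beta_{P^2} P^2 + u_j.$$

The square in the recruitment model linearises the productivity response on
the logit scale. Fits use `lme4::glmer` with a binomial family, adaptive
Gauss–Hermite quadrature (7 nodes by default; `nAGQ = 1` gives the Laplace
approximation) and *prior weights*: the number of monitored females for a
survival observation, the corrected female count for a recruitment
observation. Two consequences are worth spelling out:

* Survival responses are Kaplan–Meier proportions, not integer counts, so
  the binomial log-likelihood is evaluated with fractional successes
  $\hat S \cdot w$ — quasi-likelihood semantics. The same holds for
  recruitment when the corrected female count is fractional. (Integer
  calves over corrected females is the package default because the
  corrected denominator is the weight actually recorded; the fitted model
  is identical either way up to the weight's rounding.)
* Prior weights scale the conditional likelihood but not the
  random-intercept prior. Doubling every weight therefore leaves the
  fixed-effect estimates of the *fixed-effects* model exactly unchanged
  (information scales, estimates do not), and of the mixed model unchanged
  whenever $\hat\sigma_{pop}$ sits at the boundary; away from the boundary
  the balance between binomial and between-population variance shifts
  slightly. The test suite asserts exactly these two statements.

The reported covariance of the fixed effects is the inverse observed
information at the optimum. The authoritative interval method, matching the
original analysis, is the parametric bootstrap (`bootstrap_ci()`,
`confint()`): simulate responses from the fitted model — new population
intercepts each replicate, binomial draws with each observation's rounded
weight as the trial count — refit, and take percentile bounds
(inverse-ECDF percentiles, so tiny bootstrap sizes behave sensibly). Runs
with more than 10% failed refits abort rather than silently thin. The
reference iteration count is 10,000; tests use a few hundred.

Degenerate inputs are refused loudly: an all-zero (or all-one) response is
complete separation; a single population makes `P` collinear with the
intercept (rank-deficiency error) or, if the third covariate still varies,
pins $\sigma_{pop}$ to zero with a warning and falls back to the weighted
GLM. That weighted GLM is also the independent oracle the tests compare
the mixed fit against whenever the boundary is hit.

## From vital rates to a withstand threshold

With a 0.5 birth sex ratio, the calf/female ratio converts to a female
recruitment rate $R_f = (R/2)/(1 + R/2)$, and the finite annual rate of
change of the female segment is

$$\lambda_f(D, P) = \frac{S_f(D, P)}{1 - R_f(D, P)}.$$

Both rates are evaluated from fixed effects only (random intercepts at
zero): the threshold machinery describes a generic population at a given
$(D, P)$, not a particular herd's realised intercept. The *withstand
threshold* $D^*(P)$ solves $\lambda_f(D, P) = 1$; since both disturbance
coefficients are negative, $\lambda_f$ is strictly decreasing in `D` and
bisection to an absolute tolerance of $10^{-6}$ finds the unique root
(`mean_threshold()`; the boundary cases are flagged: "non-viable even
undisturbed" at $D^* = 0$, "viable at full disturbance" at $D^* = 1$).

Statistical uncertainty is propagated by simulating coefficients: `n_sim`
draws (default 10,000) from $N(\hat\beta, \widehat{\text{vcov}})$ for each
model, independently across the two models (they were fitted separately;
no cross-covariance exists). Each draw's own $\lambda_f = 1$ boundary is
solved — vectorised bisection for the (overwhelmingly common) monotone
draws, a cumulative grid scan for draws whose disturbance coefficient
comes out non-negative — and `confident_threshold()` returns the 5th
percentile of the per-draw thresholds. Under monotonicity this is exactly
"the largest `D` at which at least 95% of simulations still give
$\lambda_f \ge 1$", and the test suite verifies the two readings against
each other on shared draws. The multivariate-normal sampling distribution
is used rather than full bootstrap refits because the coefficient draws
are what the threshold consumes; with `vcov = 0` the confidence threshold
collapses to the point-estimate threshold exactly, a degenerate case the
tests pin down. At `n_sim` = 10,000 the threshold is stable across seeds
to well within 0.01 of `D`.

`viability_surface()` assembles the full $(D, P)$ grid of $\lambda_f$,
both threshold curves, and a classification of supplied populations
(increasing below the boundary, declining above, stable within a
configurable tolerance band).

## Forest succession models

The productivity proxy is given meaning by stand-development models fitted
to inventory pixels: ordinary least squares of stand height and canopy
cover on age, age², `P` and the age-by-productivity interaction, and a
penalized cubic-spline GAM (10 basis functions per smooth, smoothing by
GCV, `s(age) + s(age, by = P) + P`) for the deciduous fraction, which
pulses about 20 years after disturbance. Recorded canopy cover is first
rescaled by the treed fraction of the pixel and the deciduous proportion
by the vegetated fraction; pixels without trees or vegetation are removed,
and corrected values above 1 are capped with a warning. The smooth
specification (separate age smooth plus a productivity-varying smooth,
rather than a full tensor product) is a configuration choice; the fitted
surfaces, not the basis, are the output.

## The synthetic-data generator

The generator exists so the entire pipeline is testable without field
data, and its defaults *are* the study conditions the package targets: six
populations, a decade of monitoring, 15 collared females per
population-year (printed range 6–22), 150 classified females per survey
(printed range 50–252), productivity uniform on [0.04, 0.85] and
disturbance trajectories inside [0.22, 0.78] — non-decreasing, because
over a one-decade horizon disturbance accumulates faster than burns and
cutblocks age out of the 40–50-year disturbance window. The generating
coefficients default to the published mixed-model estimates (survival:
1.67, −0.77, 1.22; recruitment: −0.15, −5.05, 2.41 on `P²`), with
$\sigma_{pop} = 0.2$ — a moderate between-population heterogeneity chosen
once as realistic for herds spread over a large region — and a 10% annual
censoring probability of the same order as collar-failure rates in
long-running telemetry programmes. Survival and recruitment intercepts are
drawn independently per population by default, mirroring the separate
model fits (`shared_random_effects` couples them if wanted).

Numerical choices inside the generator:

* **Within-year death placement is constant-hazard** (exponential waiting
  time from entry), not uniform. The annual death probability is identical
  either way, but with staggered entry only the memoryless placement makes
  the Kaplan–Meier product consistent for the annual probability — a
  mid-year entrant's remaining risk must be exactly the tail of the
  cohort's. This is asserted by a Monte-Carlo test: the death frequency of
  $10^5$ simulated animal-years matches $1 - \text{logit}^{-1}(\eta)$
  within three binomial standard errors.
* Censoring competes with death by date: whichever simulated event falls
  earlier wins, matching the risk-set semantics of the estimator.
* Lost animals are replaced the following 1 April, so the collared roster
  stays near its target; survivors carry over, producing genuinely
  multi-year histories that exercise the biological-year splitter.
* Every generator call derives its own seed from the configuration by a
  fixed offset, so a config is a complete, byte-reproducible description
  of a dataset.

What the generator does *not* emulate — and therefore what green tests do
not certify about field data: spatially explicit disturbance (no
geometry, buffering or overlap handling; `D` enters as a precomputed
proportion), animal movement and detection error, inter-annual climate
effects, cause-specific mortality, and survey sightability (the 85%
detection of the survey protocol is not modelled, matching its absence
from the original vital-rate models).

## Problem sizes used by the checks

The parameter-recovery experiment runs at 60 populations × 10 years
(~9,000 animal-years; ~540 surveys), large enough that each recovered
coefficient's Monte-Carlo standard error is a fraction of its magnitude; a
24-replicate calibration shows the estimators unbiased with model-based
standard errors matching the empirical spread. The bootstrap coverage
check uses 150 replicates of an 80-observation fixed-effects dataset at
200 bootstrap iterations — sizes chosen to make the binomial tolerance
around the nominal 95% meaningful while keeping the suite quick. The
pipeline determinism checks run a deliberately small configuration (4
populations, 5–6 years, coarse grids) since determinism does not depend
on scale.

## Known limitations

* The threshold machinery is demographic, not dynamical: it classifies a
  population's position relative to $\lambda_f = 1$, it does not project
  abundance through time or include density dependence, age structure
  beyond the female two-stage implicit in $\lambda_f$, or predator
  numerical responses.
* Published survival predictions for specific herds can include those
  herds' realised random intercepts; the package's predictions are
  deliberately fixed-effects-only and will differ for atypical herds.
* The binomial weight treats a Kaplan–Meier estimate's precision as that
  of a simple proportion at the monitored-female count; censoring and
  staggered entry make true precision somewhat lower, which is partly why
  the bootstrap, not the information matrix, is the interval method of
  record.
* Independence of the survival and recruitment coefficient draws is an
  assumption of convenience; any true cross-correlation (e.g. a good year
  for both rates) is unavailable from separately fitted models.
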