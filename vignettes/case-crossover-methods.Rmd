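---
title: "Methods: case-crossover estimation of temperature-PM2.5 synergism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-crossover estimation of temperature-PM2.5 synergism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatpm)
```

`heatpm` estimates the independent and joint short-term effects of daily
maximum temperature and fine particulate matter (PM2.5) on heat-related
hospitalization (HRH) with a time-stratified case-crossover design and a
Bayesian conditional logistic model. This vignette is the package's own
account of the statistical machinery: the design, the model and its
assumptions, every tunable parameter and why its default is what it is,
what the synthetic-data generator does and does not emulate, and the
numerical choices underneath.

## The case-crossover design

A case-crossover study compares each case's exposure on the event day
with the same person's exposure on nearby non-event (referent) days.
Because the comparison is within person, anything constant over the
stratum — demographics, chronic disease, neighborhood deprivation,
housing quality — cancels out of the likelihood *exactly*; the package
tests this as a literal invariance (adding any stratum-constant design
column with any coefficient leaves every stratum log-likelihood
unchanged to machine precision).

The design choices, all conventional for time-stratified referent
selection:

- **Case day**: each person's *first* event in the record, retained only
  if it falls in the warm season (June–September). A person whose first
  event falls outside the warm season is excluded entirely — later
  warm-season events are subsequent events, never cases. This keeps the
  "first event" and "warm season" rules from interacting in a way that
  would condition on the future.
- **Referent days**: all other days in the case day's calendar month and
  year sharing its day of week. A weekday occurs four or five times a
  month, so every case has 3 or 4 referents, bidirectionally before
  and/or after the event. Bidirectional same-month selection makes the
  referent window independent of the event time and controls seasonality
  and day-of-week patterns by construction.
- **Death and disenrollment**: referent days after a hypothetical death
  date are *not* excluded (the inputs carry no death date). In
  time-stratified designs referent validity is about exposure, not
  survival; the assumption is logged here rather than silently made.
- Calendar arithmetic uses the proleptic Gregorian calendar via base R
  `Date`s; dates are timezone-free.

## Exposure windows and trimming

Analysis exposures per person-day are the same-day maximum temperature
(window of 1 day) and the 3-day mean PM2.5 (index day plus two preceding
days), reflecting the more delayed action of air pollution; a 3-day
temperature window is available for sensitivity analyses
(`window_spec(temp_window_days = 3)`). A person-day is usable only when
every day of its window is present in that area's series; incomplete
coverage drops the day, and dropping the *case* day drops the whole set.

Extreme PM2.5 outliers exert high leverage on spline fits, so the
package trims: the threshold is the empirical 95th percentile (99th for
sensitivity) of 3-day PM2.5 pooled over all case *and* referent days of
the constructed design, computed after matched-set construction and
before fitting. The quantile uses linear interpolation between order
statistics (`stats::quantile()` type 7) — no convention is canonical,
but fixing one makes every threshold exactly reproducible. Trimming
removes person-*days*; a set whose case day is trimmed is removed whole
(a case-less stratum contributes nothing to a conditional likelihood),
as is a set left with zero referents. Whether "observations" should mean
days or whole strata is genuinely ambiguous; the day-level rule is the
default and `apply_trim()` exposes the threshold so either policy can be
audited. Every drop is counted: the run manifest's person-day ledger
satisfies `candidates = retained + dropped(missing coverage) +
dropped(case uncovered) + dropped(no referents) + dropped(trim) +
dropped(case trimmed) + dropped(no referents after trim)` exactly, and a
test enforces the identity.

## The model

For matched set $s$ with rows $j$ (one case, $m_s - 1$ referents) and
linear predictor $\eta_{sj} = f_T(T_{sj}) + f_P(P_{sj}) + \gamma\,
T_{sj} P_{sj}$, the conditional likelihood is

$$L(\beta) = \prod_s \frac{\exp(\eta_{s,\text{case}})}
                          {\sum_{j} \exp(\eta_{sj})},$$

the standard matched-set conditional logistic form. No intercept or
stratum effect appears; both are absorbed by the conditioning.

- $f_T$, $f_P$ are **natural cubic splines** (linear beyond their
  boundary knots), default 4 df each. Four is the smallest basis that
  exhibits visible curvature in the exposure-response while remaining
  stable in moderate samples; it is configurable via `spline_spec()`.
  `spline_spec(df = 1)` degenerates to the raw linear column — the
  natural-spline space with no interior knots *is* the space of linear
  functions, and the raw column keeps coefficients directly
  interpretable, which the parameter-recovery tests exploit.
- **Knots**: interior knots at equally spaced quantiles of the
  *case-day* exposure distribution (df 4 puts them at the 25th, 50th and
  75th percentiles), boundary knots at the min/max of the trimmed
  analysis values. Knot locations are frozen into the design object and
  echoed in the run manifest, so effect summaries are always evaluated
  on exactly the fitted basis.
- The **interaction** is the raw product $T \times P$ in
  °C·µg/m³, one coefficient $\gamma$; its exponential is the
  multiplicative interaction OR per 1 °C·µg/m³. Because the spline
  spans contain all linear functions and the conditioning absorbs
  constants, re-centering the product as $(T-a)(P-b)$ changes nothing:
  the product coefficient and the fitted surface are invariant (tested
  to $10^{-6}$). A **tensor-product** sensitivity model replaces the
  single product column with the 16 pairwise products of two marginal
  df-4 natural-spline bases, allowing a nonlinear interaction surface;
  the marginal spline blocks are retained so additive surfaces stay in
  the span.

### Bayesian fitting

Priors are independent Normal(0, 5²) per coefficient — weakly
informative at the scale of log-ORs for these exposures (a prior SD of 5
on a log-OR is essentially flat over any plausible effect), chosen
because the posterior should be proper while the data dominate;
`prior_sd = Inf` gives the flat prior used for MLE-equivalence checks.

The posterior is log-concave (the conditional logistic log-likelihood is
concave; the normal prior only adds concavity), which licenses a simple,
fast, and exact sampler: **independence Metropolis–Hastings** with a
multivariate-t proposal (df 20, covariance 1.05 × the inverse curvature)
centred at the posterior mode found by Newton's method. For log-concave,
near-Gaussian posteriors this proposal tracks the target closely —
acceptance rates in routine fits are 0.8–0.9 and effective sample sizes
are 60–80% of nominal. Defaults: 4 chains × 1000 warmup + 1000 retained
draws, all seeded from the run configuration.

Convergence is *gated*, not assumed: split-$\hat R$ (each chain halved,
between/within variance ratio) must be below 1.01 and bulk effective
sample size (Geyer initial-monotone-sequence autocorrelation truncation)
above 400 for every coefficient, else the fit is rejected with the full
diagnostic table attached to the error (`on_fail` downgrades to a
warning for simulation studies). An independence sampler has no
divergent-transition failure mode; poor proposal adaptation shows up
directly as low acceptance and low ESS, which the gate catches.

A deterministic **maximum-likelihood oracle** (`fit_clogit()`) sits
beside the sampler: Newton–Raphson with analytic gradient and observed
information, internal column scaling for conditioning, step-halving
(concavity means steps never decrease the objective), convergence
declared at score norm $10^{-9}$. Flat likelihoods raise an explicit
non-identifiability error (rank-deficient information at the start) and
separation an explicit separation error (likelihood at its supremum, or
diverging coefficients) — never a silent garbage fit. The test suite
checks the MLE against `survival::clogit` to $10^{-6}$ and the
flat-prior posterior mean against the MLE within Monte-Carlo error.

## Effect summaries

Contrast levels default to the case-day median (reference) and case-day
95th percentile (comparison) of each windowed exposure, computed from
the trimmed analysis sample. Per posterior draw, with the reference
$(T_0, P_0)$:

- $\text{OR}_{10}$, $\text{OR}_{01}$, $\text{OR}_{11}$ are the
  exponentiated log-odds differences for raising temperature alone,
  PM2.5 alone, or both;
- $\text{RERI} = \text{OR}_{11} - \text{OR}_{10} - \text{OR}_{01} + 1$,
  the additive-scale excess of the joint effect over the sum of the lone
  effects. On the OR scale this approximates the risk-ratio RERI when
  the outcome is rare — which is why the event generator warns when its
  hazard stops being rare.

Summaries are posterior means with equal-tailed 95% intervals
(2.5th/97.5th percentiles, not HPD — the standard "95% CI" convention of
Bayesian regression software). Both the per-draw RERI and the plug-in
RERI (applying the identity to the three posterior-mean ORs) are
reported; the two *point estimates coincide exactly* because RERI is
linear in the ORs, so the distinction is purely about the interval,
which only the per-draw path provides. The OR grid reports the
posterior-mean OR of every $(T, P)$ cell against the reference cell,
whose value is identically 1.

## The synthetic-data generator

Real claims-based inputs cannot be shipped, so the generator is a
first-class, tested module whose truth is known in closed form.

**Exposures.** Daily maximum temperature is a seasonal sinusoid plus
AR(1) Gaussian deviations: $T_{at} = b + A\cos(2\pi(\text{doy}_t -
d^\*)/365.25) + \delta_{at}$ with $\delta_{at} = \rho_{AR}
\delta_{a,t-1} + \varepsilon_{at}$ at stationary SD $\sigma_T$. Daily
PM2.5 is lognormal, $\log P_{at} = \mu_P + \sigma_P z_{at}$, with
$z_{at}$ mixing the standardized same-day temperature deviation (weight
$\rho_{TP}$) and independent noise, giving
$\text{cor}(\delta, \log P) = \rho_{TP}$ exactly.

Defaults were calibrated once, by simulation, to the descriptive moments
the generator is designed to emulate, and then frozen: amplitude 7 °C,
peak day 201, baseline 23.53 °C and $\sigma_T = 4.83$ give pooled
warm-season temperature mean 29.2 °C and SD 5.0 °C; $\mu_P = 2.062$,
$\sigma_P = 0.717$ give a 3-day-mean PM2.5 that, trimmed at its own 95th
percentile, has mean 9.4 and SD 3.7 µg/m³, with the strong right skew
(rare values above 90 µg/m³) that motivates trimming in the first
place. $\rho_{AR} = 0.7$ provides realistic day-to-day persistence so
3-day windows genuinely differ from single days. $\rho_{TP} = 0.3$: a
moderate positive temperature-pollution correlation of the kind warm
stagnant air masses produce; no published magnitude was available to
match, so this is a free, documented choice.

**Events.** Each person is assigned uniformly to an area; the daily
event probability is the inverse-logit of
$\alpha + \beta_T T + \beta_P P_3 + \beta_{TP} T P_3$ evaluated at *the
same windowed exposures the analysis model uses* — this is what makes
the analysis model correctly specified under the linear hazard and true
parameters recoverable. Only each person's first event is emitted,
mirroring the first-event case rule. The first-event day is sampled
exactly by inverting the per-person survival curve with a single
uniform. `true_effects()` returns the closed-form ORs and RERI of any
linear hazard at any contrast; the baseline $\alpha$ cancels, and a test
asserts that invariance.

**What the generator does *not* emulate** — and hence what passing tests
do and do not show: no spatial correlation between areas, no demographic
covariates or effect modification (the matched design conditions
person-level covariates out, so they would add nothing testable), no
grid-to-area exposure aggregation error, no lagged (distributed-lag)
effect structure, and no outcome misclassification. Recovery tests
demonstrate that the *pipeline* is correct under its own assumptions,
not that those assumptions hold in claims data.

**Model correctness is conditional on rarity.** The conditional
likelihood treats the case day as drawn from the stratum with
probability proportional to $\exp(\eta)$; for first events from a
Bernoulli hazard this holds only in the rare-outcome limit. At daily
event probabilities around $10^{-3}$–$10^{-4}$ the within-month
depletion of susceptibles is negligible and recovery is clean; at
$10^{-2}$ it visibly biases coefficients (early-month days are
over-selected as "first"). The generator warns when the median daily
probability reaches 0.5, and the recovery experiments below use rare
settings deliberately.

## Problem sizes and verification

Everything empirical the package claims is computed by its tests or the
acceptance script, at these sizes (chosen as respectable simulation
sizes for the properties being demonstrated):

- likelihood oracle: random 3–5-row strata against direct enumeration
  ($\le 10^{-12}$); 50-stratum fixture against `survival::clogit`
  ($\le 10^{-6}$);
- flat-prior posterior vs MLE: 500 strata, linear design, posterior mean
  within 2 MCSE per coefficient;
- parameter recovery: hazard $(\beta_T, \beta_P, \beta_{TP}) = (0.05,
  0.02, 0.003)$, rare baseline, ~2 000+ strata, linear design; posterior
  means within 3 posterior SDs of truth and posterior-mean RERI within 3
  posterior SDs of the closed form;
- null calibration: 100 replicates of a zero-effect hazard at ~500
  strata each, default spline model, 500 post-warmup draws; the 95%
  RERI interval covers 0 within 3 binomial SEs of 95/100;
- generator moments: $\ge 10^5$ warm-season area-days.

## Known limitations

- The sampler's Laplace-centred independence proposal is excellent for
  log-concave conditional-logistic posteriors but would be a poor choice
  for multimodal targets; it is not a general-purpose MCMC engine.
- The posterior mean of a skewed posterior is not its mode; at small
  stratum counts with flexible spline bases the two differ at the order
  of the Monte-Carlo error, which matters only when comparing against
  the MLE.
- Percentile trimming is applied once, on the constructed design; it is
  not re-estimated within sensitivity refits, matching the analysis it
  mirrors.
- The tensor sensitivity model reports no single multiplicative
  interaction coefficient (`multiplicative_interaction()` errors by
  design).
- With `warn_extrapolation`, effect summaries evaluated beyond the
  boundary knots extrapolate linearly — the natural-spline contract —
  but contrasts far outside the data support remain extrapolations.
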