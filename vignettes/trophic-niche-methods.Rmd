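---
title: "Methods: Bayesian isotopic niches, community metrics and model selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian isotopic niches, community metrics and model selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the models, their assumptions, the defaults and why they were chosen, the
numerical decisions, and what the synthetic-data tests do and do not
demonstrate about real data. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The species niche model

Each species-by-area group's (δ¹³C, δ¹⁵N) values are modelled as
independent draws from a bivariate normal distribution with unknown mean μ
and covariance Σ. The prior is the conjugate normal–inverse-Wishart
family,

$$\Sigma \sim IW(\nu_0, \Psi_0), \qquad
  \mu \mid \Sigma \sim N(\mu_0, \Sigma/\kappa_0),$$

so the posterior is again normal–inverse-Wishart and can be sampled
*exactly*: a Wishart draw is inverted for Σ (closed-form 2×2 inversion),
then μ is drawn from its conditional normal. There is no MCMC and hence no
convergence diagnostics; identical seed, data and prior give bit-identical
draws.

Defaults (`niche_prior()`): $\kappa_0 = 10^{-3}$ (the prior mean carries a
milli-observation of weight, so $\mu_0 = (0,0)$ is immaterial),
$\nu_0 = 3$ (the smallest proper value in two dimensions), $\Psi_0 = I$
(permil²). Two remarks on vagueness:

* With $\kappa_0 \to 0$ and growing $n$, the posterior mean of Σ converges
  to the sample covariance (tested at $n = 500$ within 5%).
* $\Psi_0 = I$ is *mildly informative* for tight niches. The posterior
  scale matrix is $\Psi_0 + S$ with $S$ the centered sum of squares; at
  $n = 25$ and cell variances around 0.25 ‰² (the synthetic default), $S$
  has diagonal ≈ 6 and doubling $\Psi_0$ moves the median SEAc by roughly
  9%. For wide niches (variances of a few ‰²) the shift is under 2%, and
  the test suite evaluates prior sensitivity at that scale. Users with
  very tight niches and small samples should scale `prior$scale` toward
  their measurement scale.

**Standard ellipse.** Every Σ draw yields
$SEA = \pi\sqrt{\lambda_1\lambda_2} = \pi\sqrt{\det\Sigma}$, the area of
the 1-σ ellipse (≈ 40% coverage; the coverage convention is fixed and
only changes all areas by a common factor). The small-sample correction
$SEA_C = SEA\,(n-1)/(n-2)$ requires $n \ge 3$, which is also why groups
with fewer than three fish are non-estimable and dropped with a warning.
Collinear samples are flagged but not rejected: the full-rank prior scale
keeps the posterior proper.

## Community metrics and their posteriors

For each posterior draw $d$, the species mean vectors
$\{\mu_s^{(d)}\}$ of one area form a point set over which four metrics are
computed: convex hull area (TA), δ¹⁵N range (NR), δ¹³C range (CR) and
mean distance to centroid (CD). Propagating the draws yields full
posterior distributions of each metric.

Two genuinely open design points, and the choices made:

* *What the hull connects.* The hull is built over species posterior
  **mean vectors**, one per species per draw, so TA measures the spread of
  species niche centers, not of individual fish. An individual-based CD
  variant (`community_point_estimates(..., cd_variant = "individual")`)
  exists because centroid distance is sometimes defined per fish; the
  species-mean version is the default and the two should be compared when
  they disagree appreciably.
* *Ranges from raw points.* NR and CR are computed from the species-mean
  points directly; the extrema are necessarily hull vertices, and the test
  suite asserts the equivalence.

Geometry is deliberately boring: hull vertices from `grDevices::chull()`,
area by the shoelace sum, checked against an independent fan-triangulation
oracle to 1e−9 on a thousand random instances. Degenerate (collinear)
communities have TA = 0; areas with fewer than three species get `NA` TA
but keep NR/CR/CD, and are flagged.

## Exceedance probabilities, and what they are not

Groups are compared by
$P(a>b) = \frac{1}{n}\sum_i \mathbf{1}[X_{a,i} > X_{b,i}] \times 100$,
with strict inequality; ties are reported separately and never split, so
the exceedance, deficit and tie percentages sum to 100 exactly. Because
the group posteriors come from disjoint data, index pairing and all-pairs
crossing estimate the same quantity; `by-index` is the default (it matches
the single $n$ in the formula) and `all-pairs` is available, computed by
sorting rather than an $n^2$ loop.

One property deserves emphasis. $P(a>b)$ is a *data-conditional posterior
statement*, not a frequentist test statistic. Under a no-difference truth,
its distribution **across replicate data sets** is approximately uniform on
[0, 100] — the posterior spread of a metric and the sampling noise of the
data both scale as $1/\sqrt{n}$, so a well-calibrated posterior cannot
concentrate null exceedance values near 50%. The test suite measures
exactly this on no-change synthetic data (20 replicate surveys): roughly
half the null exceedance values fall outside [35, 65]%. Practically: a
single 70% exceedance is weak evidence; values near 0 or 100, stable
across metrics, are what signal a real difference — which is how the
detection check behaves (a 2 ‰ planted nitrogen-range expansion yields
NR exceedance above 99% while the carbon-range exceedance stays
equivocal).

## Diet summaries

The IRI follows the standard composite form
$IRI_i = (\%N_i + \%M_i)\times\%FO_i$, normalized to %IRI within a
predator group; empty stomachs never enter the records, so frequency-of-
occurrence denominators count full stomachs. If a group records counts but
no mass, the mass term is dropped and the group flagged rather than
failing. Rarefied prey richness resamples *stomachs* (not individual prey)
without replacement; its mean matches the closed-form hypergeometric
expectation, which is the test oracle.

## The information-theoretic layer

`fit_random_intercept()` is an in-package Gaussian mixed-model fitter for
a single random intercept: with variance ratio
$\lambda = \sigma^2_{group}/\sigma^2_{resid}$ the marginal covariance is
block diagonal, $V_g = I + \lambda J$, so Woodbury gives
$V_g^{-1} = I - \frac{\lambda}{1+\lambda n_g}J$ and
$\log|V_g| = \log(1+\lambda n_g)$; fixed effects and the residual variance
are profiled out in closed form and the remaining one-dimensional problem
in $\log\lambda$ is solved by `stats::optimize()` on
$\log\lambda \in [-14, 14]$ (tol 1e−10), with the $\lambda = 0$ boundary
evaluated explicitly and flagged when it wins. The test suite checks the
optimum against a brute-force λ-grid (within 1e−8 log-likelihood units)
and against lme4 on both ML and REML likelihoods. Model selection always
runs on ML fits — REML likelihoods are not comparable across fixed-effect
structures — and REML exists for variance-component reporting.

Conventions: K counts *all* estimated parameters, fixed effects plus
variance components (a linear model with p coefficients has K = p + 1, a
random-intercept model K = p + 2). Published tables sometimes count one
more or one fewer; `selection_table()` accepts raw (name, logLik, K, n)
rows so any convention can be reproduced verbatim. AICc uses
$-2\log L + 2K + 2K(K+1)/(n-K-1)$ and refuses $n \le K+1$. ΔAICc ≤ 2
flags well-supported models; ΔAICc < 4 defines the averaging set.
Averaging is the *natural* (conditional) form — each coefficient averaged
over the models containing it with renormalized weights — with Buckland
unconditional standard errors; RVI sums full-set weights. Continuous
predictors are 2-SD standardized so their coefficients are comparable with
binary ones. Interaction candidates always carry their main effects.

## What the generator emulates — and what it does not

`generate_isotope_dataset()` draws lengths lognormal(log 30, 0.25) cm,
then δ¹⁵N from the length model
$\delta^{15}N = m_{s,a} + b_a(L-\bar L) + u_{site} + \varepsilon$ with
$b_a$ = 0.02 ‰/cm in fished areas and 0.05 under protection (a steeper
trophic-position–size relationship where fishing is absent), site SD
0.15 ‰, and the residual SD chosen so the cell's marginal δ¹⁵N variance
equals the target; δ¹³C is then drawn conditionally so the full cell
covariance ([[0.25, 0.075], [0.075, 0.25]] ‰² by default) is hit exactly.
If the slope and site variance together exceed the target variance the
scenario is rejected as infeasible rather than silently renormalized.
Defaults mirror the motivating design: 3 areas × 3 sites, five species at
29 fish per area (87 total, one species at 5 per area), 62 non-empty
stomachs. The H1/H2 effect sizes (2 ‰ widening of the species-mean δ¹³C /
δ¹⁵N range in the protected area) are fixture conventions chosen once to
be comfortably detectable at these sample sizes, not field estimates.

Real data differ in ways the generator does not attempt: isotope values
need not be bivariate normal within cells; species can be absent from
whole areas (the comparison tables handle the resulting missing cells, but
the generator does not produce them by default); site effects touch only
δ¹⁵N; lengths and isotopes carry no measurement error beyond the residual;
and there is no spatial or temporal autocorrelation. Passing tests
therefore demonstrate *internal correctness* — the estimators recover the
truth of this generative family — not robustness to violations of it.

**Power-check scenario.** The model-selection recovery test asks whether a
planted length-by-status interaction is top-ranked. In the default
scenario the between-species δ¹⁵N spread (≈ 0.8 ‰ SD) enters the residual
of a species-blind model and drowns a Fig-4-scale interaction, so the
power check uses a scenario with equal species δ¹⁵N means and
`beta_ls = 0.045`, chosen from the analytic interaction standard error
$SE \approx \sigma\sqrt{1/S_{prot} + 1/S_{fish}}$ (with $S_g$ the centered
length sum of squares in status group $g$) to sit near three standard
errors at n = 87 across 9 sites. With `beta_ls = 0` the same check
confirms the interaction is *not* preferentially top-ranked.

## Numerical choices

* Positive-definiteness tolerance: eigenvalues above −1e−10 (relative) are
  clamped to zero; worse is a domain error.
* Posterior sampling consumes one seeded stream with groups processed in
  sorted label order, so results do not depend on input row order.
* Ties in exceedance are counted, never split.
* δ values at or below −1000 ‰ (non-positive isotope ratio) are rejected.
* The δ¹⁵N baseline (default 10.32 ‰, SD 0.4, from long-lived sessile
  filter feeders at the same reefs) is a configurable constant;
  `baseline_offset()` subtracts it without applying any trophic
  enrichment factor, because converting to discrete trophic levels would
  require a TEF assumption the analysis does not need.

## Problem sizes used by the test suite

Simulation-based checks are sized to keep the default run fast while
leaving Monte Carlo margins well away from their thresholds: 10⁴ draws
where the draw count itself is under test, 2 000 otherwise; 200 replicate
surveys for coverage; 100 replicates per arm of the power check; 20
replicate surveys for the null-calibration measurement; 1 000 random point
sets for the geometry oracle.

## Known limitations

* Only a single random-intercept term is supported in-house; crossed or
  nested multi-level structures should be fitted externally and entered
  into `selection_table()` as (logLik, K, n) rows.
* The niche model is bivariate only, by design.
* Exceedance probabilities inherit the calibration caveat above; they
  quantify posterior belief given one data set and are not error-rate
  controlled.
* The IRI's composite form is one convention among several; the table
  reports %N, %M and %FO separately so alternatives can be recomputed.
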