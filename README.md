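# reefniche

Bayesian isotopic niche metrics for reef fish communities.

## The problem

Marine protected areas (MPAs) are expected to change *how* fish feed before
they change how many fish there are. Bulk stable isotopes track this:
δ¹³C reflects the basal carbon source of a consumer's diet and δ¹⁵N its
trophic position, so the spread of a community in the (δ¹³C, δ¹⁵N) plane is
a quantitative picture of its trophic niche. `reefniche` implements the
statistics needed to compare such niches between areas that differ in
protection status, for hierarchical designs in which replicate reef sites
are nested within fished and protected areas — for example a rockfish
(*Sebastes* spp.) community sampled in two fished areas and one MPA.

## What it computes

**Species niches.** Each species-by-area group's (δ¹³C, δ¹⁵N) sample is
modelled as bivariate normal with a conjugate normal–inverse-Wishart prior,
giving exact joint posterior draws of the mean vector μ and covariance Σ
(no MCMC). Each draw yields a standard ellipse area

> SEA = π √(λ₁ λ₂) = π √det Σ,  SEAc = SEA · (n − 1)/(n − 2)

where λ are the eigenvalues of Σ and the (n−1)/(n−2) factor corrects the
small-sample bias.

**Community niches.** For each posterior draw the species mean vectors of
an area form a point set over which the Layman-style metrics are computed:
total hull area (TA), nitrogen range (NR), carbon range (CR) and mean
distance to centroid (CD), giving full posterior distributions of all four.

**Comparisons.** Two groups are compared with the posterior exceedance
probability

> P(a > b) = Σ 1[Xₐ > X_b] / n × 100,

the percentage of draws in which group a's metric exceeds group b's.

**Diets.** Stomach contents are summarized per prey taxon with
%N, %M, %FO and the index of relative importance
IRI = (%N + %M) × %FO, plus observed and rarefied prey richness.

**Model selection.** A built-in random-intercept Gaussian mixed-model
fitter (profiled likelihood over the variance ratio) supports the
information-theoretic layer: AICc, ΔAICc, Akaike weights, natural model
averaging with Buckland unconditional variance, and relative variable
importance, applied to candidate models of δ¹⁵N against body length and
protection status with a site random intercept.

**Synthetic data.** `niche_scenario()` encodes three hypothesized MPA
responses (carbon expansion, nitrogen expansion, no change) as parameter
patterns; `generate_isotope_dataset()` and friends produce data with a
machine-readable truth manifest so every stage has a recoverable target.

## Worked example

```r
library(reefniche)
sim <- generate_isotope_dataset(niche_scenario("H2"), seed = 1)  # 87 fish
rep <- run_full_analysis(sim$data, config = run_config(n_draws = 10000, seed = 2))
print(rep)
```

```
Trophic niche analysis report
  87 fish, 15 fitted group(s), 3 area(s); 10000 draws, seed 2

Community niche comparisons (protected vs fished orientation):
  ...
  P(NR MPA > Fished North) = 100.0%
  P(NR MPA > Fished South) = 100.0%
  P(CR MPA > Fished North) = 67.6%
  P(CR MPA > Fished South) = 39.2%
  ...
```

The scenario plants a 2 ‰ expansion of the protected area's species-mean
δ¹⁵N range and no carbon effect; the report recovers exactly that pattern —
near-certain nitrogen-range exceedance, equivocal carbon-range exceedance.
The selection table below the comparisons ranks the five candidate δ¹⁵N
models by AICc with their Akaike weights; `rep$averaged` holds the
model-averaged coefficients and each predictor's relative variable
importance, and `summary(rep$niche_fit)` the per-group SEAc posteriors.

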