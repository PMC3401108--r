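# phenosync

**Environmental predictability and the length of ungulate birth seasons.**

Wild herbivore populations differ enormously in how synchronized their
births are — from a couple of weeks to the whole year. `phenosync` is an R
package for testing the resource-availability explanation of that variation
at a comparative, multi-species scale: it quantifies how *predictable* the
vegetation dynamics of each population's home range are, and regresses the
(log) length of the birth season on that predictability while correcting for
the shared evolutionary history of the species involved. It is aimed at
comparative ecologists working with population-level trait data, satellite
vegetation indices and a species-level phylogeny.

## What it computes

**Colwell's predictability partition.** Each location's NDVI series
(bi-monthly, multi-year) is screened for artefacts, averaged over pixels,
and discretized into `s` states. With `N[i, j]` the count of state `i` in
time-of-year category `j` pooled over years, the entropies
`H(X), H(Y), H(XY)` (convention `0·log 0 = 0`) give

    constancy      C = 1 − H(Y)/log s          (inter-annual stability)
    contingency    M = (H(X)+H(Y)−H(XY))/log s (strength of seasonality)
    predictability P = C + M

all in [0, 1] and independent of the log base.

**PGLS with Pagel's λ.** Birth-season length (log days) is modelled as
`y = Xβ + ε`, `ε ~ MVN(0, σ²V(λ))`, where `V` is the phylogenetic
covariance of the population-grafted tree (populations attached to their
species as polytomies with near-zero branches) and λ rescales the
off-diagonal of `V`. β has the GLS form `(XᵀV(λ)⁻¹X)⁻¹XᵀV(λ)⁻¹y`; λ is
estimated by maximizing the profile likelihood on [0, 1]. Candidate models
(23 formulas combining contingency, constancy, their interaction, latitude,
diet, calf behaviour and gregariousness) are ranked by
`AICc = AIC + 2k(k+1)/(n−k−1)`. Trait-evolution models (Brownian, white
noise, λ) are compared by AIC, and Moran's I with the normality-assumption
standard deviate screens the data and residuals for spatial autocorrelation.

Everything upstream of real data is covered by generators (`simulateNdvi`,
`simulateYuleTree`, `simulateTraits`, `simulateStudy`) that record ground
truth, so the whole pipeline is testable end to end.

## Worked example

```r
library(phenosync)
study <- simulateStudy(n_species = 12, pops_per_species = 2,
                       ndvi_config = ndviGenConfig(n_years = 15,
                                                   spike_rate = 0.01),
                       seed = 42)
run <- runAnalysis(study$ndvi, study$tree, study$traits, seed = 42)
run
#> phenosync pipeline run (config hash 396e7de445cfcb160ce2be3b3cd269be )
#>   20 locations retained of 24; 20 populations analysed
#>   best evolutionary model: white
#>   best PGLS model: contingency (AICc 39.56, lambda 0.000)
#>   Moran's I on residuals: z = -0.386, p = 0.7

head(run$predictability[, 1:4], 3)
#>    location_id  constancy contingency predictability
#> 1  loc_t1_pop1 0.05526077   0.4481070      0.5033678
#> 2  loc_t1_pop2 0.02004382   0.7022448      0.7222887
#> 3 loc_t10_pop1 0.03857426   0.6916174      0.7301917

run$coefficients
#>          term   estimate        se         t            p
#> 1 (Intercept)   8.813156 0.7407954  11.89688 5.797971e-10
#> 2 contingency -11.358843 1.0925157 -10.39696 4.889736e-09
```

Reading the output: four of the 24 simulated locations failed the 50%
pixel-retention screen and are excluded everywhere downstream (named in
`run$qc`). Per retained location, `constancy`/`contingency` partition NDVI
predictability — e.g. `loc_t1_pop2` sits in a strongly seasonal
(contingency 0.70) but inter-annually variable (constancy 0.02) habitat.
Model selection picks the seasonality model, and its slope (−11.4 log-days
per unit contingency, t = −10.4) says birth seasons shorten sharply as
seasonality strengthens — the relationship the bundle was generated with.
Moran's I finds no residual spatial autocorrelation (p = 0.7), and λ ≈ 0
reflects that the simulated signal here sits in the environment, not the
phylogeny.

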