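---
title: "Methods: from vegetation predictability to breeding synchrony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from vegetation predictability to breeding synchrony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenosync)
```

## The scientific question

Many large herbivores concentrate their births into a short window; others
give birth year-round. The resource-availability hypothesis holds that the
length of the birth season tracks the temporal structure of the food supply:
where the growing season is short and reliable, births should be synchronous;
where resources fluctuate unpredictably between years, a longer season may be
favoured. `phenosync` implements a comparative test of that hypothesis across
populations of different species, which requires (i) a per-site measure of
resource predictability, (ii) a regression that respects the shared ancestry
of the species involved, and (iii) diagnostics for spatial pseudo-replication.

## NDVI screening

Satellite NDVI composites (bi-monthly, 24 per year by default) carry
well-known artefacts: transient drops or jumps from cloud and atmospheric
contamination, spurious negatives over water, and genuine negatives over
winter snow. The screening rules, applied per pixel in a fixed order:

1. **Winter zeroing** (northern sites only): negative values within a
   configurable winter window (default Nov–May, never more than half the
   year) are replaced by exactly 0. This runs *before* the run-length screen
   so that snow signal does not get a pixel discarded.
2. **Negative-run removal**: any run of three or more consecutive strictly
   negative values removes the pixel.
3. **Spike correction**: a change of more than 0.25 NDVI units followed by a
   rapid return is an anomaly. "Rapid return" is operationalized as return
   within one step to within the threshold of the pre-jump value — the
   natural reading at a bi-monthly cadence. An isolated spike is replaced by
   the mean of its neighbours; two consecutive anomalous values are replaced
   by weighted averages of the flanking values with weights 2/3–1/3 and
   1/3–2/3, i.e. linear interpolation across the two-point gap (the weights
   are a design choice; only "weighted average" is prescribed by the rule
   set we follow). The pass runs once, left to right, and never alters
   values more than one position from a detected anomaly.
4. **Aggregation**: retained pixels are averaged per (year, period). A
   location keeping fewer than 50% of its pixels is excluded; exactly 50%
   is kept (strict "less than half remaining" reading).

We deliberately aggregate across pixels but *not* across years: Colwell's
statistics need the year-resolved record. The across-years mean is a purely
descriptive output.

## Colwell's predictability partition

Each location series is discretized into `s` states (default 8,
`equal_width_local`; the state count and scheme are exposed because no
canonical choice exists — a sensitivity sweep over `n_states` in {4, 8, 12}
is a one-liner with `locationPredictability()`). Counts `N[i, j]` of state
`i` in time-of-year category `j`, pooled over years, give entropies H(X),
H(Y), H(XY) with the 0·log 0 = 0 convention, and

- constancy `C = 1 − H(Y)/log s` — how invariant the state is;
- contingency `M = (H(X) + H(Y) − H(XY))/log s` — how strictly the state is
  determined by the time of year (the strength of seasonality);
- predictability `P = C + M` (an algebraic identity, tested to 1e-12).

Natural logs are used internally; the `log s` normalization makes all three
metrics base-free and bounded in [0, 1]. Boundary values in binning go to
the lower bin (the maximum joins the top bin) — an arbitrary but fixed
convention.

## Phylogenetic regression

Populations are grafted onto the species tree as polytomies with branch
length `1e-6 ×` tree height. Within-species distances are treated as
approximately zero; a strictly zero branch would make the phylogenetic
covariance matrix singular, so the small epsilon keeps it positive definite
while being negligible relative to between-species distances.

Trait evolution is modelled as multivariate normal with covariance
`sigma² · V(λ)`, where `V` holds shared root-to-ancestor path lengths and
Pagel's λ multiplies the off-diagonal of `V` (λ = 0: independence; λ = 1:
full Brownian structure). `fitEvoModel()` compares Brownian motion, white
noise and the λ model by ML/AIC; the candidate set is configurable and
deliberately small — an OU model is out of scope. All likelihoods go through
a Cholesky factorization (no explicit inverses) and are checked in the tests
against naive-inverse multivariate-normal evaluation on small trees.

`pglsFit()` estimates `β = (XᵀV(λ)⁻¹X)⁻¹XᵀV(λ)⁻¹y` with λ maximizing the
profile likelihood on [0, 1] (golden-section search, tolerance 1e-8, with an
explicit check of both boundaries). Choices the literature leaves open, fixed
here:

- λ is re-estimated for every candidate model (a fixed-λ option exists).
- σ² is reported on the ML scale (`RSS_w/n`); standard errors use the
  `n − p` denominator and Student-t reference with `n − p` df. REML is
  available via `method = "REML"`, ML is the default.
- AICc = AIC + 2k(k+1)/(n − k − 1) with k counting the regression
  coefficients, σ², and λ when estimated.
- Treatment coding with fixed references: diet = browser,
  calf behaviour = follower; gregariousness enters as a numeric score
  (1–5); latitude as absolute latitude (the hypothesis concerns distance
  from the equator, not hemisphere).
- The response is the natural log of birth-season length in days.
- Adjusted R² is computed on the λ-whitened model (squared correlation of
  whitened fitted and observed values, adjusted for p).

The default candidate set (`candidateModels()`) contains 23 formulas
combining contingency, constancy, their interaction, latitude, diet, calf
behaviour and gregariousness, with the hierarchy rule (interactions only
with their main effects).

## Spatial diagnostics

Moran's I is computed with row-standardized k-nearest-neighbour weights
(k = 4, haversine distances) by default — the neighbourhood definition is a
package choice, exposed in the interface and stamped in the output. The test
uses the normality-assumption variance ("Moran's I standard deviate", two-
sided); a permutation null is available as a cross-check and agrees with the
normal approximation on Gaussian data in the test suite. No spatial
regression correction is implemented: the diagnostic is the deliverable.

## What the synthetic data emulates — and what it does not

`simulateNdvi()` produces a raised-cosine seasonal cycle (the simplest shape
with a tunable seasonal contrast, hence a controllable contingency), a
per-year lognormal amplitude multiplier plus white observation noise (so
constancy and contingency can be tuned semi-independently, mirroring their
observed negative correlation), and injected artefacts — isolated spikes of
0.4 NDVI with clean flanks, negative runs, winter negatives — all recorded
in a ground-truth ledger so screening can be *scored*, not just eyeballed.
Values are clipped to [−1, 1]. No distributional detail about real
inter-annual NDVI variation is claimed: the noise model is a modelling
choice. The generator produces no spatial raster structure, no
cloud-contamination autocorrelation, and no mixed land-cover pixels, so
passing tests demonstrate the *rules* behave as specified, not that the
rules are sufficient for any particular satellite product.

`simulateTraits()` draws contingency ~ U(0, 0.5) and constancy ~ U(0, 1)
(the observed covariate ranges), builds the mean from the interaction model
with coefficients (9.33, −11.53, −6.18, 7.67) on the log-day scale, and adds
multivariate-normal residuals with covariance `0.8² · V(0.3)` by default.
The phylogenetic covariance is rescaled to unit height first, so the
residual SD is interpretable at the tips regardless of tree depth.
Life-history covariates are drawn independently of the response — they are
pure noise competitors in model selection.

## Problem sizes and numerical choices

The validation suite uses 200-replicate recovery simulations at n = 70
populations (35 species × 2) for coefficient recovery and model selection,
200 replicates at n = 128 tips per λ ∈ {0, 0.5, 1} for λ recovery, and
1000-draw nulls for the Colwell identity and Moran's I — sizes at which
Monte-Carlo error is small relative to the tolerances while the whole suite
runs in minutes. Degenerate inputs are handled explicitly: constant series
refuse quantile binning, exact-fit regressions flag σ² ≈ 0, λ = 0 requests
on singular grafted covariances raise an error suggesting a larger epsilon,
and coincident coordinates under inverse-distance weights get an epsilon
offset.

## Known limitations

- The winter window is a fixed configurable period set; real snow seasons
  vary by pixel and year.
- Water masking is assumed done upstream (pixels may arrive flagged); no
  geometry is computed.
- The discretization (8 equal-width states) is a default, not an estimate;
  conclusions should be checked across state counts.
- λ is bounded to [0, 1]; estimates that would exceed 1 are truncated by
  construction.
- Intermediate phylogenetic signal is intrinsically hard to pin down: at
  around a hundred tips the ML estimate of λ near 0.5 carries substantial
  sampling spread (the validation suite measures a mean absolute error of
  roughly 0.14 at n = 128 on Yule trees, and an independent implementation
  returns the same estimates on the same data). Boundary values (λ = 0 or 1)
  are recovered far more precisely.
- The candidate evolutionary-model set is {BM, white, λ}; richer models
  (OU, EB) are intentionally out of scope.
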