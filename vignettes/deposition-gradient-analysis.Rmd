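---
title: "Methods: trait-based diversity and stability along deposition gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait-based diversity and stability along deposition gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdgradient)
```

## The analysis chain

`fdgradient` analyzes plant communities sampled along a short spatial
gradient downwind of emission sources. Three tables describe the
communities — a species × trait matrix (eight leaf traits: SLA, LDMC, LC,
LT, LD, LTC, LTN, LTP), a site × species relative-abundance table, and a
long site × species × replicate biomass table — and a fourth carries
per-site environmental covariates (ion depositions, deposition pH, soil
chemistry, enzyme activities). The chain is:

1. per-site community-weighted trait means (CWM) and the inverse-CV
   stability index (ICV);
2. the four trait-space diversity indices FRic, FEve, FDis and Rao's Q;
3. correlation-matrix PCA of the site × CWM table (the leaf-strategy
   spectrum) and simple regressions of its axes on covariates;
4. Spearman and Mantel screening of diversity–environment association;
5. all-subsets AICc multimodel averaging of deposition/soil predictors;
6. composite-variable construction (BC deposition, N deposition as first
   PCA axes of their ion blocks) and a recursive path model pruned down
   to significant paths.

## Index definitions and geometry

All trait geometry uses Euclidean distance on traits z-scored over the
**full species pool**, never per community; with eight traits in
incommensurate units (m²·kg⁻¹ to g·kg⁻¹), pooled z-scoring is the only
way the distances, hulls and centroids are comparable across sites.

**FRic.** The community hull volume divided by a reference volume. The
reference is the hull of the pooled standardized trait cloud over all
communities in the dataset, which makes FRic a 0–1 fraction of the
occupied niche space. A hull in *d* dimensions needs more than *d*
affinely independent points, so coordinates are projected onto the
leading `min(S - 1, T, hull_dim)` principal axes of the pooled cloud
before both hulls are computed; `hull_dim` defaults to 3, where exact
hull volumes (1-D range, 2-D shoelace over the hull vertices, 3-D
incremental beneath–beyond) are available. Capping the hull at the three
dominant pooled axes is the established dimensionality-reduction
convention for this index family; with the two-factor trait structure
below, three axes carry essentially all between-species trait variance.
Affinely degenerate communities get volume 0.

**FEve.** Branch evenness along the minimum spanning tree:
`EW_l = d_ij / (P_i + P_j)` per branch, `PEW_l = EW_l / Σ EW`, and
`FEve = (Σ min(PEW_l, 1/(S-1)) - 1/(S-1)) / (1 - 1/(S-1))`. The MST uses
Prim's algorithm with lexicographic tie-breaking so outputs are identical
across platforms. Two caveats are inherent to the index: at S = 2 the
normalizing denominator vanishes, so FEve is returned as missing; and
when pairwise distances tie exactly, equally minimal trees with different
branch sets exist, so no deterministic tie-break can make FEve invariant
to relabeling on such degenerate inputs (continuous trait data ties with
probability zero).

**FDis and Rao's Q.** FDis is the abundance-weighted mean distance to
the abundance-weighted centroid; Rao's Q is `Σ_{i<j} d_ij p_i p_j`. Rao's
Q requires a probability vector and refuses to renormalize silently.
Single-species communities return FRic = FDis = RaoQ = 0 with FEve
missing. Brute-force oracles — exhaustive spanning-tree enumeration via
Prüfer sequences (feasible to S = 7), double loops, literal sums — are
exported (`oracle_mst()`, `oracle_rao()`, `oracle_fdis()`,
`oracle_feve()`) and the test suite holds the fast paths to them at
1e-10.

**CWM, CV and ICV.** CWM is the abundance-weighted trait mean; a missing
trait value makes that trait's CWM missing rather than silently
renormalizing. CV is 100·sd/mean with the sample (n−1) SD — at three
quadrat replicates the n vs n−1 choice is material, and sample SD is the
field convention. The variation bands are weak [0, 15], moderate
(15, 35], large (35, ∞): the printed anchor points 0–15 / 16–35 / >36
leave (15, 16] and (35, 36] unassigned, and half-open intervals restore
continuous coverage while preserving the anchors. ICV averages each
species' biomass over replicates first, then takes μ/σ across species
(`method = "across_species"`). The verbal definition also admits a
per-species reading (mean over species of each species' replicate
μ_i/σ_i); that is implemented as `method = "within_species"` and is an
explicit switch because the two can disagree substantially — the package
never chooses silently. σ = 0 yields an infinite-stability sentinel
(+Inf) with a warning rather than an error.

## Ordination, screening and model averaging

The CWM PCA uses the trait **correlation** matrix (units are
heterogeneous) and fixes the sign of each component so its
largest-magnitude loading is positive — PCA signs are otherwise
arbitrary. Axis–environment strength is simple per-covariate OLS R²
(equal to squared Pearson r), the plain reading of per-covariate
correlation bars.

The Mantel test correlates upper-triangle distances, permutes rows and
columns of the second matrix simultaneously, and reports the one-sided
upper-tail `p = (1 + #{r_perm ≥ r_obs}) / (1 + n_perm)` with 999
permutations by default — the ecology convention. The test suite
verifies its type-I error calibration (rejection rate at α = 0.05 within
[0.03, 0.07] over 1000 null replicates) and the uniformity of null
p-values.

Multimodel averaging standardizes the response and all predictors, fits
OLS on every subset up to `max_predictors` (default 3 in the pipeline;
all subsets in the low-dimensional test cases), ranks by
`AICc = -2ℓ + 2k + 2k(k+1)/(n-k-1)`, and averages standardized
coefficients with Akaike weights over models with ΔAICc ≤ 4
(configurable). Averaging is full-model (zero-substitution): predictors
absent from a model contribute 0, which shrinks weakly supported
coefficients — the usual conservative default. Confidence intervals use
unconditional model-averaged standard errors. Relative importance is
reported two ways, because the two common definitions disagree: the
|averaged estimate| ratio (default output) and an Akaike-weighted R²
share (`importance_r2`). Near-collinear subsets (correlation-matrix
condition number above 1e8) are skipped with a warning.

## Composites and path models

BC deposition (DCa, DMg, DNa, DK), N deposition (DNO, DNH) and soil BC
(SCa, SMg, SNa, SK) blocks are summarized by the first axis of a
correlation-matrix PCA; scores are mean-zero and sign-oriented to
correlate non-negatively with the mean of the standardized indicators, so
"more deposition" is always positive.

All structural models here are recursive DAGs over observed or composite
variables, so per-equation least squares on standardized data reproduces
the global ML solution — the package implements this directly rather
than calling an SEM engine, and the test suite checks the equivalence
against direct minimization of the Wishart discrepancy
`F = log|Σ| - log|S| + tr(SΣ⁻¹) - p` to 1e-6. The implied matrix is
`Σ = (I-B)⁻¹ Ψ (I-B)⁻ᵀ` with the exogenous block of Ψ fixed at sample
values; `χ² = (n-1)F`, `df = p(p+1)/2 - free parameters` (edges +
endogenous residual variances + exogenous (co)variances),
`GFI = 1 - tr[(Σ⁻¹S - I)²]/tr[(Σ⁻¹S)²]`, and
`RMSEA = sqrt(max(χ² - df, 0)/(df (n-1)))` (0 at df = 0). Identification
requires a full-rank sample covariance (n ≥ p + 2) and estimable
equations; the saturated exogenous moments are not regression parameters
and do not count against the sample size, which matters late in pruning
when mediators that lose all parents become exogenous.

Pruning removes one edge per iteration — the retained path with the
largest p-value above α = 0.05 — and refits until all paths are
significant; single-step backward elimination is the reproducible
reading of "eliminate nonsignificant paths". Conventional acceptance
cutoffs (χ² p > 0.05, GFI ≥ 0.90, RMSEA ≤ 0.08) are reported via
`path_fit_acceptable()` and configurable. The shipped
`prior_model()` is a **reconstruction**: exogenous S/N/BC deposition →
{deposition pH, SOC, STP, SpH, SAKP, SBG} → one diversity response, with
direct deposition → response edges; the exact prior topology in the
motivating study design is not fully published, so the default is
user-overridable through the plain-text `cause -> effect` edge-list
format (`read_path_spec()`).

## What the synthetic generator emulates

`synthetic_config()` defaults encode the emulated field design: 45 sites
(3 emission sources × 5 distances × 3 sampling points, distances 0–2000
m), 3 quadrat replicates, 8 traits, a 30-species pool. Every covariate is
a distance-decaying deterministic trend plus Gaussian noise scaled by the
dimensionless `noise_sd` (default 1; 0 gives exactly the trend). The
four BC ions load 0.80–0.95 on one latent factor so their first PCA axis
is well-defined; soil Na is coupled to that factor with coefficient 0.8
by default, mirroring the strong BC-deposition–soil-Na association such
gradients show; N ions share a second latent; deposition pH declines
with S and N loads; STP rises mildly with N and BC.

Species traits follow a two-factor model — a conservative axis (LDMC,
LTC, LD loading +0.75–0.8, LT −0.8, LC +0.5) and an acquisitive axis
(LTN 0.7, SLA 0.6, LTP 0.35) — giving the CWM PCA a recoverable
two-axis strategy spectrum. Trait means and SDs are set to realistic
leaf-trait scales (e.g. SLA 8 ± 2.5 m²·kg⁻¹, LTC 400 ± 60 g·kg⁻¹).
Abundances are a softmax of Gaussian-niche log-suitability in the latent
trait plane (positivity and unit sum without truncation artifacts), with
a 0.5% detection threshold below which species are unobserved.

The two injected effects are defined on the standardized scale, and the
generator honors that by construction:

- `beta_bc_fd` (default −0.5): log niche breadth is
  `log σ_s = log 0.6 + 0.5 (β·BC_s + sqrt(1-β²)·η_s)` with standardized
  BC scores and unit-normal η, so β is exactly the standardized effect of
  BC on log breadth; FDis/FRic are monotone in breadth, and the fitted
  standardized BC → FDis path recovers β up to the mild attenuation of
  the breadth → dispersion map.
- `beta_stability_lt` (default +0.5): between-species biomass spread
  follows `m_i ∝ p_i^γ_s` with `γ_s = exp(-β_LT · z(CWM.LT_s))`, so
  communities with thicker leaves have more even biomass and higher ICV;
  replicate noise is lognormal with σ = 0.15, smaller than the
  between-species spread, matching the premise behind the μ/σ stability
  reading.

The generator reproduces the *statistical* structure the analysis
assumes — gradient-correlated covariates, trait-mediated abundance
responses, replicate biomass noise — and nothing else: no dispersion
physics, no ion chemistry, no spatial autocorrelation between sampling
points, no interannual variation, no trait plasticity (species trait
values are fixed across sites), and no observation error on traits.
Passing tests therefore demonstrate that the inference chain recovers
effects under its own assumptions, not that those assumptions hold in
any particular field system.

## Numerical choices and problem sizes

Hull visibility tolerance is scale-relative (1e-12 × point-cloud
extent); degenerate configurations return volume 0 by contract. MST ties
break lexicographically. PCA signs orient the largest-magnitude loading
positive. Abundance vectors must sum to 1 within 1e-9 at validation and
1e-8 inside Rao's Q. The per-stage random streams derive from one master
seed through a counter scheme, so adding a stage never shifts another
stage's randomness, and identical config + seed reproduce identical
artifact checksums.

The shipped verification uses problem sizes chosen to make each property
sharp at desk scale: 200 random communities (S ≤ 6, T ≤ 3) against the
brute-force oracles; 1000 null replicates × 999 permutations for Mantel
calibration; 100 replicates for AICc ranking; 50 replicate gradients of
300 sites for effect recovery (mean pruned BC → FDis path within ±0.15
of the injected −0.5, negative-path retention and positive ICV ~ CWM.LT
slope each ≥ 90%).

## Known limitations

FRic beyond three hull dimensions is deliberately unsupported; FEve on
exactly tied distances depends on the deterministic tie-break; the
Wishart χ² is asymptotic and poorly calibrated at the default 45-site
design with ten model variables (the recovery checks use 300 sites);
composite indicators assume one dominant axis per block; no partial
Mantel tests, no multiple-testing correction across the screening grid,
no latent-variable measurement models, and no bootstrap standard errors.
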