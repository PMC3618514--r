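---
title: "Cost-integrated wavelet connectomics: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-integrated wavelet connectomics: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`costnet` implements a resting-state functional-connectome analysis as a
single reproducible chain: regional BOLD series are turned into
band-restricted wavelet correlation networks, network topology is
summarised by cost-integrated efficiency metrics, population-level edge
structure is standardised as a mean statistical parametric network
(SPN), and the topological and diffusion-anisotropy measures are related
to dimensional trait scores by per-region general linear models with
false-discovery-rate control. This vignette explains each model, the
tunable parameters and their defaults, the numerical conventions, and
what the synthetic-data generator does and does not emulate.

## From BOLD series to weighted networks

**Wavelet correlation.** Temporal coherence between two regions is
measured in a single frequency band: both regional series are decomposed
with a 4-level maximum-overlap discrete wavelet transform (MODWT,
Daubechies least-asymmetric length-8 filter, "LA(8)"), and the Pearson
correlation of the level-*k* detail coefficients estimates the
band-restricted association. The MODWT is undecimated — every level
keeps one coefficient per timepoint — and shift-covariant, which makes
these correlations well defined for short physiological series. With
sampling interval `tr` seconds, level *k* captures
`[1/(2^(k+1) tr), 1/(2^k tr)]` Hz; at `tr = 2.5` the four levels are
0.1–0.2, 0.05–0.1, 0.025–0.05 and 0.0125–0.025 Hz, and level 3
(0.025–0.05 Hz, the conventional low-frequency resting-state band) is
the default analysis band.

Numerical conventions: the MODWT uses periodic (circular) boundary
handling, which preserves the exact energy identity
`||x||² = Σ_j ||W_j||² + ||V_J||²` that the test suite asserts;
boundary-affected coefficients are retained in correlation estimation by
default, and `exclude_boundary = TRUE` drops the standard count
`L_k − 1` per level for sensitivity analyses. A series must be at least
as long as the deepest equivalent filter (106 points for 4 LA(8)
levels); constant regional series are an explicit error rather than a
propagated `NaN`.

**Soft threshold.** Correlations map to edge weights as `w = |r|²`,
emphasising strong and penalising weak correlations without
binarisation. Weight matrices are symmetric, zero-diagonal, with entries
in [0, 1].

## Graph model and topology parameters

Thresholded networks are undirected binary graphs. For a graph with *N*
nodes, `M_C = N(N−1)/2` is the complete-graph edge count (11026 at
N = 149) and the wiring cost `K = M/M_C` is the mean off-diagonal
adjacency (for weighted graphs, the mean off-diagonal weight). Four
parameters are computed: nodal degree `k_i`; nodal efficiency
`e_i = mean_j 1/l_ij` over the BFS shortest-path lengths, with
`1/∞ = 0` for unreachable pairs; global efficiency `E_g = mean_i e_i`;
and local efficiency `E_l`, the mean over nodes of the global efficiency
of each node's neighbour-induced subgraph (the node itself removed,
paths confined to the subgraph). Nodes with fewer than two neighbours
contribute local efficiency 0, since their neighbour subgraph contains
no pair. These conventions are the standard efficiency-based
small-world formulation and are validated in the tests against
brute-force path and subgraph enumeration on all 4-node graphs and
random 7-node graphs, and against igraph on larger random graphs.

The kernels (bitset BFS plus a distance-1/2 shortcut for dense neighbour
subgraphs) are compiled code because they run inside the Monte-Carlo
loop below; the shortcut is exact, as only pairs without a common
in-subgraph neighbour fall through to a masked BFS.

## Cost integration

Any fixed weight threshold changes a network's wiring cost and hence its
topology, making between-subject comparison threshold-dependent. Cost
integration removes the arbitrariness by averaging a topological
parameter over thresholded graphs at all costs:
`X* = Σ_k p(k) X(G^k)` with `k` uniform over the achievable costs
`m/M_C`. `G^k` keeps exactly the `m = round(k·M_C)` heaviest edges
(round half to even; ties between equal weights break by ascending
`(i, j)` index so the graph is deterministic — with continuous wavelet
correlations ties have measure zero). Because exhausting all `M_C`
costs is expensive at N = 149, `X*` is estimated by Monte Carlo:
costs are drawn uniformly (with replacement by default; a flag disables
replacement) from the achievable costs inside `[0.05, 0.95]`, 200 draws
by default, and all requested metrics are evaluated on the identical
sampled graphs. The tests verify the estimator against the exhaustive
grid average on 20- and 30-node networks (a 2000-draw estimate lands
within 0.01 absolute; a 200-draw estimate within three analytic
standard errors, the quantitative content of "200 samples suffice").

**A saturation bound worth knowing.** For any graph,
`E_g ≤ 0.5 + 0.5·K`, with equality exactly when every non-adjacent pair
is at distance 2. A nearest-neighbour ring lattice reaches diameter 2
once each node links about half the network (cost ≳ 0.5 at N = 149) and
then *attains* this maximum; at cost 0.95 every graph has minimum degree
above N/2 and therefore diameter ≤ 2, so all graphs tie. Consequently
"brain networks have higher `E_g` than the regular lattice" can only
hold strictly below this saturation regime; above it the curves
coincide by arithmetic necessity. The package's validation asserts
strict ordering below saturation and documents the tie at the bound.

## Mean statistical parametric network

Individual correlation matrices differ in mean level and spread, so raw
thresholds are not comparable across groups. The mean SPN standardises
each edge's across-subject mean correlation `r̄^e` against the grand
mean and grand SD pooled over all subjects and all upper-triangle edges:
`z^e = (r̄^e − r̄)/sd(r)`. Seed-region profiles list first-degree
connections above a threshold in descending strength; the threshold is
either a raw correlation or a p-value mapped to a standard-normal
quantile (one-sided upper tail by default, `z > 2.576` at `p = 0.005`;
a flag switches to two-sided). Percentile thresholds use type-7 linear
interpolation.

## Trait association

Each regional (or global) measure is regressed by ordinary least
squares on the trait term(s) plus covariates: design 1 uses age and
gender (coded 0 = female, 1 = male), design 2 adds verbal IQ. The trait
effect is an F-contrast; the default is the joint 2-df test on the ASSQ
and SRS slopes, with 1-df single-score and combined-score contrasts
available. Effect size is the partial eta squared
`η_p² = F·dfh/(F·dfh + dfe)`, numerically identical to
`SS_effect/(SS_effect + SS_error)` on the same fit (asserted in tests).
A per-subject random intercept is not identifiable with one observation
per subject and region, so the within-person term is absorbed into the
residual — an explicit design decision, not an omission. Families of
per-region p-values (149 by default) are corrected by Benjamini–Hochberg
step-up FDR at α = 0.05; the implementation delegates to
`p.adjust(method = "BH")` and is checked against a brute-force step-up
oracle on a thousand random p-vectors.

## What the synthetic cohort emulates

The generator produces the study conditions the analysis assumes, at
their native scale: 127 subjects, 149 regions, 260 timepoints at
TR = 2.5 s.

**Phenotypes** come from a latent Gaussian copula over verbal IQ,
performance IQ, ASSQ and SRS. Marginals: VIQ ≈ N(106.9, 13),
PIQ ≈ N(108.5, 14), SRS a rounded clipped N(27.2, 19.4), and ASSQ a
clipped exponentiated Gaussian (`round(exp(1.34 + 0.98 z) − 1)`,
integers 0–39), i.e. right-skewed, matching the qualitative
normal/non-normal split of the two trait scales. Because a nonlinear
marginal attenuates Pearson correlation, the latent correlations are
inflated by the quadrature-computed factor `cor(Z, f(Z))` so the
observed-scale targets (VIQ–PIQ 0.55, VIQ–ASSQ −0.393, VIQ–SRS −0.343)
are hit in expectation; at n = 5000 the empirical correlations sit
within ±0.03 of the targets. At n = 127 a single cohort's correlation
estimate has a standard error near 0.08, so individual cohorts scatter
around the targets — the tests therefore assert unbiasedness across
seeds rather than a tight band per seed. The ASSQ–SRS latent
correlation is not an externally fixed quantity and is exposed as a
parameter (default 0.6). Age is a truncated normal on 18–65; gender is
drawn with P(male) = 78/127; both are independent of the trait scores.

**BOLD series** are sums of band-limited unit-variance signals plus
white noise: each region couples to its own community (8 roughly equal
communities by default), more weakly to a second random community, and
to a global signal, with heterogeneous loadings
(community U(0.5, 1.2), secondary U(0, 0.9), global U(0.2, 1.0),
noise SD 1). The shared signals are brick-wall filtered into the
level-3 band, so the wavelet stage is genuinely exercised: association
is concentrated where the analysis looks for it. The secondary
memberships matter for realism — with purely disjoint communities the
top 5% of edges are almost all within-community and the thresholded
graph shatters into cliques, unlike real connectomes; overlapping
memberships put strong bridges among the top-ranked edges so low-cost
graphs stay connected and the efficiency-by-cost curves show the
expected small-world ordering.

**Injected effects** act on coupling amplitude, not on correlations
directly. The designated hub's loadings on *all* its shared signals are
scaled by `1 + β_hub·z` (trait z-score, multiplier floored at 0,
default β = −0.5); scaling a single source would shrink the hub's total
variance and mechanically inflate its remaining correlations, the
opposite of the intended de-synchronisation. Every region's community
coupling is scaled by `1 + β_el·z` (default −0.1), a small global
synchrony effect that depresses mean local efficiency. FA values are a
per-region baseline U(0.35, 0.55) plus N(0, 0.03) subject noise, with
the designated regions shifted by `β_fa·z·0.03` (default −0.3).

**Label volumes** place region centres on a 3-D lattice with Gaussian
probability blobs (peak 0.9, SD 1.5 voxels at spacing 3) that overlap
deliberately, so the p > 0.25 threshold and the highest-probability
overlap resolution (ties to the lower region index) are exercised; FA
volumes built from the resolved labels round-trip exactly through the
probability-weighted extractor.

**What is not emulated** — and hence what passing tests do not show
about real data: no haemodynamic response function, no head motion or
scanner drift, no spatial autocorrelation or anatomically realistic
atlas geometry, no heavy-tailed physiological noise. The generator
validates the *statistical machinery* (band selection, thresholding,
integration, inference calibration), not preprocessing robustness.

## Reproducibility and problem sizes

A single master seed fans out deterministically to per-stage,
per-subject child seeds (`derive_seed()`, an affine mixer modulo
2³¹−1), so any stage can be re-run in isolation; seeded runs are
bit-reproducible and the pipeline writes a manifest with a canonical
configuration fingerprint. The test suite works at deliberately small
scales — 10–24 subject cohorts with 20–60 regions for module tests,
127 × 50 for the replicate power study, 127 × 149 for single-cohort
checks — sizes chosen so the full suite completes in about a minute
while every assertion still has the statistical resolution it claims.
`scripts/acceptance.R` re-runs the full chain at the native
127 × 149 × 260 scale.

## Known limitations

* The GLM is ordinary least squares per region; no mixed-effects or
  robust variants.
* Efficiencies are computed on binarised thresholded graphs only; no
  weighted-path efficiency.
* The mean SPN is descriptive (edge z-scores), not an inferential
  group-difference network.
* Phenotype correlation targets hold in expectation; single small
  cohorts scatter with the usual `O(n^{-1/2})` estimator noise.
* The `E_g`-versus-regular-lattice ordering is provable only below the
  saturation bound described above.
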