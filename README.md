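# costnet

Cost-integrated graph analysis of wavelet functional connectomes.

`costnet` is an R package for researchers relating resting-state fMRI
network topology (and regional white-matter anisotropy) to dimensional
phenotype scores. It implements, as one tested chain:

1. **Wavelet connectivity** — regional BOLD series are decomposed with a
   4-level maximum-overlap discrete wavelet transform (LA(8) filter);
   the Pearson correlation of level-3 coefficients (0.025–0.05 Hz at
   TR = 2.5 s) gives the band-restricted association `r_ij`, and the
   soft threshold `w_ij = r_ij²` gives a weighted network.
2. **Cost-integrated topology** — the threshold-free summary
   `X* = E_k[X(G^k)]`, where `G^k` keeps the `round(k·M_C)` heaviest
   edges and the wiring cost `k` is drawn uniformly from [0.05, 0.95]
   (Monte Carlo, 200 draws by default). Implemented for nodal degree
   `k_i*`, nodal efficiency `e_i*`, global efficiency `E_g*` and local
   efficiency `E_l*` (Latora–Marchiori conventions, `1/∞ = 0`).
3. **Mean statistical parametric network** — edge z-scores
   `z^e = (r̄^e − r̄)/sd(r)` of the population mean correlation against
   the pooled grand statistics, with seed-region first-degree
   connection profiles at correlation, percentile or p-value thresholds.
4. **Trait association** — per-region OLS of each metric on the trait
   terms (joint 2-df ASSQ + SRS contrast by default) controlling for
   age, gender and optionally verbal IQ; slopes `B`, effect sizes
   `η_p² = F·dfh/(F·dfh + dfe)`, and Benjamini–Hochberg FDR across
   regions.
5. **Probability-weighted extraction** — regional mean BOLD and mean FA
   from probabilistic label volumes (p > 0.25 threshold,
   highest-probability overlap resolution).
6. **Synthetic cohorts** — a generator of phenotypes (latent Gaussian
   copula with calibrated correlations, right-skewed ASSQ), band-limited
   modular BOLD with injectable trait effects, label volumes and FA
   tables, so the entire pipeline is testable without imaging data.

## Worked example

```r
library(costnet)

cfg <- pipeline_config(
  cohort = cohort_config(n_subjects = 24, n_regions = 30,
                         n_communities = 6, seed = 42),
  cost = cost_config(n_samples = 100)
)
res <- run_pipeline(cfg)

deg <- res$associations$degree
head(deg[order(deg$p_value),
         c("region", "f_stat", "p_value", "partial_eta_sq",
           "b_assq", "fdr_significant")], 3)
#>    region f_stat  p_value partial_eta_sq  b_assq fdr_significant
#> 1  l-R001  39.19 1.81e-07          0.805 -0.3501            TRUE
#> 5  l-R005   4.58 2.38e-02          0.325 -0.0543           FALSE
#> 19 r-R004   4.25 2.99e-02          0.309  0.1354           FALSE

mean(res$metrics$eg_star); mean(res$metrics$el_star)
#> [1] 0.697
#> [1] 0.816
```

The generator plants a negative trait effect on region `l-R001` (the
designated hub): the association table recovers it — a large F with a
negative ASSQ slope on cost-integrated degree, FDR-significant within
the 30-region family — while the remaining regions stay at chance
levels. The cohort's cost-integrated global and local efficiencies
(`E_g*` ≈ 0.70, `E_l*` ≈ 0.82) reflect the small-world regime the
modular generator emulates.

Seed-region profiles from the mean SPN:

```r
thr <- percentile_threshold(res$spn, "l-R001", 90)   # 0.698
prof <- first_degree_connections(res$spn, "l-R001", thr)
prof$connected_regions
#>   region strength
#> 1 l-R002    0.787
#> 2 l-R004    0.778
#> 3 l-R003    0.764
```

All stages are seeded: the same `pipeline_config()` reproduces
byte-identical outputs, and `run_pipeline(..., output_dir = )` writes
per-subject matrices, metric and association tables, and a JSON
manifest with a configuration fingerprint.

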