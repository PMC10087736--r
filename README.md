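# metafst

Population-genomic differentiation of marine microbial species estimated
directly from metagenomes, and attribution of its drivers.

Shotgun metagenomes from ocean surveys carry, within the reads recruited to a
species' reference assembly, the allele frequencies of that species'
population at every sampling station. `metafst` turns per-station allele-count
tables (from any metagenomic variant caller, TSV or VCF with allele depths)
into:

1. **Genomic distances** — per-SNP Wright FST with pair-restricted allele
   averaging, summarized per station pair as the *median* FST over the SNPs
   the two stations share; pairs sharing no SNP stay missing. The global FST
   is the mean of the pairwise values. Complete-linkage dendrograms (with
   mean imputation of missing pairs, used for clustering only) support
   heatmap displays.
2. **Candidate driver distances** — least-cost over-sea geographic distance
   on a land/sea grid (8-connected haversine shortest paths, km);
   environmental distance as Euclidean distance in the space of
   Kaiser–Guttman-retained PCA axes of standardized environmental variables;
   oceanographic distances from directed Lagrangian products (probability of
   connection averaged over 3/6/12-month horizons then symmetrized by max;
   mean connection time symmetrized by min).
3. **Driver attribution** — isolation-by-distance vs isolation-by-environment
   via ordinary least squares of the normalized genomic distance on the
   candidate distances,

   y = β₀ + β_geo·x_geo + β_env·x_env + β_pc·x_pc + β_mct·x_mct + ε,
   with y = FST/(1−FST),

   fitting all 2⁴ term subsets and selecting by BIC
   (n·ln(RSS/n) + k·ln(n)); the selected model is reported with per-term
   t-tests, the Fisher F-test against the intercept-only null, and R².

SNP cells are first filtered per station to the vertical-coverage window
[4, μ + 2σ): at least four reads, and fewer than two standard deviations
above that station's mean SNP coverage (screening reads recruited from
closely related species).

A synthetic-data generator with known ground truth (Balding–Nichols island
model; logit-Gaussian-process isolation-by-distance; per-SNP environmental
effects; panmictic null; sparse Poisson/negative-binomial read sampling;
two-basin sea grids with correlated environmental fields and
distance-decaying asymmetric connectivity) makes every stage testable
offline and powers the validation suite.

## Worked example

Simulate an isolation-by-environment survey (13 stations, 3000 SNPs, 10×
mean coverage), then run the full analysis:

```r
library(metafst)

cfg <- sim_config(scenario = "ibe", n_stations = 13, n_snps = 3000,
                  mean_coverage = 10, seed = 42)
sim <- simulate_dataset(cfg)

tab <- filter_snps_by_coverage(sim$table)
#> coverage filter: 32974/38998 observed cells kept (386 below 4 reads,
#> 1031 at/above mu+2sigma, 4791 below 1 alt reads); 0 SNP(s) removed entirely

fst <- pairwise_fst_matrix(tab)
fst
#> pairwise_fst: 13 stations, 0 pair(s) with no shared SNP
#>   global FST (mean pairwise): 0.0967 [moderate differentiation]

pca <- env_pca(sim$stations$stations)
pca
#> env_pca: 13 stations x 9 variables; 2 axis(es) kept (65.9, 13.4% of variance)

ocean <- oceanographic_distances(sim$stations$conn)
obs <- assemble_pairs(fst, geo = sim$stations$sea_dist,
                      env = env_distance_matrix(pca),
                      pc = ocean$pc, mct = ocean$mct)
fit <- exhaustive_bic_select(obs)
fit
#> Drivers of genomic differentiation (exhaustive BIC selection)
#>   n pairs: 78; models compared: 16
#>   selected terms: env
#>     beta_env = 0.02013  (t-test p = 6.488e-07, significant)
#>   overall F-test vs null model: p = 6.488e-07
#>   R2 = 27.96%
```

The generator planted an environmental effect; BIC selection recovers
`env` as the sole driver with a positive coefficient: differentiation
increases with environmental dissimilarity, not with geographic separation —
the isolation-by-environment signature. The filter log shows the coverage
window at work; the global FST of 0.097 sits in the moderate differentiation
class (bins at 0.05 / 0.15 / 0.25).

File-based workflows use `write_simulation()` + `run_pipeline()` (or the
CLI wrapper in `inst/cli/metafst.R` with subcommands `simulate`, `filter`,
`fst`, `distances`, `regress`, `pipeline`), which write all matrices, a
results-table summary, the dendrogram and a JSON run manifest.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the statistical
model, the filtering and symmetrization rules, the synthetic-data generator
and its calibration, numerical choices and known limitations.
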