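---
title: "Methods: estimating and explaining protist population differentiation from metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating and explaining protist population differentiation from metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metafst)
```

## The problem

Marine protists are too rarely culturable, and their field populations too
sparse per sample, for classical population-genetic surveys. Shotgun
metagenomes offer a workaround: reads recruited to a species' reference
assembly carry that species' allele frequencies at each sampling station, so
genomic differentiation between stations can be estimated without isolates.
`metafst` implements this estimation and the downstream question it exists
to answer: is differentiation structured by geography
(isolation-by-distance, IBD), by environment (isolation-by-environment,
IBE), by ocean circulation, or by none of them?

The package starts from per-station allele counts at biallelic SNPs — the
output of any variant caller applied to reads recruited per sample —
deliberately leaving read QC, mapping and variant calling to the dedicated
upstream tools.

## Coverage filtering

Metagenomic SNP calls are dominated by two artefacts: spurious low-support
calls, and positions whose coverage is inflated by reads from closely
related taxa. Both are screened by a per-cell vertical-coverage window: a
(SNP, station) cell is retained iff its coverage `c` satisfies

    min_cov <= c < mu + sigma_mult * sigma

with `min_cov = 4` reads and `sigma_mult = 2` by default. `mu` and `sigma`
are the mean and sample (n−1) standard deviation of coverage over that
*station's* covered SNPs (coverage ≥ 1): mean coverage varies by orders of
magnitude between stations, so a global window would be either vacuous for
deep stations or empty for shallow ones. The sample standard deviation is
used because per-station SNP sets can be small; a station with fewer than
two covered SNPs has no defined `sigma` and only the lower bound is applied
(with a warning). By default a retained cell must also carry at least one
alternate read (`min_alt = 1`); setting `min_alt = 0` restricts the rule to
coverage alone. Filtering is applied once; re-applying it can remove further
cells because `mu` and `sigma` change with the retained set, and the test
suite asserts the retained set is non-increasing under re-application.

## Genomic distances

For a SNP observed at both stations of a pair, with alternate-allele
frequencies $p_1, p_2$ and $\bar p = (p_1 + p_2)/2$ computed over *those two
stations only* (coverage differs so wildly between stations that a
grand mean over all stations would be dominated by the deep ones):

$$F_{ST} \;=\; \frac{H_T - H_S}{H_T}, \qquad
  H_T = 2\bar p(1-\bar p),\quad H_S = p_1(1-p_1) + p_2(1-p_2),$$

algebraically $(p_1-p_2)^2 / (4\bar p(1-\bar p))$, which is the form
implemented (non-negative in floating point). SNPs fixed for the same
allele in both stations ($H_T = 0$) carry no information and are excluded.
The pair's genomic distance is the **median** of the per-SNP values over the
shared SNPs — robust to the long right tail of per-SNP FST — and pairs
sharing no SNP stay missing rather than being guessed. The global FST is
the arithmetic mean of the non-missing pairwise values, each unordered pair
once. Frequencies enter unweighted by coverage; a coverage-weighted variant
was considered and rejected as the default because the median over SNPs
already damps noisy cells, but `snp_pair_fst()` operates on any frequency
matrix, so alternative weighting is a pre-processing step away. No
finite-sample (Weir–Cockerham-style) correction is applied; the estimator
is deliberately the plain two-population Wright form, and the read-sampling
bias it carries at low coverage is characterized below rather than
corrected.

Pairwise values are binned into the standard differentiation classes
(< 0.05 little, 0.05–0.15 moderate, 0.15–0.25 high, > 0.25 very high;
boundaries belong to the lower class by closed upper bound). For heatmap
dendrograms, missing pairs are replaced by the mean of the non-missing
off-diagonal entries and stations are clustered by complete linkage. The
imputation exists *only* for clustering: the regression below consumes the
matrix with missing pairs dropped.

## Candidate driver distances

**Geographic.** Stations snap to the nearest sea cell of a land/sea grid
(within 500 km by default); the distance between two stations is the
shortest path on the 8-connected sea-cell graph with haversine edge weights
(Earth radius 6371 km) — the minimal over-sea route, never crossing land.
Grid resolution is the user's choice; the discretization error is bounded by
roughly one cell diagonal, and the test suite asserts grid paths never
undercut the great-circle distance by more than that.

**Environmental.** Environmental variables (temperature °C, salinity PSU,
nutrients mmol·m⁻³, oxygen ml·l⁻¹, chlorophyll-a mg·m⁻³) are optionally
log1p-normalized (off by default; useful for right-skewed nutrient
concentrations), standardized, and decomposed by PCA on the correlation
structure. Axes are retained by the Kaiser–Guttman criterion — eigenvalue
strictly above the mean eigenvalue (1 after standardization), with a tiny
relative tolerance so an exactly flat spectrum retains nothing and asks for
an explicit axis count instead. Environmental distance is the Euclidean
distance over the retained axis scores used as-is: scores already scale
with the square root of their eigenvalue, so axes contribute in proportion
to the variance they carry. An optional flag additionally multiplies each
axis by its variance fraction, covering the stricter "variance-weighted"
reading; it is off by default because the scores are already
variance-weighted in the usual sense.

**Oceanographic.** Lagrangian transport products are directed: the
probability of connection (PC) within a dispersal horizon, and the mean
connection time (MCT, days). PC matrices for the 3-, 6- and 12-month
horizons are averaged per *directed* pair first (the average of a
per-direction quantity is itself per-direction), then symmetrized by the
maximum of the two directions; MCT is symmetrized by the minimum. The PC
diagonal is undefined and ignored; the MCT diagonal is 0.

## Driver attribution

Each unordered station pair with a non-missing genomic entry yields one
observation: response $y = F_{ST}/(1-F_{ST})$ (the standard linearization of
FST against distance; a pair with $F_{ST} = 1$ has no finite $y$ and is
dropped with a warning) and regressors $x_{geo}$ (km), $x_{env}$
(unitless), $x_{pc}$ (probability), $x_{mct}$ (days), all untransformed. An
optional z-scaling flag exists purely for numerical conditioning elsewhere;
coefficients are always reported on the original scales.

OLS is fit for **all $2^4 = 16$ term subsets** (intercept always included)
and the subset minimizing

$$\mathrm{BIC} = n\ln(\mathrm{RSS}/n) + k\ln n$$

is selected, $k$ counting the estimated coefficients including the
intercept. This is the Gaussian log-likelihood up to constants, the form
used by standard subset-selection implementations; any constant offset per
coefficient cancels in comparisons. Exact ties break toward the smaller
model. The selected model is reported with two-sided t-tests per term
(threshold 0.05), the Fisher F-test against the intercept-only null, R² in
percent, and the full 16-row BIC trace. Exact collinearity among candidate
regressors is resolved before enumeration by dropping the offending term
with a warning.

Pairs sharing a station are not independent, and plain OLS on pairwise
distances ignores this — deliberately, because the method being packaged is
exactly that linear-model analysis. A Mantel-style cross-check
(`permutation_check()`) permutes station identities, refits the selected
model, and reports the fraction of permutations reaching the observed R²;
it is an optional diagnostic, not the headline inference.

## The synthetic-data generator

No public dataset at desk scale carries known truth for this analysis, so
the generator is a first-class module. It emulates a Mediterranean-style
survey: a rectangular basin (optionally split by a land ridge with a
southern strait into two sub-basins), `n_stations = 13` stations on distinct
sea cells, nine correlated environmental variables with a configurable
east–west warm/oligotrophic gradient (`env_gradient = 0.4` sd units by
default; 0 makes the environment spatially exchangeable), directed PC
matrices decaying exponentially with over-sea distance (decay length
proportional to the horizon) under lognormal asymmetry noise
(`asym_sd = 0.8`), and MCT growing linearly with distance
(20 km/day, 5-day floor) with milder noise.

Station allele frequencies follow the scenario:

* **island** — Balding–Nichols: per SNP an ancestral $p \sim U(0.05,0.95)$,
  then station frequencies $\mathrm{Beta}\!\left(p\frac{1-F}{F},
  (1-p)\frac{1-F}{F}\right)$, giving variance $F\,p(1-p)$; the closed-form
  variance powers a moment test.
* **ibd** — per SNP, station logit-frequencies are a Gaussian-process draw
  with covariance $\sigma_{gp}^2\exp(-d_{sea}/L)$
  ($\sigma_{gp} = 1.4$, $L = 1500$ km), a desk-scale stand-in for
  stepping-stone coalescence with direct control of the distance decay.
* **ibe** — per SNP, a coefficient of magnitude `beta_env = 1.0` and random
  sign acts on the standardized temperature of each station:
  $\mathrm{logit}(p_s) = \mathrm{logit}(p) + b_l\,z_s + \varepsilon$. The
  random sign keeps the marginal frequency spectrum symmetric while making
  differentiation grow with environmental separation.
* **null** — all stations share $p$ exactly.

The ibd and ibe scenarios add residual logit noise whose standard deviation
varies *by station* (`sigma_noise = 0.8` scaled by a lognormal factor with
sd `station_sd_spread = 0.4`): stations differ in effective sampling, so
pairs carry baseline differentiation variance that no distance layer
explains. Without this, essentially all across-pair variance would be
driver-borne and the regression's R² would be unrealistically high. With
the defaults, the environment-only model explains on the order of 15% of
the variance of $y$ in the ibe scenario at 13 stations / 3000 SNPs / 10×
coverage — the regime of a moderate real-data effect — and the validation
suite requires the true driver to be selected with the correct sign in at
least 80% of 100 full-pipeline replicates (ibd analogously for geography;
under the null, intercept-only must be the modal selection). Exact
singleton selection is *not* required: MCT and PC are by construction noisy
monotone transforms of sea distance, exactly as in real oceans, so
occasional co-selection of a correlated term is the honest behaviour of
BIC at $n \approx 78$.

Read counts are sampled per cell: coverage from Poisson(`mean_coverage`) or
negative-binomial (over-dispersed/zero-inflated; reproduces station pairs
with *no shared SNP* at sparse coverage, e.g. mean 0.1×), then the
alternate count Binomial(coverage, true frequency). SNPs covered nowhere
are dropped, as they would never be called from reads. Everything is
deterministic given the config seed (stations, frequencies and reads use
fixed seed offsets, so the stages are independently reproducible).

What the generator does **not** emulate: linkage between SNPs (loci are
exchangeable and independent), selection, reference bias, mapping artefacts
of related taxa (the coverage ceiling is motivated by them but the
generator plants none), temporal variation, and multi-allelic sites.
Passing recovery tests therefore show the *statistical machinery* is sound
under the stated models — not that any real dataset satisfies those models.

## Numerical choices and edge cases

* Per-SNP FST is computed as $(p_1-p_2)^2/(4\bar p(1-\bar p))$ and clipped
  to ≤ 1; the numerator form is exactly non-negative in floating point.
* Medians over an even number of SNPs take the midpoint of the central
  values.
* An even-count coverage example worth remembering: when every coverage
  equals `min_cov`, `sigma = 0` makes the window `[4, 4)` empty and the
  station retains nothing — the strict upper inequality is intentional.
* Distance matrices are symmetrized exactly (`(d + t(d))/2`) after graph
  queries to suppress floating-point asymmetry; genomic matrices are the
  only kind allowed missing entries.
* The Kaiser–Guttman comparison uses a `1 + 1e-8` relative tolerance so a
  degenerate all-equal spectrum errors out with instructions rather than
  keeping whichever half of the eigenvalues rounded up.
* BIC ties (exact equality) resolve toward fewer terms; observation order
  never affects the result.
* Stations snapping into disconnected sea components produce an error
  naming the offending pair, not an Inf distance.

## Validation problem sizes

The test suite validates each stage against an independently coded oracle:
brute-force double loops for the coverage window and the median-FST matrix,
naive $O(n^3)$ agglomeration for complete linkage, $O(V^2)$ Dijkstra on an
explicit cell graph for over-sea distances, and normal-equations enumeration
of all 16 subsets for BIC selection. Oracle comparisons use 100 random
tables (filter), 100 random datasets of 78 pairs (BIC), 20 random
5-station tables (FST + clustering), and toy grids for geometry; recovery
checks use 13 stations × 2000–3000 SNPs with 100 replicates per scenario.
These sizes make the full suite run in a few minutes while keeping
Monte-Carlo margins wide (selection-rate thresholds sit ≥ 10 points below
the calibrated rates).

## Known limitations

* The FST estimator is uncorrected for finite read sampling; at low
  coverage it is biased upward. The suite demonstrates the bias at 5× and
  its shrinkage at 50× rather than hiding it. Comparisons across stations
  of very different depth should lean on the median's robustness and on the
  coverage ceiling, not on absolute FST values.
* OLS on pairwise distances inherits the usual non-independence caveat;
  p-values are anti-conservative to an unknown degree. Use
  `permutation_check()` when the selected model is borderline.
* The least-cost distance depends on grid resolution near straits; a strait
  narrower than one cell closes.
* Lagrangian connectivity is an input product; the package symmetrizes and
  averages it but cannot validate it.
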