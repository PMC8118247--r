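# trophica

Quantitative trophic ecology for fish diet studies, built around the
analyses a stomach-content + stable-isotope survey needs: prey-specific
diet indices, prey-curve sample-sufficiency testing, diet-based trophic
levels, permutational multivariate analysis of diet composition, and
bivariate isotopic niche metrics. The motivating use case is a multi-site,
multi-year survey of a pelagic mesopredator (a rockfish feeding on
euphausiids, gelatinous tunicates, amphipods, squids and fishes), but every
component is generic over per-stomach count/weight tables and per-fish
(δ¹³C, δ¹⁵N) tables.

## What it computes

**Prey-specific index family.** For prey category *i* over the *n* full
(non-empty) stomachs of a stratum:

- %FO*ᵢ* = 100 · (stomachs containing *i*) / *n*
- %PN*ᵢ* (%PW*ᵢ*) = mean per-stomach count (weight) percentage of *i*,
  averaged only over stomachs containing *i*
- %N*ᵢ* (%W*ᵢ*) = the same mean over **all** full stomachs, zeros included,
  so %N*ᵢ* = %PN*ᵢ* · %FO*ᵢ* / 100
- %PSIRI*ᵢ* = %FO*ᵢ* · (%PN*ᵢ* + %PW*ᵢ*) / 200 = (%N*ᵢ* + %W*ᵢ*) / 2,
  which sums to 100 across prey and is additive under category merging.

**Cumulative prey curves.** Expected number of distinct prey categories in
the first *k* stomachs under random ordering (randomized, or exact via the
hypergeometric closed form); sample size is judged sufficient when the OLS
slope over the last five points of the mean curve is ≤ 0.05 categories per
stomach.

**Trophic levels.** TL = 1 + Σ*ⱼ* P*ⱼ*·TL*ⱼ* per fish, with P*ⱼ* the diet
proportion (gravimetric by default) and TL*ⱼ* configurable prey trophic
levels; summarized per stratum.

**Multivariate diet analysis.** Bray–Curtis dissimilarities on per-stomach
%N or %W compositions; PERMANOVA (McArdle–Anderson distance-based linear
model, sequential SS, free permutation); Pearson screening of correlated
covariates (|r| > 0.65); forward stepwise model building ranked by
pseudo-F; PERMDISP dispersion tests; CAP (distance-based constrained
ordination) with axis tests and biplot scores.

**Isotopic niche.** C:N > 3.5 lipid screening, then the six niche metrics
per group: carbon/nitrogen ranges (CR, NR), convex hull area (TA), mean
distance to centroid (CD), mean nearest-neighbour distance (MNND) and its
standard deviation (SDNND).

A synthetic-data generator (`scenario()`, `simulate_diet_dataset()`,
`simulate_isotope_dataset()`) emulates the whole sampling design — empty
stomachs, zero-inflated counts over 8 generalized prey categories,
per-item weights, covariates, and bivariate-normal isotope groups — so the
full pipeline is testable without any external download.

## Worked example

```r
library(trophica)

d    <- simulate_diet_dataset(scenario("study"), seed = 42)
full <- apply_exclusions(d, drop_other = FALSE)
psiri(subset_stratum(full, "FAR", 2013), stratum = "FAR_2013")
```

```
Diet composition, stratum 'FAR_2013' (n = 39 full stomachs)
 category   %N  %PN   %W  %PW  %FO %PSIRI
     TUNI 71.1 73.0 79.2 81.3 97.4   75.2
     EUPH 13.5 19.5  5.6  8.2 69.2    9.6
     CRUS 11.2 19.8  6.6 11.6 56.4    8.9
     CEPH  2.5 32.9  5.5 71.5  7.7    4.0
     TELE  0.9 36.4  2.3 90.4  2.6    1.6
     AMPH  0.7 13.4  0.2  3.0  5.1    0.4
     ROCK  0.1  2.2  0.6 21.9  2.6    0.3
```

Tunicates dominate this simulated 2013 stratum (75.2 %PSIRI, present in
97.4% of stomachs); each row satisfies %N = %PN·%FO/100, and %N, %W and
%PSIRI each sum to 100. Sample sufficiency and the isotopic niche:

```r
cur <- accumulation_curve(subset_stratum(full, "FAR", 2013),
                          permutations = 999, seed = 7)
b <- endpoint_slope(cur)
sprintf("endpoint slope b = %.3f -> sufficient: %s", b, sufficiency(b))
#> "endpoint slope b = 0.051 -> sufficient: FALSE"

iso <- simulate_isotope_dataset(scenario("study"), seed = 42)
group_enc_table(lipid_filter(iso))
```

```
Isotopic niche metrics (per mil; TA per mil squared)
    group  n   CR   NR   TA   CD MNND SDNND
 COR_2013 31 1.39 1.14 1.09 0.41 0.11  0.06
 FAR_2013 30 1.20 1.05 0.87 0.33 0.10  0.06
 COR_2014 30 1.28 1.68 1.39 0.48 0.15  0.09
 FAR_2014 27 1.40 1.38 1.35 0.45 0.14  0.11
 HMB_2014 27 0.98 0.84 0.53 0.30 0.08  0.07
```

The slope of 0.051 prey categories per stomach sits just above the 0.05
threshold, so this 39-stomach stratum would be flagged as marginally
undersampled. The whole analysis can also be driven from one YAML config
with `run_full_analysis()`, which writes every stage's table as CSV.

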