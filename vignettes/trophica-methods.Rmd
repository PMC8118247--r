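---
title: "Methods and design of the trophica analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the trophica analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trophica)
```

This vignette documents the statistical methods the package implements,
the assumptions behind them, the parameters a user may want to change, and
the design decisions taken where more than one defensible convention
exists.

## Data model

A diet dataset is a matrix pair — per-stomach prey counts and prey weights
(grams, recorded at 0.001 g resolution) over a shared set of prey
categories — joined with per-fish metadata (location, year, month,
longitude, depth, total length, sex) and a prey taxonomy. The taxonomy has
two levels: *lowest* (e.g. Salpidae, *Pyrosoma* spp.) rolling up into
eight *generalized* categories (squids, unidentified crustaceans,
amphipods, euphausiids, tunicates, unidentified teleosts, rockfishes, and
a rare-prey "Other" bin). Aggregation to the generalized level conserves
per-record count and weight totals exactly, so every index that is a mean
of per-stomach percentages is additive under category merging.

Three record-level exclusion rules produce the analysis view
(`apply_exclusions()`): stomachs with no identifiable prey are always
removed (they still count in `sample_summary()` totals); records
containing exclusively Other prey are removed when `drop_other = TRUE`;
and mixed records have their Other contributions zeroed, after which
proportions are recomputed downstream. The operation is idempotent.
Unknown solids and liquids are represented as absence: an "empty" stomach
is one with all-zero identifiable prey. Bait and incidentally ingested
material (rocks, parasites) are assumed removed before the tables are
built, and counts are taken as final (minimum-count handling of paired
hard parts is a laboratory procedure, not a data-analysis one).

## The prey-specific index family

A prey *occurs* in a stomach if its count or its weight is positive —
well-digested prey can be weighable but uncountable, and this convention
keeps the occurrence set consistent between the numeric and gravimetric
metrics. With \(n\) full stomachs in a stratum:

\[
\%FO_i = 100\,\frac{n_i}{n}, \qquad
\%PN_i = \frac{1}{n_i}\sum_{k:\,i \in k} 100\,\frac{c_{ki}}{\sum_j c_{kj}},
\qquad
\%N_i = \%PN_i \cdot \%FO_i / 100,
\]

identically for weights, and
\(\%PSIRI_i = \%FO_i(\%PN_i + \%PW_i)/200 = (\%N_i + \%W_i)/2\).
`mean_percent_abundance()` evaluates both routes — the direct mean over
all stomachs and the prey-specific decomposition — and asserts agreement
to 1e-9, so the identity is checked on every call rather than trusted.
Tables are sorted by descending %PSIRI with alphabetical tie-breaks for
determinism. All values are kept unrounded internally; display rounding is
half-away-from-zero to one decimal (`round_half_up()`), the convention of
published composition tables. When reconstructing such a table from its
*printed* components, the inputs are already rounded, so reconstructed
cells are only guaranteed to ±0.1; the package's own tables do not have
this problem because they round last.

## Cumulative prey curves

`accumulation_curve()` averages, over random stomach orderings, the number
of distinct prey categories seen in the first \(k\) stomachs. The exact
expectation has a hypergeometric closed form — a category present in
\(n_i\) of \(n\) stomachs is missed by a random subset of size \(k\) with
probability \(\binom{n-n_i}{k}/\binom{n}{k}\) — and `method = "exact"`
computes it; the randomized estimator is unbiased for it, which the tests
verify at 999 permutations. The default of 999 permutations with a
required, recorded seed makes curves reproducible. The sufficiency
regression (`endpoint_slope()`) is ordinary least squares of the **mean**
curve on sample size over its final five points: published per-stratum
slopes are single numbers, which is consistent with regressing the mean
curve rather than per-permutation curves. The threshold \(b \le 0.05\)
categories per stomach is inclusive.

## Trophic levels

`fish_trophic_level()` computes \(TL = 1 + \sum_j P_j\,TL_j\), a linear
functional of the diet proportions, so it inherits linearity, invariance
to zero-proportion prey, and the bounds \(1 + \min TL_j \le TL \le 1 +
\max TL_j\). \(P_j\) defaults to gravimetric (weight) proportions —
standard where the interpretation is energetic — with a numeric basis
available, since published mean TLs do not always state which was used.
Prey trophic levels ship as defaults (`default_prey_tl()`) in which only
euphausiids (2.25) and teleosts/rockfishes (3.24) are anchored by the
convention that euphausiid-exclusive and fish-exclusive diets give TL 3.25
and 4.24; the remaining categories (squids 3.2, amphipods 2.5,
unidentified crustaceans 2.4, tunicates 2.1, other 2.5) are typical
literature values for pelagic taxa and are expected to be replaced with
study-specific assignments via the `prey_tl` argument or the pipeline's
`prey_tl:` config key.

## Distance-based multivariate analysis

All tests run on a dissimilarity matrix, Bray–Curtis
(\(d_{ij} = \sum_k |x_{ik}-x_{jk}| / \sum_k (x_{ik}+x_{jk})\)) for
compositions and Euclidean for oracle checks. The engine is the
McArdle–Anderson identity: with \(A = -D^2/2\) and the centering projector
\(J\), the matrix \(G = JAJ\) has \(\operatorname{tr}(G)\) equal to the
total sum of squares and \(\operatorname{tr}(HG)\) equal to the SS
absorbed by a design with hat matrix \(H\).

Conventions, chosen once and applied everywhere:

* **Sequential (Type I) SS**, matching stepwise model construction; term
  order is selection order. With Euclidean distance and one factor the
  pseudo-F reduces to the classical one-way ANOVA F (a test asserts this
  to 1e-9, and the whole term table is cross-checked against
  `vegan::adonis2` to 1e-10).
* **Free permutation of raw observations**, the simplest scheme consistent
  with unrestricted sampling; \(p = (b+1)/(m+1)\) including the observed
  statistic, so p-values are bounded below by \(1/(m+1)\). For \(n \le 8\)
  an exhaustive mode enumerates all \(n!\) relabelings, which the tests
  compare against a brute-force enumeration oracle.
* **Covariate screening** drops, from each pair with \(|r| > 0.65\) and
  \(p < 0.05\), the variable later in the user's priority order — which
  member of a correlated pair to keep is genuinely a modelling choice, so
  the order is an explicit argument rather than a hidden rule.
* **Forward selection** enters, at each step, the candidate with the
  largest pseudo-F among those with permutation \(p \le 0.05\) (entry
  threshold configurable; alphabetical tie-break), and the final table is
  re-ranked by F. Interaction terms are accepted as candidates but are off
  by default in the pipeline.
* **Negative eigenvalues.** Bray–Curtis is non-Euclidean, so the
  principal-coordinate embedding used by PERMDISP and CAP discards
  negative-eigenvalue axes and reports the discarded share of absolute
  inertia; this is the most common convention, and on Euclidean inputs it
  is exact (PERMDISP's centroid distances then match direct geometry, and
  CAP matches `vegan::capscale` axis for axis).
* **PERMDISP** recomputes group centroids and distances under each label
  permutation; **CAP** tests the overall model and each axis by permuting
  observations, and per-term tests reuse the PERMANOVA machinery in
  sequential mode by default, with a marginal mode available since either
  reading of a published CAP table is possible.

## Isotopic niche metrics

The lipid screen removes samples with C:N weight ratio strictly above 3.5
(the threshold itself is retained). CR and NR are coordinate ranges; TA is
the shoelace area over `grDevices::chull()` vertices, zero for fewer than
three distinct or collinear points; CD is the mean distance of
*individuals* to the group centroid; MNND/SDNND are nearest-neighbour
statistics in which a point is never its own neighbour, duplicate points
legally contribute distance zero, and SDNND uses the \(n-1\) sample
standard deviation. CD deserves a note: an alternative definition — the
mean distance between *population* means and a cross-population centroid —
appears in parts of the literature, but per-group tables of individual
spread are produced by the individual-level definition, which is what this
package computes. The metrics are translation invariant; CR, NR, CD, MNND
and SDNND scale linearly and TA quadratically under uniform scaling; and
TA ≤ CR·NR always.

## The synthetic-data generator

`scenario("study")` encodes the sampling design the package was built
around: five location × year strata with totals 40/56/104/125/108 and
empty-stomach probabilities 0.175/0.268/0.731/0.384/0.333; stratum mean
diet compositions over the eight generalized categories (tunicate- and
euphausiid-dominated in 2013, more mixed in 2014); mean item counts of
48/209/3/7/15 per stomach, reflecting an order-of-magnitude drop in
identified items between years; total lengths of roughly 40.6 ± 3.8 cm at
the offshore site versus 30–31 cm elsewhere; depths within 37–168 m; and
isotope groups of about 30 fish with δ¹³C between −19 and −16.3‰, δ¹⁵N
between 13.1 and 15.5‰, 2013 signatures more negative than 2014, and C:N
ratios Normal(3.3, 0.15) truncated to [3.0, 3.9] so a realistic fraction
exceeds the 3.5 screen. Per-stomach compositions are Dirichlet draws with
concentration 1.5, making individual diets dominated by one prey group, as
individual-level diet data typically are; item weights are lognormal with
category-specific medians (8 g rockfish items versus 0.02 g amphipods), so
numeric and gravimetric indices can rank prey differently. Each fish has a
deterministic RNG sub-stream derived from the base seed and its index, so
enlarging a stratum never perturbs previously generated fish.

Three reference scenarios support the statistical validation: `null`
(identical strata, for type-I error), `planted_location_effect`
(location-specific Dirichlet means, for selection power), and
`heatwave_shift` (a between-year swap of euphausiid for tunicate/teleost
weight, for sign checks on the constrained ordination).

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: within-stratum spatial autocorrelation,
prey-size/predator-size covariance, digestion-state measurement error in
counts versus weights, temporal autocorrelation within a sampling month,
and diet–isotope coupling at the individual fish level (diet and isotope
tables are generated independently). Conclusions about those structures
need real data.

## Problem sizes and numerical choices

The test suite validates the permutation machinery at sizes chosen for
exactness and statistical resolution rather than scale: exhaustive
enumeration at \(n = 6\) (720 orderings); type-I error over 1000 null
datasets of 20 stomachs at 99 permutations (acceptance band 0.03–0.07 at
\(\alpha = 0.05\)); selection power over 200 replicates of 250 fish at 99
permutations (required > 0.9); accumulation curves at 999 permutations
against the closed form; hull areas against a fan-triangulation oracle on
1000 random point sets. Equality tolerances are 1e-9 to 1e-12 wherever an
identity or oracle is exact; rounding comparisons use one decimal, and
reconstructions from printed (pre-rounded) inputs tolerate ±0.1.

Degenerate inputs are handled explicitly rather than by accident: all-zero
composition rows are an error in `bray_curtis()` (they should have been
excluded); records with zero total weight are dropped with a warning from
weight-basis proportions; single-member groups are excluded from PERMDISP
with a warning; groups of two get niche metrics but `TA = NA` in the group
table; aliased model terms are an error naming the term; and constant
covariates are dropped by the screen with a warning.

## Known limitations

PERMANOVA here supports crossed fixed effects and interactions but not
nested or random effects; distances other than Bray–Curtis and Euclidean
are not provided; richness extrapolation (Chao, jackknife) and
coverage-based rarefaction are out of scope for the prey curves; isotope
analyses stop at the six niche metrics — no Bayesian standard ellipses and
no mixing models; and trophic levels are diet-based only (no δ¹⁵N-to-TL
conversion). The per-term CAP p-values depend on the sequential/marginal
choice when terms are correlated; both are exposed and neither is claimed
to match any particular published table.
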