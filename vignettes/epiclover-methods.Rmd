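---
title: "Methods: band-based genetic and epigenetic variation analysis"
author: "epiclover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band-based genetic and epigenetic variation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiclover)
```

## Scope and data model

`epiclover` analyses dominant fingerprint data: binary presence/absence
calls of anonymous DNA fragments (AFLP) and of methylation-sensitive
fragments (MSAP) for individuals sampled from populations nested in habitat
groups. The universal currency is the `BinaryMarkerMatrix` — a complete
individuals × markers 0/1 matrix. Missing calls are deliberately not
representable: every downstream formula (band frequencies, squared
Euclidean distances, entropy) assumes complete data, and in practice
ambiguous fingerprints are re-run rather than imputed. Sample order is
taken from the metadata table and marker matrices are re-indexed to it, so
that individual- and population-level distance matrices align across the
genetic and epigenetic datasets.

One canonical CSV dialect (comma separator, `.` decimal) is used for all
tables, with `;`/tab accepted on input; fingerprinting toolchains export
inconsistently, and a single canonical form keeps write–read round trips
bit-exact.

## MSAP subepilocus scoring ("mixed scoring 2")

The isoschizomers HpaII and MspI cut the same CCGG motif with different
methylation sensitivity. Jointly the two profiles distinguish four states
per fragment and individual: band in both (`u`, unmethylated), MspI only
(`m`, methylation of the internal cytosine, CG context), HpaII only (`h`,
hemimethylation of the external cytosine, CHG context), band in neither
(uninformative — the site may be absent or methylated in a form invisible
to both enzymes).

`mixedScoring2()` expands each fragment into three candidate indicator
columns (u/m/h). An individual scores 1 in exactly the column matching its
state — the columns are mutually exclusive by construction, which makes the
transformation invertible (`profilesFromSubepiloci()`), a property the test
suite exercises on random profile pairs.

Two choices here were genuinely open:

* **Drop rule.** Only candidate columns that are all-zero across every
  individual are dropped; monomorphic *present* columns are retained.
  Retaining them is what makes "percentage of polymorphic subepiloci"
  meaningfully below 100%, and the counting identity
  `n_u + n_m + n_h = n_subepiloci ≤ 3 × n_fragments` holds on any input.
  Whether published marker totals excluded monomorphic-present columns can
  rarely be told from reports; the all-zero rule is recorded as this
  package's convention.
* **Error rate.** `genotypingErrorRate()` compares original and replicate
  calls cell-wise (fragments × replicated individuals) and reports a single
  percentage per marker system, matching how reproducibility is usually
  quoted for fingerprint data.

## Diversity statistics

For each population, `populationDiversity()` reports the percentage of
bands (markers with ≥ 1 presence), private bands (present here, absent in
all other populations), polymorphic markers (both states observed — no
minimum-frequency threshold, so with n = 16 a 1/16 variant counts; no
threshold is standard for dominant data and the thresholdless rule is
recorded as an assumption), and the mean Shannon information index. The SI
at a marker is read as the **two-state entropy** of band frequency `p`:

$$SI = -\left[p \log_2 p + (1-p)\log_2(1-p)\right], \qquad 0\log_2 0 := 0$$

so it is symmetric in `p` and `1 − p`, bounded by 1, and monomorphic
markers contribute 0. The one-term reading (`−p log₂ p` only) is bounded by
`1/e·log₂e ≈ 0.531`, which is inconsistent with published per-population
subepilocus SI values that reach 0.58 and above; only the two-term entropy
covers the observed range. Summary rows append the grand mean and the
standard error computed as the sample standard deviation across populations
divided by √(number of populations).

## Hierarchical AMOVA and Φ-statistics

Distances are squared Euclidean on binary rows — the number of markers at
which two individuals differ. The two-level partition (groups G,
populations K, individuals N) uses the standard distance-based sums of
squares

$$SS_{total}=\tfrac1N\sum_{i<j}d_{ij},\quad
  SS_{within}=\sum_k \tfrac1{n_k}\sum_{i<j\in k}d_{ij},\quad
  SS_{AP}=\sum_g \tfrac1{N_g}\sum_{i<j\in g}d_{ij}-SS_{within},$$

with `SS_AG` the remainder and degrees of freedom `G−1`, `K−G`, `N−K`.
Variance components come from the mean squares via the unequal-sample-size
coefficients `n′`, `n″`, `n‴`; for a balanced 2 × 5 × 16 design these are
16, 16 and 80, a closed form the tests assert. Φ-statistics are
`Φ_RT = V_a/V_T`, `Φ_PR = V_b/(V_b+V_c)`, `Φ_PT = (V_a+V_b)/V_T`.

Numerical conventions:

* **Negative variance components are truncated to zero** before percentages
  and Φ-statistics (the convention of the widely used spreadsheet AMOVA
  implementations, and the reason reported component tables contain no
  negative entries). Sums of squares are reported untruncated, so SS
  additivity holds to 1e−9.
* **Degenerate data** (all individuals identical) yield all-zero SS; Φ is
  reported as 0 with a warning rather than NaN.
* **Permutation p-values** use `(b + 1)/(m + 1)`, which cannot return 0 and
  treats the observed arrangement as one more permutation — whether
  spreadsheet implementations' "999 iterations" include the observed
  arrangement is not documented, and this estimator is the defensible
  choice for 999/9999-permutation designs. Ties are counted with a 1e−12
  tolerance so that permutations reproducing the observed statistic to
  floating error count as ≥.
* **Permutation schemes** per statistic: `Φ_PT` shuffles individuals across
  all populations, `Φ_RT` shuffles whole populations among groups, `Φ_PR`
  shuffles individuals among populations within their group.

`pairwisePhiPT()` runs the one-level analysis on each population pair,
truncating negative Φ to 0; the resulting matrix is the population-level
distance input to the Mantel/MMRR stage. Pairwise p-values can be computed
but are not consumed downstream — only the Φ values serve as distances.

## Mantel, partial Mantel and MMRR

All three operate on the `n(n−1)/2` upper-triangle entries of aligned
population-level matrices. The Mantel statistic is the Pearson correlation
of those vectors; significance comes from jointly permuting rows and
columns of the first matrix. The default tail is **upper** (positive
association), the convention of the ecology packages these tests come from;
this matters when interpreting large p-values attached to negative r. A
two-sided option exists. In the partial test the first matrix is permuted
and the first-order partial correlation is recomputed under each
relabeling; conditioning matrices collinear with an input raise an error
rather than returning an unstable ratio. For `n ≤ 7` an exhaustive mode
enumerates all `n!` relabelings, which the tests compare against a
brute-force oracle at n = 4.

MMRR standardizes each unfolded matrix (centred, unit standard deviation),
fits ordinary least squares with intercept, and permutes the response
matrix, recomputing all statistics each time: two-tailed on |t| for
coefficients, upper-tail for F. With a single predictor the standardized
coefficient is algebraically the Mantel r — asserted numerically in the
tests. Predictor sets with condition number above 1e6 are rejected, naming
the most correlated pair.

Geographic distances are haversine great-circle distances (mean Earth
radius 6371.0088 km) on unprojected coordinates, computed through
`geosphere`; at the ~100 km extent of a regional study the difference to a
projected planar distance is negligible. Habitat dissimilarity codes
unequal-habitat pairs 1 and equal pairs 0.

## Environment (Ellenberg indicator values)

`meanWeightedEiv()` computes per-site abundance-weighted means of species
indicator values, excluding species marked indifferent ("x") or missing
from the indicator list from both numerator and denominator. Abundances are
used on whatever scale is supplied (percent cover or transformed ordinal);
no internal transformation is applied, since the weighted-mean formulation
does not prescribe one. Species names match exactly after whitespace/case
normalization and unmatched species are reported, never silently dropped.

## Group statistics

`twoSampleTest()` operationalizes "t test, or rank test if necessary" with
a Shapiro–Wilk screen at α = 0.05 on each group: Welch's unequal-variance t
when both pass, Wilcoxon–Mann–Whitney otherwise, always two-sided; the
branch taken and the screen p-values are returned so either choice can be
audited, and a `force` argument pins the branch. Welch rather than pooled t
is the modern default of R's `t.test()`. Paired comparisons use the
classical paired t and refuse zero-variance differences. Correlation tests
report Pearson r with the two-sided t-based p on n − 2 df; a Spearman
variant is computed alongside in the pipeline's interdependence stage
because published reports sometimes quote a rank coefficient where a
product-moment one is specified — both are reported, neither asserted as
the other.

No multiple-testing correction is applied by default across the table of
group tests, mirroring common practice in this literature; corrected
p-values can always be obtained from the returned raw p-values with
`p.adjust()`.

## The synthetic-data generator

`simulationConfig()` defaults describe the canonical study: 2 habitat
groups × 5 populations × 16 individuals, 124 AFLP loci, 159 MSAP fragments.
Differentiation follows a Balding–Nichols-style Beta model: ancestral band
frequency `p ~ U(0.1, 0.9)` per locus; group frequency Beta-distributed
around `p` with variance `θ_group·p(1−p)`; population frequency Beta around
the group value with `θ_pop`; individual calls Bernoulli. Because the
among-population variance of a Bernoulli trait under this model is exactly
`θ·p(1−p)`, the simulated `θ` is the quantitative target that band-based
AMOVA Φ_PT estimates — the basis of the parameter-recovery checks. Defaults
`θ_pop = 0.04`, `θ_group = 0.03` place global Φ_PT near 0.07, the weak
differentiation regime typical of common outcrossing grassland species.
`θ = 0` passes frequencies through unchanged (the degenerate Beta limit).

Optional isolation by distance uses a Gaussian copula with exponential
spatial correlation `exp(−c·d_km)` on the population-level Beta quantiles:
marginals (and hence θ) are preserved exactly while neighbouring
populations become similar. The default is `c = 0` (no IBD).

MSAP fragments get a presence frequency from the same hierarchical model;
present copies draw a methylation state from fragment-specific (u, m, h)
Dirichlet weights, with two effect channels: `habitat_methylation_shift`
adds a log-odds increment to the m state in the second habitat (default
0.3, producing a small habitat contrast in m-subepilocus diversity), and
`env_effect` (default 0.3) turns standardized site moisture into a softmax
temperature so wetter sites have more even state distributions and hence
higher epigenetic diversity. Site environments are drawn from
habitat-specific normals (meadows wetter and more nitrogen-rich, calcareous
sites more alkaline and lighter), clamped to the Ellenberg range 1–9.

What the generator does **not** emulate: the empirical band-frequency
spectrum of real AFLP data (many rare bands), so absolute SI levels of
synthetic datasets are higher than typical published values; linkage and
shared fragment homoplasy; genotyping error; and any genetic–epigenetic
coupling (the two datasets are simulated independently). Passing tests
therefore demonstrate correctness of the estimators and calibration of the
tests under the generating model, not faithfulness of that model to any
particular field dataset. A related observable: the u/m/h indicator
expansion spreads each fragment's variation over three columns and adds
state-assignment noise, so epigenetic Φ_PT of synthetic MSAP data sits
below the presence-level θ used to generate it.

## Test and verification sizes

The suite verifies: exhaustive oracles (diversity on ≤ 4 × 4 matrices,
AMOVA on 8 individuals against literal double-loop sums, Mantel/partial
Mantel at n = 4 against all 24 relabelings); analytic identities (SS
additivity, balanced-design coefficients 16/16/80, single-predictor MMRR =
Mantel r, scoring round-trips); agreement of Mantel r and p with the
independent `vegan` implementation; Φ_PT parameter recovery (50 replicates
per θ ∈ {0.05, 0.10, 0.20} at the full 160 × 124 design, tolerance ±0.02);
and null calibration of all six permutation tests (500 replicates × 199
permutations each; rejection counts at the 5% level checked against the
99.8% binomial interval). These sizes were chosen to make Monte Carlo error
small relative to the tolerances while keeping the default run in minutes
on one core.

## Known limitations

* Two hierarchy levels only (group/population/individual); deeper designs
  and sequence-based AMOVA distances are out of scope.
* Fragment-size binning of raw electropherograms is upstream of this
  package; inputs are already-binned 0/1 matrices.
* Dominant markers conflate heterozygotes with dominant homozygotes; no
  allele-frequency back-calculation is attempted, and all statistics are
  band-(phenotype-)based.
* The Mantel family inherits the known inflated type-I behaviour under
  spatially autocorrelated non-exchangeable data; MMRR is offered
  alongside, not as a remedy.
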