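---
title: "Covariate-adjusted ordination of miRNA-mRNA co-expression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariate-adjusted ordination of miRNA-mRNA co-expression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ordimir)
```

## The problem

Joint miRNA and mRNA expression profiles from diseased tissue are riddled
with spurious correlations when the histological composition of the samples
varies. In necrotic liver, for instance, hepatocyte transcripts fall and
infiltrating-leukocyte transcripts rise in proportion to the amount of
necrosis; any two genes responding to the same compositional drift appear
strongly correlated (positively if they respond in the same direction,
negatively otherwise) regardless of any regulatory relationship. ordimir
implements an analysis chain that removes this confounding at the
correlation level and then maps the adjusted co-expression structure:

1. optional selection of differentially expressed genes by a multivariate
   permutation F-test with false-discovery-rate confidence control;
2. pairwise Kendall tau-b among all genes, replaced by first-order partial
   Kendall correlations with the histological covariate removed;
3. transformation of correlations into zero-centered nonmetric distances,
   `d = -tau`;
4. classical multidimensional scaling computed by singular value
   decomposition;
5. thematic map statistics: dispersion ellipses per functional class,
   density fields and their complementarity, per-miRNA median-correlation
   shifts between conditions, target-pair distance analysis with a
   sign-flip control, a multiple regression of mirSVR scores on
   per-dimension map distances, and seed-sequence grouping.

## Correlation model

**Kendall tau-b.** Expression levels in diseased tissue are far from
normal, so all pairwise association is rank-based. With concordant/
discordant pair counts `C`/`D` and tied pairs `n1`, `n2` within each
margin,

$$\tau_b = \frac{C - D}{\sqrt{(n_0 - n_1)(n_0 - n_2)}}, \qquad
  n_0 = \binom{n}{2}.$$

The implementation counts discordances by merge-sort inversion counting
(Knight's algorithm, `O(n log n)` per pair) in C++, so the full
640-gene matrix (204,480 pairs) takes about a second. A constant margin
makes the coefficient undefined; the package returns `NA` and
`pairwise_matrix()` aborts with the list of offending genes (silently
substituting 0 would distort the ordination geometry). A
`drop_constant = TRUE` escape removes constant genes instead.

**Partial correlation.** A single ordinal covariate (the necrosis grade)
is removed by the first-order formula

$$\tau_{xy\cdot z} =
  \frac{\tau_{xy} - \tau_{xz}\tau_{yz}}
       {\sqrt{(1-\tau_{xz}^2)(1-\tau_{yz}^2)}}.$$

With one covariate the first-order and higher-order schemes coincide, so
this is the only variant provided. A covariate rank-collinear with a gene
(`|tau| >= 1 - 1e-12`; the tolerance absorbs floating-point rounding at
perfect concordance) makes the pair undefined and is reported as an error.

**Bimodality diagnostic.** The confounding signature is a bimodal
distribution of all pairwise correlations. We quantify it with Sarle's
bimodality coefficient `(skew^2 + 1) / kurtosis` using plain moment
estimators, flagged bimodal above the uniform-distribution benchmark 5/9.
The original observation is visual; the coefficient is this package's
operationalization and its threshold is the standard benchmark, not a
fitted value.

## Ordination

Correlations become distances by `d = -tau` rather than `1 - tau`, keeping
the data zero-centered. The scaling step recovers the similarity
`S = -d`, double-centers it, `B = J S J` with `J = I - 11'/n`, and
factorizes `B` by SVD; coordinates are the left singular vectors scaled by
the square roots of the singular values. Two design points deserve
emphasis:

* *Why double-centering.* Applying SVD to the raw `-tau` matrix would mix
  the grand mean into the leading axis; the double-centered form is the
  classical-scaling interpretation consistent with zero-centered input and
  an SVD factorization, and it is what `reconstruct_similarity()` inverts
  exactly at full rank.
* *Nonmetric input.* `-tau` is not Euclidean, so `B` can have negative
  eigendirections. SVD absorbs their magnitude into the singular values;
  the per-axis sign pattern is returned in `axis_sign` so heavily
  non-Euclidean structure is detectable, and the reconstruction uses it.

Axis orientation is fixed by flipping each axis so its largest-magnitude
loading is positive, which makes coordinates reproducible across runs,
platforms and BLAS builds (up to that convention).

Sammon mapping and Kruskal's nonmetric MDS are provided as robustness
comparators (via `MASS`), both initialized from the classical
configuration, which also makes them deterministic. They require positive
dissimilarities: when the input contains nonpositive values the package
shifts all off-diagonal distances uniformly by `-min + eps` with
`eps = 1e-4` of the range. The shift is monotone, and rank order is all a
nonmetric method uses; the epsilon only moves the closest pair off the
zero boundary, which the optimizers reject. Agreement between
configurations is measured by the symmetric Procrustes correlation
`sqrt(1 - ss)` (via `vegan`), which is invariant to rotation, reflection,
scaling and translation.

Maps are drawn in the leading `k = 3` dimensions; `k = 50` dimensions are
retained for the mirSVR regression, matching that analysis' stated
dimensionality.

## Differential expression

The F statistic is the one-way ANOVA F on log2 values (with two groups,
the squared two-sample t). The multiple-testing rule is a
confidence-quantile formulation of multivariate permutation testing: genes
are ranked by observed F with ties broken by gene id; for each candidate
set size `m` the number of permuted F values at or above the m-th largest
observed F is counted in every label permutation, and the largest `m`
whose `confidence`-quantile of (count / m) is at most the FDR target is
selected. The exact internals of the tool that popularized this selection
are not public, so this formulation is documented as the package's own;
under the global null it selects anything in at most `1 - confidence` of
datasets, which the test suite verifies empirically (200 null replicates
of 100 genes x 20 samples at 500 permutations). Constant genes receive
`F = 0` and are never selected. Signed fold changes follow the
geometric-mean convention: `2^(mean case - mean control)` reported as `r`
when at least 1 and `-1/r` otherwise, and the fold-change filter is a
strict inequality (a gene at exactly the threshold is excluded).

## Thematic statistics

* **Dispersion ellipses** are covariance ellipses scaled by 1.6 standard
  deviations — the `ordiellipse`-style "sd" convention, not a chi-square
  quantile. Membership testing uses the Mahalanobis radius.
* **Density fields** are Gaussian KDEs on a regular grid covering the
  bounding box with a 10% margin, normalized over the grid; the
  miRNA/mRNA complementarity score is the Spearman correlation of the two
  surfaces across cells of a shared grid (negative = complementary
  occupancy). The original complementarity observation was visual; the
  score is our operationalization and is labeled as such.
* **Median-correlation shifts** compare, per miRNA, the median tau against
  all mRNAs in two conditions; classification uses a strict ±0.15
  threshold on the difference.
* **Target-pair analysis** measures Euclidean map distances of declared
  miRNA-mRNA target pairs against the background of all miRNA-mRNA id
  pairs. The sign-flip control negates both cross-species blocks of the
  association matrix (preserving symmetry) and re-runs the full ordination
  with identical settings — not merely re-signs coordinates — before
  re-measuring; when inhibitory and feed-forward couplings balance, the
  flip leaves the mean target distance essentially unchanged.
* **The mirSVR regression** uses the per-dimension absolute coordinate
  differences of each pair as 50 predictors of the pair's mirSVR score in
  an ordinary least-squares fit, summarizing with the multiple R² and the
  overall F-test p-value. The per-dimension absolute difference is the
  only per-dimension "distance" that is well defined.
* **Seed groups** are exact-string partitions after normalizing seeds to
  uppercase RNA alphabet (T to U); only groups of two or more are
  returned, singletons are counted in the attributes.

## The synthetic study generator

`generate_study()` emulates the motivating design: 109 miRNAs + 531 mRNAs
(640 genes) over 13 diseased and 17 control samples, with full ground
truth for every planted mechanism. Per gene and sample,

```
expression = baseline
           + direction * covariate_effect * necrosis_grade   (cases only)
           + block_effect_sd * block_factor[block, sample]
           + coupling terms
           + N(0, noise_sd)
```

Defaults and their rationale:

| parameter | default | rationale |
|---|---|---|
| `n_mirna`, `n_mrna` | 109, 531 | the study's differentially expressed panels |
| samples | 13 cases, 17 controls | the study's design |
| `necrosis_grades` | 1:4, cyclic | the grading scale is published elsewhere; any monotone numeric encoding is equivalent for rank-based analysis |
| `frac_hepatocyte_genes` | 0.5 | necrosis trades hepatocytes for infiltrate, so essentially every profiled gene belongs to one compartment; half down, half up, none neutral |
| `covariate_effect` | 1.0 log2/grade | a 3-grade span then moves a gene 8-fold, strong but realistic for compositional drift |
| `block_effect_sd` | 0.5 | functional co-expression visible above noise without dominating |
| couplings | 1.0 each | planted regulatory correlations clearly above sampling noise at n = 13 |
| `noise_sd` | 0.5 log2 | typical residual array noise |
| `n_target_pairs` | 200 | enough pairs to support a 50-predictor regression |
| `n_seed_groups` | 8 | the number of same-seed groups reported in the study |

Couplings are latent-factor contributions: an inhibitory pair loads a
shared standard-normal factor with opposite signs, a feed-forward pair
(transcription-factor co-activation) with the same sign. Pair signs are
drawn cyclically from the mechanisms whose strength is positive, so
setting `feedforward_coupling = 0` yields an inhibitory-only study. All
coupled pairs are declared in the target table, inhibitory pairs with
stronger (more negative) mirSVR scores. All randomness flows from one
integer seed through R's default Mersenne-Twister generator; identical
configs give bit-identical bundles.

What the generator does **not** emulate: probe-level microarray artifacts
and RMA preprocessing, heavy-tailed or skewed expression marginals,
multiple or latent covariates, dependence between the covariate and the
coupling machinery, and realistic miRNA target multiplicity. Tests passing
on this generator therefore demonstrate that the pipeline recovers the
planted mechanisms under Gaussian noise with a single observed
confounder — not that it would resolve every pathology of real arrays.

## Numerical choices and degenerate inputs

* Undefined correlations (constant genes) abort with the offending gene
  list; missing values are rejected at parse time with the cell location.
* Duplicate gene rows in input TSVs are averaged with a warning; duplicate
  sample ids are an error.
* Matrix round-trips through TSV are exact to 6 significant digits
  (`write_expression()` default).
* F-statistic ties are broken by gene id for a stable selection order.
* The permutation count must be at least 100: below that the permutation
  distribution cannot resolve a 1% FDR target.
* Intercept correction records an extrapolation caveat when zero lies
  outside the covariate range (it always does for necrosis grades 1-4).
* Thresholds (fold change, |R| screen, median-shift, ellipse membership)
  are strict inequalities throughout.

## Problem sizes used by the test suite

The suite exercises the full 640 x 13/17 design for the map-level
statistics, and scales Monte Carlo studies to keep the default run inside
a few minutes: the bimodality transition uses 20 replicates of 100 genes x
13 samples; the correction-improvement rate 100 replicates of 160 genes;
the null FDR calibration 200 replicates of 100 genes x 20 samples with 500
permutations; the regression null calibration 200 score redraws on a fixed
ordination. These sizes are the package's choices for a reproducible desk
run and are recorded here so users can scale them up.

## Known limitations

* The FDR-confidence selection is our documented reconstruction of an
  under-specified procedure; counts selected on real data will not match
  historical tool output exactly.
* The complementarity score and the bimodality coefficient operationalize
  claims that were originally visual.
* With 13 samples a single Kendall tau has a standard error around 0.2;
  individual pair correlations are noisy and only aggregate map structure
  should be interpreted.
* One observed covariate is removed; latent covariates (e.g. disease
  etiology) remain an open problem and are out of scope.
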