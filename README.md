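# ordimir

Covariate-adjusted ordination maps of joint miRNA–mRNA co-expression.

## The problem

When tissue composition varies across samples — necrosis replacing
hepatocytes with infiltrating leukocytes, tumor content, fibrosis — bulk
expression correlations are dominated by that compositional drift: any two
genes tracking it look strongly co-expressed whether or not they interact.
ordimir is for transcriptomics analysts who want to map the *genuine*
miRNA–mRNA, miRNA–miRNA and mRNA–mRNA co-expression structure of such
confounded case/control designs.

## The method

For genes *x*, *y* and an observed histological covariate *z* (e.g. the
necrosis grade), the package computes tie-corrected Kendall correlations

&nbsp;&nbsp;τ<sub>b</sub> = (C − D) / √((n₀ − n₁)(n₀ − n₂))

(merge-sort inversion counting in C++, O(n log n) per pair) and removes the
covariate with the first-order partial correlation

&nbsp;&nbsp;τ<sub>xy·z</sub> = (τ<sub>xy</sub> − τ<sub>xz</sub>τ<sub>yz</sub>) / √((1 − τ<sub>xz</sub>²)(1 − τ<sub>yz</sub>²)).

Correlations become zero-centered nonmetric distances, d = −τ, and the
distance matrix is embedded by classical multidimensional scaling via SVD of
the double-centered similarity B = J(−d)J. On top of the map it computes the
thematic statistics of this analysis style: 1.6-SD dispersion ellipses per
functional class, kernel density fields and their complementarity, per-miRNA
median-correlation shifts between conditions (±0.15 τ threshold), target-pair
distances with a sign-flip control, a 50-dimension regression of mirSVR
scores on per-dimension map distances, and seed-sequence grouping. A
multivariate permutation F-test with FDR-confidence control (1% FDR at 80%
confidence by default) provides the upstream gene selection, and a
synthetic-study generator with full ground truth (640 genes × 13 + 17
samples, necrosis covariate, functional blocks, inhibitory and feed-forward
couplings) makes the whole chain testable offline. All randomness flows from
a single integer seed through R's default Mersenne-Twister generator.

## Worked example

```r
library(ordimir)

bundle <- generate_study(study_config(rng_seed = 42))
necrosis <- bundle$samples$necrosis[bundle$samples$condition == "case"]

# raw vs covariate-adjusted correlation structure
distribution_profile(pairwise_matrix(bundle$case))
#> <tau_profile> 204480 pairs, bimodality coefficient 0.711 (bimodal)
assoc <- pairwise_matrix(bundle$case, covariate = necrosis,
                         covariate_name = "necrosis")
distribution_profile(assoc)
#> <tau_profile> 204480 pairs, bimodality coefficient 0.317 (unimodal)
```

The raw case-liver correlations are bimodal — masses of spurious strong
positive and negative correlations induced by the necrosis covariate — and
removing the covariate restores a unimodal, control-like distribution.

```r
ord <- classical_scaling_svd(to_distance(assoc), k = 3)
head(tidy(ord), 3)
#> # A tibble: 3 × 5
#>   gene_id species   dim1    dim2     dim3
#>   <chr>   <chr>    <dbl>   <dbl>    <dbl>
#> 1 miR-001 miRNA   0.0665  0.0149 -0.00967
#> 2 miR-002 miRNA   0.194   0.0906 -0.0777
#> 3 miR-003 miRNA   0.158  -0.406   0.0884

target_pair_analysis(ord, assoc, bundle$targets, n_dims = 3)
#> <target_distance_report> 200 pairs in 3 dims: observed 0.548,
#>   background 0.605 (sd 0.230), sign-flip 0.564
```

Declared target pairs sit at essentially the same mean distance after
flipping the sign of every miRNA–mRNA correlation and re-running the MDS
(0.548 vs 0.564, a shift of 0.07 background SDs): with balanced inhibitory
and feed-forward couplings, map distance alone does not read out repression
direction. `autoplot(ord, classes = ...)` draws the map with class
ellipses; `run_study_pipeline(run_config(...))` chains every stage and
writes TSV outputs plus a hashed manifest, and
`inst/scripts/ordimap.R` wraps it for the shell.

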