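---
title: "Single-SNP versus haplotype-block association scans in inbred panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-SNP versus haplotype-block association scans in inbred panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(haploscan)
```

## The question the package addresses

In a highly inbred crop panel every line is effectively haploid: one allele
per locus, genotypes coded 0/1. Genome-wide association in such panels can
test each SNP on its own, or first group map-contiguous SNPs into
multi-allelic *haplotype blocks* and test the block alleles jointly. Whether
blocking helps depends on the mutational and recombinational history of the
causal variant relative to the markers: a causal polymorphism younger than
the surrounding marker variants rides on a specific multi-SNP haplotype and
can be invisible to every single SNP. `haploscan` implements the full
benchmarking loop — synthetic panel generation, three blocking rules,
parsimony-tree edge tests, a mixed-model likelihood-ratio scan of arbitrary
degrees of freedom, phenotype simulation with controlled genetic
architecture, and power evaluation at an empirical false discovery rate — so
the comparison can be run end to end on data generated in seconds.

## The association model

Every scan fits the mixed linear model

y = X b + h + e,  h ~ N(0, sigma_g^2 K),  e ~ N(0, sigma_e^2 I),

where `K` is an allele-sharing kinship matrix (proportion of markers at
which two lines carry the same allele) that absorbs polygenic covariance and
population structure, and `X` contains an intercept (optionally
breeding-program contrasts) plus the tested locus's columns. Writing
`delta = sigma_e^2 / sigma_g^2`, one eigendecomposition of `K` (and of the
projected `K` for REML) turns every likelihood evaluation into an O(n)
expression — the spectral trick that makes genome-wide likelihood-ratio
scans cheap. The variance ratio is estimated once per phenotype under the
null model (100-point log-spaced grid on `[1e-5, 1e5]` refined by bounded
scalar search) and reused across loci; `lrt_scan(refit = TRUE)` re-optimizes
it under every alternative as a validation mode. The fast mode tracks the
exact refit tightly for weak signals and is conservative (never larger) at
strong ones, which costs a little power but no false positives.

Likelihood-ratio tests of fixed locus effects use full ML, not REML,
because the fixed-effect sets differ between null and alternative and REML
likelihoods are not comparable across fixed-effect models. The statistic is
referred to a chi-squared distribution with degrees of freedom equal to the
number of tested columns: 1 for a SNP, `k - 1` common-allele columns plus a
pooled-rare column for a block with `k` common alleles (rare columns whose
carrier mass falls below `rare_floor = 0.028` are dropped from the test),
and 1 for a tree edge.

Two scales of heritability are reported by `fit_variance_components()`. The
model-scale ratio `sigma_g^2 / (sigma_g^2 + sigma_e^2)` is what the
optimizer sees, but with an allele-sharing `K` it is not the phenotypic
genetic fraction: next to an intercept only the double-centered part of `K`
is identifiable, so `h2_realized` rescales `sigma_g^2` by the mean diagonal
of the double-centered kinship. It is `h2_realized` that recovers the
simulated heritability.

## Blocking rules

All blocking runs on the original (pre-imputation) calls with complete-case
haplotype counting; imputed probabilities enter only the design matrices.

* **Four-gamete blocks** grow greedily left to right; a SNP joins the
  current block unless, against any SNP already in the block, all four
  two-locus gamete classes are observed each above the recombinant cutoff
  (default 2%). Applying the pairwise test against *every* SNP in the block
  (not only the adjacent one) is our reading of the method; it is recorded
  as a dialect choice since the original software's internals are not
  restated anywhere we could follow.
* **Diversity blocks** partition each chromosome by dynamic programming so
  that within every block at least 97% of lines carry a haplotype of
  frequency at least 0.028, minimizing the number of segments and breaking
  ties toward more SNPs inside multi-SNP blocks. The coverage constraint is
  the binding definition; the DP objective is our choice among the several
  criteria diversity-based blockers offer. The DP caps candidate blocks at
  `max_span = 30` markers, matching the scale of block sizes seen in
  practice and bounding compute.
* **Sliding windows** block every run of three consecutive SNPs,
  overlapping, so the whole map is covered and a chromosome with `n` SNPs
  yields `n - 2` loci.

For a block with `k` common alleles (frequency >= 0.02, most frequent
first), the incidence matrix holds `k` columns per block: the probabilities
of carrying alleles `2..k` and of carrying a pooled rare allele. A line that
certainly carries allele 1 is all zeros for that block. Haplotype-allele
probabilities are products of per-SNP allele probabilities from imputation,
so missing data turns into fractional design entries rather than lost lines.
Unblocked SNPs enter as single minor-allele-probability columns.

## Parsimony-tree edge tests

Four-gamete block alleles usually admit a *perfect phylogeny* (no site pair
shows all four gametes). Each segregating site then induces one edge of the
parsimony tree; sites with identical bipartitions stack onto one edge, and
the tree length equals the number of segregating sites. Alleles that break
compatibility (recombinants) are dropped lowest-frequency-first — the drop
rule is ours, since only "recombinant alleles that do not fit" is knowable
from the method's descriptions — and reported as excluded. Every
positive-length edge produces two design columns: the probability of
belonging to the clade away from the most frequent allele, and the
probability of belonging to neither clade (rare or excluded haplotypes).
Each edge is tested with 1 df against a null that already contains the
"neither" column, so the contrast is genuinely between the two clades; the
minimum p over a block's edges is the block's representative test.

## Synthetic data: what it emulates, and what it does not

`generate_genotypes()` builds lines as mosaics of a small founder pool
(default 8). Founder alleles follow a Markov chain along each chromosome
with retention `ld_strength * exp(-d / ld_decay_cM)` per interval and a
piecewise-constant regional target frequency; lines switch founders with
probability `0.5 * (1 - exp(-d / recomb_scale_cM))`. Tied map positions are
created by giving geometric-size clusters of adjacent markers one cM value.
Defaults (`ld_strength = 0.60`, `ld_decay_cM = 5`, `tie_fraction = 0.6`,
`maf_min = 0.028`, `missing_rate = 0.007`) were chosen once so that a
2098-marker, 7-chromosome panel reproduces the summary statistics the
analysis assumes — roughly 60% of adjacent pairs co-located, mean adjacent
r² ≈ 0.45 (median ≈ 0.37), MAF floor exact with median ≈ 0.27 — and then
frozen. The MAF floor is enforced exactly by flipping founder alleles at
offending markers rather than dropping markers, so the requested marker
count is honored.

The generator does **not** emulate breeding-program substructure beyond
what the founder pool induces, coalescent site-frequency spectra, or any
non-random missingness (missingness is MCAR because nothing in the study
design implies a mechanism). Tests passing on these panels therefore show
that the machinery is correct and that the qualitative power orderings hold
under block-like LD; they do not certify power values for any real panel.

## Phenotype simulation

A simulated phenotype is `a*q + g + e`: `q` the centered carrier indicator
of the QTL (a SNP, or a two-SNP allele combination at the center of a
block), with `a` inversely proportional to `sd(q)` so QTL of different MAF
contribute equal variance; `g` the centered sum of polygene marker scores
(one marker per k-means cluster of marker profiles, so no block contributes
twice); `e` Gaussian. By default the polygene and error are orthogonalized
against the components before them and the three are rescaled so that the
*in-sample* variance fractions are exactly `p` (QTL) and `h2` (QTL +
polygene). Exact scaling makes calibration checks sharp
(`exact_scaling = FALSE` restores expectation-only scaling, under which the
realized fractions scatter around their targets). Pair-QTL use combination
(0,0) at block positions 1–2 (sliding windows) or at the two center SNPs
(other blockings), with (0,1) assigned to a seeded random subset when more
specs are requested than blocks exist; combinations carried by fewer than
2.8% of lines are discarded.

## Power at an empirical FDR

A discovery is true when the locus's nearest point — the SNP position, or
the closest boundary of the block interval — lies within 10 cM of the QTL
(the "20 cM window" is ±10 cM; the two phrasings found in practice are
reconciled by exposing a single `window_cM` parameter). Power at a nominal
threshold is the fraction of replicates with at least one true discovery;
FDR is `1 - true/total` pooled over replicates. Power *at* an FDR of 0.10
or 0.20 is interpolated by a local linear regression of power on FDR over
the nearest 10% of curve points, and its standard error comes from
bootstrapping replicate rows of the p-value matrix. Permutation thresholds
take the EER quantile of per-permutation minimum p-values; solving the
Sidak/Bonferroni relation `1 - (1 - t)^m = eer` for `m` yields the
effective number of independent tests.

## Numerical choices and degenerate inputs

* Kinship is made PSD by clipping negative eigenvalues at zero; line pairs
  with no jointly observed marker are an error, not a guess.
* LD metrics are complete-case; a locus monomorphic on complete cases gives
  `NA`, never 0. χ²′ standardizes the Pearson statistic by
  `N (min(k, l) - 1)` and coincides with r² for biallelic pairs.
* Tied-marker ordering enumerates all orders for runs of ≤ 8 markers
  (≤ 40,320 permutations) and uses repeated 2-opt from the input order above
  that; marker IDs break exact objective ties, so results are deterministic.
* Imputation is a windowed nearest-haplotype vote (10 flanking markers per
  side, 20 most similar donor lines, similarity-weighted allele frequency).
  It is a deliberately simple, pluggable stand-in for model-based haplotype
  imputation; on LD-structured panels it beats the majority-allele baseline
  comfortably, which is all the incidence matrix needs.
* Rank-deficient locus designs are reported `tested = FALSE` with `NA` p
  rather than silently skipped.
* The trial-BLUP stage gates multi-location program datasets on entry-mean
  repeatability `s2_line / (s2_line + s2_e / l) >= 0.5` — the threshold is a
  config default, chosen because the source value is not legible — and
  single-location datasets on a CV below 10%; records beyond 3 standardized
  SD within a trial are removed; disconnected trial designs are an error
  naming the groups.

## Problem sizes

The test-suite and acceptance sizes are deliberate package choices: unit
tests run on panels of 100–300 lines and a few hundred markers; the
calibration checks use 400 lines × 500 markers with 200 replicates; the
analysis drivers under `analysis/` run a scaled study (400 selected lines,
600 markers, 40 QTL × 3 replicates per cell, 300 bootstrap resamples,
200–1000 permutations). Scaling replicate counts down widens Monte-Carlo
error but leaves every qualitative contrast (power orderings, blocking
diagonal dominance) intact, which is what the property checks assert.

## Known limitations

* The four-gamete and diversity blockers are documented dialects of their
  namesakes, not bit-level replicas of Haploview or HapBlock.
* The imputation stand-in ignores genotype uncertainty beyond the local
  window and does not phase genuinely diploid heterozygous data.
* TreeScan-style edge tests are only built for four-gamete blocks (other
  blockings can contain enough recombination that no single best tree
  exists).
* Power numbers from the synthetic study are not comparable to any real
  panel's values; only their orderings and the calibration targets are.
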