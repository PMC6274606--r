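---
title: "Methods: cross-species integration of aggression gene evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species integration of aggression gene evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossaggr)
```

## The problem

Human genome-wide association studies (GWAS), transcriptome studies of
selectively bred rodent models, and causal gene reports (OMIM single-gene
disorders, knockout-mouse aggression phenotypes) each implicate genes in
aggressive behaviour, and each has distinct blind spots. `crossaggr`
integrates such evidence across species: it tests whether the gene lists
overlap more than chance, ranks individual genes by weighted cumulative
evidence, compares the lists' biological-pathway profiles, and asks
whether genes backed by human versus rodent evidence occupy different
positions in an interaction network.

The package works on nine evidence lists: two human GWAS lists (adult and
child), four rodent transcriptome lists (three selectively bred mouse
strain pairs — denoted Finland, Holland, USA — and one rat line pair),
two high-risk lists (OMIM, knockout mice), and a non-aggression GWAS
control list. Rodent symbols are converted to human orthologs before any
comparison.

## Overlap testing

The overlap of two lists of sizes $K$ and $n$ sharing $k$ genes, drawn
from a universe of $N$ genes, is tested with the one-tailed (enrichment)
Fisher's exact test, i.e. the upper-tail hypergeometric probability

$$P(X \ge k) = \sum_{i=k}^{\min(K,n)}
  \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}}.$$

The tail is accumulated in log space from log-binomial coefficients, so
very small p-values are computed without term-wise underflow. The default
universe is $N = 22{,}000$, the approximate number of known genes shared
by the designs being integrated; it is a visible parameter
(`universe`) because the effective universe of any particular study pair
(array coverage, annotation release) is rarely knowable exactly, and the
test is sensitive to it at small $k$. Pairwise tests across the nine
lists are reported uncorrected at $\alpha = 0.05$, with an optional BH
adjustment, matching the descriptive role of the all-pairs table;
category-level tests (GWAS vs transcriptome vs high-risk unions) use the
same statistic.

## Weighted gene ranking

Each gene's evidence is counted once per list (binary membership) and
tallied per category: $g$ over the two GWAS lists, $r$ over the four
transcriptome lists, $h$ over the two high-risk lists. The weighted score
is

$$\text{score} = 1 \cdot g + 0.5 \cdot r + 1.5 \cdot h,$$

up-weighting causal evidence by 50% relative to GWAS and discounting
rodent transcriptome evidence to 0.5 — which also equalizes the maximum
contribution of the four rodent lists (2) with that of the two GWAS lists
(2). The maximum score is 7. Ties are broken by total occurrence count,
then alphabetically, giving a reproducible total order. The default
reporting threshold is score $\ge 2$ (inclusive).

## Co-expression modules

The transcriptome stage is a deliberately minimal variant of weighted
gene co-expression network analysis:

* **Adjacency** $a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$ (unsigned,
  no topological-overlap transform). The soft power $\beta$ is the
  smallest candidate whose connectivity distribution fits a scale-free
  topology with $R^2 \ge 0.8$ (signed fit index; argmax fallback with a
  warning).
* **Clustering**: average-linkage hierarchical clustering of
  $1 - a_{ij}$, with a *static* cut at height 0.88 (default). The cut
  height is an implicit correlation bar: at the conventional power 6,
  admitting a gene below dissimilarity 0.88 requires its average
  correlation with the module to exceed roughly
  $(1-0.88)^{1/6} \approx 0.70$. Cuts much closer to 1 admit
  chance-level correlations — with a dozen samples, absolute
  correlations near 0.6 arise by chance among a few hundred genes — and
  in our simulations such cuts attach unrelated background genes to
  real modules; cuts much below 0.88 begin to shatter coherent modules
  whose eigengene happens to have low sample variance. Weakly coherent
  modules can still be recovered by raising the cut explicitly. A
  static cut was chosen over dynamic tree cutting because it is
  deterministic and has one interpretable parameter. Clusters smaller
  than `min_module_size` (default 20) are left unassigned and are not
  tested.
* **Eigengene**: first principal component of the gene-standardized
  module submatrix, unit-norm, sign-oriented to correlate positively
  with its members on average.
* **Association**: two-sided pooled-variance t-test of the eigengene
  between high- and low-aggression groups; BH adjustment across the
  modules of one dataset; selection at BH $p < 0.05$ (strict), with an
  optional relaxed rule (uncorrected $p < 0.005$) for designs that
  pre-specify a lenient criterion for a given dataset. Up- and
  down-regulated module gene sets from one strain pair can be merged
  into a single evidence list (`merge_module_sets()`).

The pooled-variance t-test is the smallest-assumption default for the
tiny group sizes typical of these designs (Welch is available via
`var_equal = FALSE`).

## Pathway profiles and MDS

Each evidence list is tested for over-representation in every pathway of
a user-supplied GMT collection with the same hypergeometric statistic,
over the configured gene universe (not the GMT union — the choice is
explicit because reference-set conventions differ between tools).
$-\log_{10} p$ values are reported and enrichment is coded binary at
$p < 0.05$ (strict). Profile similarity between lists is the
Rogers–Tanimoto dissimilarity of their binary vectors,

$$d = \frac{2(b+c)}{a + d_0 + 2(b+c)},$$

where $a$/$d_0$ count matching 1s/0s and $b+c$ the mismatches
(double-weighted). Classical (Torgerson) metric MDS embeds the
dissimilarity matrix: double-center $-\tfrac12 J D^{(2)} J$,
eigendecompose, take the top positive eigenpairs (default 4 dimensions).
Rogers–Tanimoto matrices are generally non-Euclidean; negative
eigenvalues are excluded from both coordinates and the
variance-explained denominator, with a reported count. Axis signs are
fixed by a largest-magnitude-positive rule so embeddings are
reproducible.

## Network degree comparison

Top-ranked genes are classified by evidence source — `human_only` (GWAS
and/or OMIM only), `rodent_only` (rodent transcriptome and/or knockout
mice only), or `both`. Note the high-risk *weighting* category mixes
species; the classification deliberately splits it. Given an interaction
network, log10 degrees are compared between classes by median (quantile)
regression on a binary class indicator; with a single binary covariate
the median-regression slope equals the difference of class medians,
which is computed in closed form. Inference uses a seeded stratified
case bootstrap (default 1000 resamples; two-sided percentile p with
add-one correction), a distribution-free construction that is fully
specified and reproducible. Genes with degree 0 are excluded (log
undefined) with a warning.

## The synthetic-data generator

The generator produces inputs with exactly the statistical structure the
stages assume, so the pipeline is testable end to end without any
external downloads:

* **Gene lists**: drawn from a synthetic universe `G00001..G22000` with
  the nine study list sizes (175, 281, 89, 381, 271, 397, 85, 211, 172)
  and the published pairwise overlap counts hit *exactly* by
  constructive allocation (shared genes first, then unique fill), rather
  than rejection sampling.
* **Expression**: additive eigengene-plus-noise model — three planted
  25-gene modules, 150 background genes, 6 + 6 samples, noise SD 0.5;
  the first module's eigengene differs between groups by 3 SD. These
  sizes mirror the small selectively-bred designs the method targets;
  the standardized shift of 3 gives an effect a 6-vs-6 t-test can
  detect reliably without being trivial at the chosen noise level.
  Arrays are not emulated at probe level.
* **Pathways**: 50 pathways of 20–120 genes; three planted pathways
  share 40% of their members with the child-GWAS list, the rest drawn
  uniformly.
* **Network**: a configured-degree (Chung–Lu) random graph with expected
  degree 12 for human-evidence and dual-evidence nodes, 4 for
  rodent-only nodes and 3 for 160 background nodes — a planted 3:1
  degree ratio of the kind the degree contrast is meant to detect.

A single root seed derives independent per-stage streams, so adding or
re-running one stage never shifts another's draws; identical seed and
configuration give byte-identical outputs.

What the generator does *not* emulate: probe-level measurement error and
normalization artifacts, linkage disequilibrium and SNP-to-gene mapping
noise in GWAS lists, annotation-version drift in pathway databases, and
the literature bias of curated interaction networks. Passing recovery
tests therefore demonstrate the pipeline's statistical behaviour under
its own model assumptions, not robustness to those real-data features.

## Numerical choices and degenerate inputs

* Hypergeometric tails: log-space summation; $P(X \ge k) = 1$ exactly
  whenever $k$ is at or below the lower support bound; infeasible
  margins raise errors.
* Binary enrichment coding is strict at the threshold ($p = 0.05$ codes
  0).
* BH-selection of modules is strict at the threshold (BH $p = 0.05$ is
  not selected).
* Eigengene sign: positive mean member correlation, falling back to
  largest-magnitude-positive when that mean is zero (e.g. a two-gene
  module with opposite profiles).
* MDS of an all-zero dissimilarity matrix returns all points at the
  origin; non-symmetric input is an error.
* Ortholog mapping keeps *all* human targets of a one-to-many mapping
  and collapses many-to-one mappings; unmapped symbols are dropped with
  a count, not an error. Genes mapping to multiple orthologs count once
  per human symbol in overlap tests.
* Empty gene lists after filtering are an error; empty module selections
  and empty overlap results are warnings with empty outputs.

## Problem sizes used in the test-suite simulations

Recovery properties use the generator defaults above (225-gene
expression matrices, 12 samples; 10 seeds). Type-I calibration of the
module association runs 200 seeds of a no-shift configuration with a
reduced background (50 genes) — the family-wise rate of any BH-significant
module is compared against the nominal 0.05 plus a three-standard-error
Monte-Carlo margin. Exactness of the hypergeometric tail is checked
exhaustively for universes up to 30 and by dense random sampling up to
60 against an enumeration oracle, at $10^{-12}$ absolute tolerance.

## Known limitations

* The co-expression stage is a simplified stand-in: unsigned adjacency,
  no topological overlap, static cut. It is not intended to reproduce
  any particular published module decomposition.
* Enrichment profiles depend strongly on the pathway collection
  supplied; profile-level results (shared-pathway counts, MDS variance
  splits) are only comparable within one collection.
* The degree comparison inherits whatever ascertainment bias the input
  network carries; well-studied genes have inflated degrees.
* The bootstrap p-value for the median contrast is percentile-based and
  conservative at very small class sizes.
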