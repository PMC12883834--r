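---
title: "neuroselect: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{neuroselect: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures `neuroselect` implements,
the assumptions behind them, and the design decisions taken where the
method left genuine freedom. It states no empirical result beyond what the
package's own tests and `scripts/acceptance.R` compute.

## The problem

The package asks where, in a space of task-associated functional brain
networks, protein-coding genes under unusual selection pressure are
spatially co-expressed. Inputs are (a) per-network volumetric z-score maps
in MNI space, (b) a gene × biopsy-site expression matrix with site
coordinates, (c) a gene × phylogenetic-branch table of raw ω = dN/dS
estimates with per-cell status codes describing the outcome of the
maximum-likelihood estimation, and (d) a gene × cell-cluster mean
expression matrix with cluster metadata. The output is a set of biclusters
— gene sets jointly extreme in ω rank on one branch and strongly
correlated with a subset of networks — summarized over network domains and
cell types.

## Projection of network maps onto biopsy sites

Sampling density of expression atlases varies strongly across the brain,
so the projection is density-adaptive. For each site we compute the
squared Euclidean distance (mm²) to its nearest *other biopsy site*; at or
below the threshold (default 5 mm², inclusive) the site takes the z-value
of the voxel centre closest to it, otherwise a Gaussian-weighted mean of
surrounding voxels:

$$F(n,s) = \frac{\sum_v w_v z_v}{\sum_v w_v},\qquad
w_v = \exp\!\left(-\frac{(d_v-\mu)^2}{2\sigma^2}\right)$$

with $\mu = 0$, $\sigma = 20$ mm and $d_v$ the site-to-voxel-centre
distance in mm. Design choices the method description leaves open:

- **Gaussian neighbourhood.** We include all finite voxels within
  3σ (60 mm) of the site and normalize by the weight sum. Weights beyond
  3σ are below 1.2% of the peak, and normalization makes a constant volume
  an exact fixed point of the operator (a property the test suite checks).
- **σ applies to distance in mm**, not squared distance; the sparse-regime
  weighting is then a textbook isotropic Gaussian kernel.
- **Nearest voxel** means the voxel centre minimizing Euclidean distance;
  exact ties take the lowest column-major voxel index. Non-finite voxels
  are excluded from both rules; a dense-regime site whose nearest voxel is
  non-finite falls through to the Gaussian rule (logged), and a site with
  no finite voxel within support becomes missing.
- Squared site-to-site distances are accumulated directly (no
  square-root round trip) so the inclusive threshold comparison is exact
  at the boundary.

## Correlation, domains, overlap

Gene-to-network association is Spearman's rank correlation over biopsy
sites with pairwise-complete observations; entries with fewer than 3
complete pairs are set missing. Networks are clustered on their
gene-correlation profiles (rows of the network × gene matrix) with Ward's
minimum-variance method on squared Euclidean distances; the domain count k
maximizes the average silhouette width over a search range (default 2–12,
capped at #networks − 1), ties resolved toward smaller k. Missing
correlations are zero-imputed before clustering with a warning. Volumetric
overlap uses the Dice coefficient 2|A∩B|/(|A|+|B|) on thresholded masks
(threshold configurable, default z > 0, strict; two empty masks give 0
with a warning) and the Pearson correlation over voxels finite in both
maps.

## Preparing the selection and correlation matrices

**Status constraints.** Cells with a stable ω estimate are kept; unstable
cells (including short-edge instability) are always removed. The relaxed
mode additionally resolves dN = 0 to ω = 0 (purifying), dS = 0 to the
maximum retained ω of the branch (adaptive; if a branch has no stable cell
to anchor this, the cell is set missing with a warning), and identical
sequences to 0 (neutral); the conservative mode removes all three.

**Rank normalizations.** Per branch,
$\tilde\omega_{ij} = (1 + |\{k\ne i : \omega_{kj} < \omega_{ij}\}|)\,/\,
|\{k : \omega_{kj}\ \mathrm{present},\ \omega_{kj} > 0\}|$ with minimum
(competition) tie ranks. The denominator deliberately counts only strictly
positive entries, so when zeros are abundant the top values can slightly
exceed 1; we follow the formula literally and do not cap. Per gene,
$\tilde r_{ij} = (1 + |\{k\ne j : r_{ik} < r_{ij}\}|)/|n|$ with maximum
tie ranks, so every gene's best network maps to exactly 1; afterwards each
gene's minimum entries are set to 0 and genes with max |r| < 0.1 are
zeroed entirely. Missing correlations propagate as zeros at this stage.

**The 0.1 and 0.75 thresholds.** Both appear in the method: we use 0.1 on
raw correlations as the spatial-informativeness gene filter (absolute
values by default — a strong negative spatial correlation is informative)
and 0.75 as a retained-gene criterion applied by default to the
rank-normalized rows (`filterOn = "raw"` switches to raw correlations);
each is independently configurable.

**Gene pools and harmonization.** High pools are ω > 1, low pools
ω ≤ 1e−9 (exact zeros after constraint handling; the tolerance and cuts
are configurable). "Harmonizing pool sizes across branches" is realized as
deterministic truncation to the cross-branch minimum, keeping the most
extreme raw ω (largest for high, smallest for low; ties by gene label) —
reproducible with no resampling. An empty pool after harmonization is an
error naming the branch.

## The genetic-algorithm biclusterer

A bicluster is $B = (g_{sub}, [b_{sub}\ n_{sub}])$: a gene set qualifying
jointly on one branch's ω̃ window and a set of network columns at
r̃ ≥ 0.75 (all comparisons inclusive). The analysis matrix is binarized
against branch-specific thresholds anchored on the harmonized pools: the
high-direction window is [min ω̃ over the pool, ∞), the low-direction
window (−∞, max ω̃ over the pool]. Candidates are binary masks over the
network columns; the branch's ω column is forced into every candidate and
the gene set is the rows carrying 1 in every selected column
(exact-membership encoding). Fitness is the size score
|genes| × |columns|, optionally weighting ω and network columns 2:1
(`do_weighting`; the weights are package defaults, since only the
existence of differential weighting is specified).

GA mechanics are not part of the published method description, so the
package uses standard defaults, all configurable: tournament selection
(size 2), uniform crossover (rate 0.7), per-bit mutation (1/#columns), one
elite per subpopulation, `nsubpops` isolated subpopulations (no
migration) splitting `popsize` evenly (we read "popsize" as the total).
Initial candidates are sparse (expected two network columns switched on)
so early generations have nonempty gene sets to climb from. Equal-fitness
candidates are tie-broken by lexicographically smallest column mask, and
every random draw derives from the run's seed, so searches are fully
reproducible.

`amountOfBiclusterSearches` iterated searches each emit at most one best
candidate meeting `min_genes` (default 5) and `min_network_cols` (default
1); the emitted bicluster's qualifying cells are then tabu-masked to zero
before the next search, per the `variableClassNotOnTabuList` pair for
(ω, network) columns — TRUE means that column class is *exempt* from
masking. With the pair (TRUE, FALSE) no two sequentially emitted
biclusters can share a (gene, network) qualifying cell, by construction.
The `global_optim` outer loop cycles in fixed order through
{weighting on, off} × {tabu pair (T,T), (T,F)} — four combinations, hence
the advice to use a multiple of 4 — with a distinct child seed per
iteration, pooling all results with the combination recorded in each
bicluster's metadata.

Merging: biclusters are similar if their gene overlap exceeds 50% of the
smaller set or their network sets are identical; connected components of
the similarity graph are merged by union and the size score recomputed.
We iterate the merge to a fixed point so the operation is idempotent (a
single pass is not guaranteed to be, because unions can create new
overlaps). Each run mines one branch at a time, so $b_{sub}$ is a
singleton in practice; the type still carries a set.

## Post-processing and cell-type enrichment

Top-N selection (default top 20 per branch; top 40 overall also
supported) breaks score ties by larger gene count, then stable input
order. A bicluster whose networks span several domains belongs to all of
them. The branch × domain summary accumulates scores per cell and divides
by the global matrix maximum (per-branch normalization is an option; the
original figure's normalization is not specified, and a global scale keeps
cells comparable across branches), alongside unique-gene counts per cell.

For cell types, each cluster column of the gene × cluster matrix is
filtered to its top decile (linear-interpolation quantile; values strictly
below the 90th percentile are zeroed, boundary ties kept). Each branch ×
domain gene set is then correlated with every filtered cluster column via
the point-biserial correlation of the set-membership indicator over the
gene universe shared by the ω table and the cell matrix. How the gene sets
are "related using correlations" is not recoverable from the method
description; the membership-indicator correlation is the simplest
construction that yields one correlation per cluster to z-score, and the
z-scoring population is all clusters within one branch × domain cell
(matching per-branch normalization with domain stratification). A cluster
is enriched iff its z strictly exceeds 1.96; zero-variance cells yield no
enrichment, with a warning. Collapsing by supercluster, class or
neurotransmitter counts *presence* — the number of branch × domain cells
with at least one enriched cluster of the group — separately for neuronal
and non-neuronal clusters.

## The synthetic-data generator

`makeDataset()` emulates the input shapes at desk scale: 12 networks on a
24³ grid of 2 mm voxels in 3 planted domains (networks of one domain share
a Gaussian-blob base pattern plus a per-network perturbation), 300 sites
(10% dense pairs 1 mm apart to exercise the direct rule, the rest sparse),
800 genes × 6 branches, 50 cell clusters. Three planted modules of 40
genes each tie a branch (alternating high/low ω direction) to one domain's
networks: module expression is `effect` × z-scored network site profile +
Gaussian noise (`effect = 2`, `noise_sd = 0.5` by default, chosen as a
moderate signal-to-noise regime: Spearman correlations of roughly 0.7
between module genes and their networks), module ω is uniform in (2.5,
3.5) for high modules and exactly 0 for low ones. Every branch receives 45
filler high-ω genes in (1.1, 2.0) — strictly below the module range, so
cross-branch pool harmonization cannot truncate planted modules — and 45
dN = 0 genes, plus a scattering of the other status codes. One cell
cluster per module over-expresses the module genes above the filter
percentile. Everything is bit-reproducible from the seed.

What the generator does **not** emulate: realistic neuroanatomy, spatial
autocorrelation structure of real expression atlases, hemispheric
sampling asymmetries, or the marginal distributions of real ω tables.
Passing recovery tests therefore demonstrates the pipeline's correctness
and sensitivity under planted structure, not performance on real atlas
data.

## Problem sizes and numerical choices in the test suite

The GA's documented defaults (20 searches, popsize 250 for high-ω / 1200
for low-ω runs, 100 generations) reflect full-scale mining. The test and
acceptance suites run the same code at desk scale — typically 4 searches,
popsize 120, 60 generations on 300–800-gene fixtures — which recovers the
planted modules reliably while keeping the suite fast. Oracle-equivalence
tests compare the rank normalizations, pairwise-deleted Spearman and the
Gaussian projection against brute-force reimplementations of the printed
formulas; GA optimality is checked against exhaustive column-subset
enumeration on matrices with ≤ 12 columns.

Further numerical conventions: all threshold comparisons are inclusive;
z-scores use the sample standard deviation; silhouette ties prefer
smaller k; Dice of two empty masks is defined as 0; correlations of
constant vectors are missing with a warning rather than an error wherever
a constant can arise from filtering.

## Known limitations

- No spatial-autocorrelation-preserving null maps ("spin tests"); overlap
  and correlation statistics are descriptive.
- No volume resampling or registration: volumes and sites must already
  share the MNI frame, and all volumes of a run must share grid and
  affine.
- One ω column per run; multi-branch biclusters arise only through
  merging.
- GO-term enrichment of bicluster gene lists is out of scope; the
  summary's per-cell gene sets are exported for external tools.
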