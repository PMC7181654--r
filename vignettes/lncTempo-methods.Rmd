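---
title: "lncTempo: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncTempo: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncTempo)
```

# Overview

lncTempo analyses long noncoding RNA (lncRNA) genes across a neuronal
differentiation time course. It covers five analysis layers, each with a
documented mathematical definition and a synthetic-data generator that plants
known ground truth so every layer can be validated end to end:

1. **Positional biotype classification** of lncRNA genes relative to
   protein-coding partner genes (`classifyBiotypes()`).
2. **Expression preparation**: filtering, per-gene standardization
   (`filterExpressed()`, `standardizeTime()`).
3. **Soft temporal clustering** with fuzzy c-means and marker-driven stage
   labelling (`fcmCluster()`, `assignStages()`).
4. **Networks**: weighted co-expression modules via topological overlap
   (`coexpressionModules()`), and mutual-information networks with
   data-processing-inequality pruning (`inferNetwork()`, `applyDPI()`).
5. **Coding potential**: Fickett TESTCODE statistic plus ORF coverage
   (`codingPotentialReport()`).

`runPipeline()` chains all layers; `simulateBundle()` writes a complete
synthetic input bundle with a ground-truth manifest.

# Positional biotypes

Every lncRNA gene is classified against protein-coding genes on the same
chromosome by a deterministic rule table. The partner is the coding gene with
the largest base-pair overlap; if none overlaps, the nearest coding gene
within the genic window (gap of at most 5000 bp, boundary inclusive: a gap of
exactly 5000 bp is genic, 5001 bp is intergenic); ties are broken by
lexicographic gene id.

With respect to the partner, the classes are:

| class | strand  | geometry |
|-------|---------|----------|
| XI    | antisense | lncRNA contained inside the coding gene |
| XO    | antisense | lncRNA contains the coding gene |
| XH    | antisense | partial overlap of the two 5' ends (divergent, head-to-head), or non-overlapping with 5' ends facing each other |
| XT    | antisense | partial overlap of the two 3' ends (convergent, tail-to-tail), or non-overlapping with 3' ends facing each other |
| SD    | sense   | non-overlapping, lncRNA downstream of the coding gene |
| SU    | sense   | non-overlapping, lncRNA upstream of the coding gene |
| IG    | —       | nearest coding gene farther than 5000 bp |

Two boundary cases do not fit the seven classes and are labelled rather than
forced: same-strand *overlapping* pairs become
`unclassified_sense_overlap`, and antisense partial overlaps where one 5' end
and one 3' end meet become `ambiguous_ends`. Containment (XI/XO) is tested
before partial overlap, so a fully nested antisense gene is never XH/XT.

The extension of XH/XT to *non-overlapping* antisense pairs inside the
genic window (classified by whether the 5' or 3' ends face each other) is a
deliberate completion of the rule table: without it, such pairs — which are
neither intergenic (gap ≤ 5 kb) nor overlapping — would have no class.

Classification is O(lnc × coding) per chromosome with interval arithmetic on
`GRanges`; annotation is read with `rtracklayer` and collapsed to one range
per gene.

# Expression preparation

`filterExpressed()` keeps genes with RPKM at or above a threshold (default 1)
in at least `minTimepoints` (default 1) timepoints. `standardizeTime()`
applies `log2(x + 1)` and then z-scores each gene across timepoints using the
**population** standard deviation (dividing by *n*, not *n − 1*); with only
8 timepoints the difference is material and the population form matches the
definition of the cluster distance geometry. Constant rows get all-zero
z-scores with a warning instead of NaN, so downstream clustering never sees
non-finite input.

# Fuzzy c-means and stage assignment

`fcmCluster()` implements the textbook alternating updates with Euclidean
distance:

$$\mu_{ij} = \frac{1}{\sum_k (d_{ij}/d_{ik})^{2/(m-1)}}, \qquad
  c_j = \frac{\sum_i \mu_{ij}^m x_i}{\sum_i \mu_{ij}^m},$$

iterated until the largest absolute centroid change drops below `tol`
(default `1e-6`). The fuzzifier default is `m = 1.25` and the downstream
membership threshold (`min.acore`) is 0.5 — values in common use for
time-course transcriptomes. As `m → 1⁺` memberships become hard indicators
and the algorithm reduces to k-means, a limit exercised in the test suite.

The number of clusters `c` is not estimated from the data; it is a design
choice. The bundled pipeline uses `c = 5`, one centroid per planted profile
family — three temporal stages, the flat expressed background, and the graded
coding-partner profiles — so the flat background is not absorbed into a stage
cluster and no planted cluster is split by a surplus centroid.

Initialization is k-means++ under a fixed seed. A single k-means++ draw
occasionally seeds two centroids inside one planted cluster; `fcmCluster()`
therefore draws `nInit = 10` candidate seedings and keeps the one with the
lowest one-step FCM objective. The selection criterion is the algorithm's own
objective, the procedure is deterministic given `seed`, and an explicit
`init` matrix bypasses it.

`assignStages()` labels each cluster by the marker-gene panel (pluripotency:
POU5F1, NANOG, NODAL, TDGF1; commitment: PAX6, SOX1; later development:
EMX2, TBR1, BCL11B, CACNA1E, PRSS12, CARTPT) with the highest mean
membership, requiring it to reach `min.acore`; ties leave the cluster
unassigned. Legacy symbols (OCT4/POU5F, TDGF, CTIP2) are translated via
`markerAliases()`.

# Weighted co-expression modules

Given a samples × genes matrix, `coexpressionModules()` computes the Pearson
correlation, the unsigned soft-threshold adjacency $a_{ij} = |r_{ij}|^\beta$,
and the topological overlap matrix

$$\mathrm{TOM}_{ij} = \frac{\sum_u a_{iu} a_{uj} + a_{ij}}
  {\min(k_i, k_j) + 1 - a_{ij}}, \qquad k_i = \sum_{u \ne i} a_{iu},$$

implemented with a single matrix product (the O(n³) elementwise definition is
kept as a test oracle, agreement to `1e-12`). Modules are average-linkage
hierarchical clusters of `1 − TOM` under a **static** cut at height 0.99;
clusters smaller than `minModuleSize = 10` are relabelled 0 (unassigned).
Labels are assigned by decreasing module size with ties broken by the
lexicographically smallest member, so the labelling is order-invariant.
Merge heights are rounded to 12 decimals and made monotone with `cummax()`
before `cutree()` — average linkage can produce heights that decrease by
~1e-16 from floating-point jitter, which `cutree()` rejects.

$\beta$ defaults to automatic selection: the smallest power whose binned
degree distribution fits $\log_{10} p(k) \sim \log_{10} k$ with
$R^2 \ge 0.8$ and a negative slope.

# Mutual-information networks

`mutualInformation()` discretizes both vectors into `B` equal-frequency bins
(ranks with `ties.method = "first"`, so the binning is deterministic) and
returns the plug-in estimate
$\sum_{ab} p(a,b) \log_2 \frac{p(a,b)}{p(a)p(b)}$ in bits. With
`bins = "auto"`, `B = floor(sqrt(n))`. When `B` divides `n`,
`MI(x, x) = log2(B)` exactly, since the binned marginal is uniform by
construction.

**Bias.** The plug-in estimator is biased upward by approximately
$(B-1)^2 / (2 n \ln 2)$ bits under independence (the Miller–Madow term). At
`n = 1000` this is ~0.16 bits for the auto choice `B = 31`, but ~0.012 bits
for `B = 5` — which is why the documented "independent Gaussians score below
0.05 bits" example uses `bins = 5`. `inferNetwork()` does not need any bias
correction because its significance threshold is the $(1-\alpha)$ quantile of
a pooled permutation null computed with the *same* binned estimator: the bias
is present identically in the null and the observed values and cancels out of
the thresholding decision.

**DPI.** `applyDPI()` prunes indirect edges: per triangle, the strictly
weakest edge is marked when its MI is below `(1 − tolerance)` (default
tolerance 0.15) times the second-weakest; all marks are collected against the
unpruned network and removed together (one-pass). Two protections hold:
a tie between the two weakest edges removes nothing, and an edge that is the
(weak) maximum of *any* triangle is never removed — the classic mark set
alone does not guarantee the latter, because an edge can be weakest in one
triangle yet maximal in another.

Hubs are ranked by degree (ties: summed MI, then gene id). The network-change
statistic is the number of genes of a biotype set with degree ≥ 2
(`multiedgePartnerCount()`, `networkDelta()`).

# Coding potential

`fickettScore()` implements the TESTCODE statistic: position asymmetry
$\max_i n_b(i) / (\min_i n_b(i) + 1)$ over the three codon positions and
content fraction per base, each converted to a probability by the published
lookup tables and combined with the published weights. Scores range ~0.26 to
~1.30; the conventional decision cutoff is 0.74. Sequences shorter than
200 nt are not scored (the tables are unreliable there); N bases are
stripped, and more than 10% non-ACGTN is an error.

`orfCoverage()` scans the three forward frames for the longest ATG-to-stop
open reading frame (inclusive of the stop) and reports its length fraction,
with flags for open-ended ORFs. `classifyTranscript()` calls a transcript
coding only when both the Fickett score (≥ 0.74) and ORF coverage (≥ 0.5)
agree, noncoding when both are below, and indeterminate otherwise.

# The synthetic generators, realism, and limits

`simulateAnnotation()` lays out lncRNA/coding pairs left-to-right with 10-kb
spacers from exact `geometrySpec()` geometries, so the planted biotype is
unambiguous. `simulateExpression()` draws log-normal noise around planted
temporal profiles over a flat background. `simulateNetworkSamples()` plants
hub (star), chain (3-gene Markov chain, one degree-2 node per unit) and
independent structures with controllable correlation. `simulateSequences()`
plants ORFs built from a biased codon table inside otherwise random
sequence, and makes noncoding controls by composition-preserving shuffles
that destroy codon-position structure while keeping base content.

Realism limits, deliberately accepted: one transcript per gene (no
isoforms), no batch or library-size effects, Gaussian log-scale noise with a
free `noiseSd`, problem sizes (numbers of pairs, samples, genes per module)
chosen as package defaults rather than estimated from any dataset. The
generators exist to provide *checkable* truth, not to imitate a specific
experiment.

# Degenerate-input policy

Errors for structurally unusable input (duplicate gene ids, negative RPKM,
non-numeric expression, < 8 MI samples, < 2 bins, asymmetric
correlation/adjacency, short sequences in `fickettScore()`); warnings plus a
defined value for statistically degenerate but representable input (constant
vectors → MI 0, constant z-rows → zeros, empty post-filter matrix, < 30 MI
samples); silent deterministic tie-breaking wherever an arbitrary choice
would otherwise be hidden (partner selection, module labels, hub ranking,
DPI scan order).

# Reproducibility

All stochastic steps take explicit seeds and restore the caller's RNG state
(`withSeed()`). `runPipeline()` writes a `report.json` with no timestamps and
an md5 of the resolved configuration, so a rerun with the same config and
seed is byte-identical.
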