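---
title: "Methods: marker set enrichment and key driver analysis for multi-omics integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker set enrichment and key driver analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`msekda` implements an integrative-genomics workflow for diseases with both
genetic and epigenetic risk components, of which psoriasis is the motivating
example. The workflow aggregates the *full* spectrum of GWAS and EWAS
summary statistics — not just genome-wide-significant hits — at the level of
gene sets (curated pathways or data-driven coexpression modules), finds the
processes on which genetic and epigenetic evidence converges, and then uses
tissue-specific gene networks to nominate the hub genes ("key drivers")
whose network neighborhoods concentrate those disease processes. Validation
closes the loop on independent case/control expression data.

The stages, each an exported function family:

1. **Marker-to-gene mapping** (`map_by_distance()`, `map_cpg()`,
   `map_by_table()`, `combine_maps()`) with LD correction (`ld_prune()`).
2. **Marker set enrichment analysis, MSEA** (`msea()`, `meta_msea()`,
   `select_significant()`).
3. **Superset construction** (`merge_gene_sets()`,
   `superset_uniqueness()`, `revalidate_supersets()`).
4. **Weighted key driver analysis, wKDA** (`wkda()`, `shared_kds()`,
   `extract_subnetwork()`).
5. **Module preservation** between condition-specific coexpression networks
   (`rbh_preservation()`, `annotate_modules()`).
6. **Expression validation** (`de_genes()`, `rank_genes()`, `gsea_es()`,
   `gsea_significance()`).
7. **Orchestration** (`run_pipeline()`), plus a synthetic-data generator
   (`sim_config()`, `simulate_study()`) that plants known ground truth.

Everything operates on plain-text interchange formats: two-column
association TSVs, BED-like annotations, GMT gene sets, three-column LD and
edge-list TSVs, genes-by-samples expression TSVs.

# Marker-to-gene mapping and LD pruning

SNPs map to genes by chromosomal distance (default ±50 kb around the gene
body), by tissue eQTL evidence tables (skin, blood, or their union), by
precomputed functional-evidence tables, or by the union of all schemes;
CpGs map by a ±5 kb window. Coordinates are 0-based half-open (BED
convention) throughout, windows extend the gene interval symmetrically, and
strand is ignored — the window is symmetric, so strand carries no
information for this purpose. Every mapping row records its scheme, and
`combine_maps()` preserves the contributing schemes in a provenance column.

Correlated SNPs carry redundant association signal, so before enrichment
testing the association table is pruned: marker pairs with r² > 0.7 define
a graph, and exactly one representative per connected component survives.
Components, not cliques, are used because "in LD with" is transitive in
intent and components are deterministic. The representative is the member
with the **smallest p-value** (ties: lexicographic id): the enrichment test
asks whether a set's signal is coordinately strong, so the pruning step
should preserve, not dilute, each locus's best evidence. Whether to prune
before or after mapping is ambiguous in general; here markers are
study-level objects and pruning happens on the association table before
set-level extraction, which also keeps the permutation null consistent.

# MSEA: the chi-squared-like enrichment statistic

For a gene set, member genes are mapped to markers and the markers'
association p-values extracted (a marker mapped to several member genes is
counted **once per set**, so a single locus cannot be double-counted). With
a grid of probabilities $q_j$ (default $\{5\mathrm{e}{-4}, \dots, 0.5\}$,
ten points concentrated in the tail), let $c_j$ be the $q_j$-quantile of
the background p-values (all mapped markers), $O_j$ the number of set
p-values $\le c_j$, and $E_j = n_{\text{set}} q_j$. The statistic is

$$S = \sum_j \frac{O_j - E_j}{\sqrt{E_j + \kappa}}, \qquad \kappa = 1 .$$

$S$ accumulates standardized excesses of small p-values across the whole
tail, which is what gives the method power for polygenic signal spread over
many sub-threshold loci; $\kappa$ damps the variance of the extreme-tail
terms where $E_j \ll 1$.

Significance is empirical: each permutation replaces the set's genes by a
uniformly random set of the **same mapped-gene count** drawn from the
mapped-gene universe, and

$$p = \frac{1 + \#\{S^* \ge S_{\text{obs}}\}}{N + 1}$$

with $N$ = 1999 by default. Because this null law depends only on the
mapped-gene count, sets of equal count share one cache of $N$ draws — a
pure speed optimization that leaves the null distribution unchanged.
Benjamini–Hochberg FDR is computed over all retained sets within a study;
sets with fewer than 10 or more than 500 mapped genes are skipped and
reported (very large sets are uninformative and dominate by size alone).
Null-set size matching is by gene count, not marker count; an analyst
worried about residual marker-count confounding should inspect the
`n_markers` column, which the results carry for exactly that reason.

**Meta-analysis.** Sets tested in ≥ 2 studies are combined by unweighted
Stouffer: $z_i = \Phi^{-1}(1 - p_i)$, $z = \sum z_i / \sqrt{k}$,
$p = 1 - \Phi(z)$. Study p-values are clamped to $[10^{-12}, 1-10^{-12}]$
so a degenerate empirical p of exactly 1 contributes a large finite
negative $z$ rather than destroying the combination. Sample-size weighting
is deliberately not the default: MSEA empirical p-values already reflect
each study's resolution, and the studies combined here (e.g. three small
EWAS) are of comparable size. Selection uses the disjunctive rule:
significant in ≥ `min_studies` individual studies *or* in the meta row;
the GWAS arm (a single study) uses `min_studies = 1`.

**The permutation floor and BH.** The add-one estimator floors p at
$1/(N+1)$; with $N = 1999$ that is $5\times10^{-4}$. A lone true positive
among $m$ tested sets can therefore reach BH FDR < 0.05 only if
$5\times10^{-4}\, m < 0.05$, i.e. $m < 100$. This arithmetic is worth
internalizing when sizing a permutation budget to a collection: the
package's power experiments use 80-set collections at $N = 1999$.

# Supersets

Significant sets from different sources overlap heavily. Two sets merge
when their geometric-mean overlap ratio
$r = \sqrt{r_{AB}\, r_{BA}} \ge 0.2$ **and** their Fisher overlap test
passes BH FDR < 0.05 (family: all within-list pairs — the gate is applied
to every pair test, and restricting the family to pre-passing pairs would
bias the correction). Supersets are the connected components of this
graph: the description of the merging rule is pairwise-threshold based,
and transitive closure is its deterministic completion, whereas iterative
agglomeration with recomputed ratios would depend on merge order. A
superset exceeding 500 genes is trimmed to the core genes shared by ≥ 2
member sets (fallback: rank by membership multiplicity, truncate, ties
lexicographic) — "core" has no canonical formula, and multiplicity ≥ 2 is
its minimal faithful reading. Supersets are re-tested by MSEA/meta-MSEA
after merging, optionally excluding a gene list (e.g. HLA genes, whose
tight physical clustering and co-regulation can carry a whole superset).
A superset is *unique* to its evidence stream when no cross-list Fisher
test reaches FDR < 0.05.

# wKDA: weighted key driver analysis

Given an edge-weighted gene network (e.g. a tissue-specific functional
network, treated as undirected because posterior functional edges are not
causal arrows; a directed mode exists) and a disease gene set, every node
with a neighborhood of ≥ 10 genes is a candidate. With $O_w$ the summed
neighborhood edge weights of disease genes, $W$ the node's total
neighborhood weight, and $\rho$ the disease-set fraction of network nodes,

$$T = \frac{O_w - \rho W}{\sqrt{\rho W + \kappa}}, \qquad \kappa = 1 ,$$

mirroring the MSEA statistic. The default neighborhood is depth 1 (the
"first level"); for deeper neighborhoods a gene contributes the maximum
product of edge weights along any admissible path, the natural
monotone-decreasing aggregation when weights are confidences in (0, 1].
The null permutes disease-set labels over nodes (size-preserving);
label permutation does not control for degree, so the package reports each
candidate's neighborhood size and hit count alongside the statistic, and
the hub-free calibration experiment (below) checks that the node-level
type-I error stays nominal on degree-homogeneous graphs. Candidates are
not restricted to non-members of the disease set; membership is recorded
in the output instead. Key drivers shared by ≥ 2 (superset, network)
combinations are summarized by `shared_kds()`; `extract_subnetwork()`
exports a key driver's first-level subnetwork with superset-membership and
marker-significance annotations.

# Module preservation and annotation

Coexpression module assignments from a disease and a normal network are
compared by reciprocal best hits: all cross-network pairs are scored with
the one-sided hypergeometric overlap test, BH-corrected over all pairs,
and a module is *preserved* exactly when its best hit (smallest p, ties by
larger overlap then lexicographic id) points back at it and that pair
passes FDR < 0.05; everything else is *differential*. Overlapping
multiscale modules are not de-duplicated. Module–pathway annotation uses
the same overlap test, BH-corrected per module across pathways. The gene
universe for every Fisher test is passed explicitly (in practice, the
genes measured in both datasets); results are sensitive to it, so no
silent default is offered.

# Expression validation

Differential expression uses a per-gene Welch t-test with BH FDR — a
deliberately simple, assumption-light stand-in appropriate for the
package's synthetic fixtures and continuous expression summaries (count
modeling and moderated statistics are out of scope). Gene ranking for
GSEA uses signal-to-noise $(\bar x_2 - \bar x_1)/(s_1 + s_2)$, the
standard two-class metric; zero-variance genes are excluded with a logged
count. The enrichment score is the classic weighted Kolmogorov–Smirnov
running sum (hit increments $|r|^w$ normalized by the set total, default
$w = 1$; miss decrements $1/(N - n_{\text{set}})$), signed by the
maximum-magnitude deviation; an exact tie between the positive and
negative extremes resolves to the positive side, a necessary convention
because at $w = 0$ the increments are rational and opposite extremes of
equal magnitude occur. Significance permutes **phenotype labels** (the
correct exchangeability unit at these sample sizes; gene permutation
ignores inter-gene correlation), with the one-sided p computed within the
same-sign permutation mass — normalizing by all permutations would be
anticonservative by roughly a factor of two under a symmetric null. NES
divides the ES by the mean magnitude of same-sign permuted ES; FDR is BH
over set-level p-values (recorded in the output metadata, as this differs
from the bespoke FDR of the original GSEA tool).

# The synthetic-data generator

`simulate_study()` emulates the statistical structure the real analyses
rely on, with every planted entity recorded in `$truth`:

- **Annotation**: genes at regular 150 kb spacing (beyond twice the 50 kb
  window, so distance mapping is unambiguous) on 5 chromosomes, 5 markers
  per gene body.
- **Association studies**: background markers draw p ~ Uniform(0,1); a
  `signal_fraction` (default 0.5) of markers mapped to planted-set genes
  draw p ~ Beta(a, 1) with `signal_strength` a = 0.2 — the simplest
  one-parameter left-skewed family whose a = 1 limit is exactly the null.
  Three EWAS replicates share the truth but use independent RNG streams.
- **LD**: disjoint blocks of 5 consecutive markers at constant r² = 0.9;
  enough to exercise the pruning contract (realistic decay is a non-goal).
- **Network**: 500 nodes, Erdős–Rényi background of mean degree 6, plus 5
  planted hubs, each with 30 neighbors of which 80% are drawn from that
  hub's designated planted pathway (hubs cycle through the planted sets —
  a regulator drives one process, and this is what makes per-superset
  wKDA recovery well-posed). Background edges avoid the hubs so a fully
  enriched hub neighborhood is exactly its planted draw.
- **Expression**: 50 samples per group; unit-variance Gaussian noise;
  module genes load 0.7 on a shared per-module latent factor (marginal
  variance kept at 1); the hubs and their disease-gene neighbors are
  shifted up by 2 SD in cases, so key-driver subnetworks genuinely
  up-regulate.
- **Determinism**: every artifact derives its RNG stream from
  `seed` plus a fixed per-artifact offset, so each artifact is
  individually reproducible and identical configs give byte-identical
  files.

What the generator does **not** emulate — realistic LD decay, genotype
sampling, methylation beta-value distributions, batch effects, scale-free
degree distributions, correlated gene sets from a shared ontology — bounds
what the passing tests show: they demonstrate correctness and calibration
of the statistical machinery under its stated null and a faithful planted
alternative, not performance on real cohorts.

# Numerical and design notes

- Empirical p-values use the add-one estimator everywhere; p = 0 is
  impossible by construction.
- The hypergeometric overlap test is the upper tail of `phyper` (the
  one-sided Fisher exact test); `fisher.test` serves as an independent
  cross-check in the test suite, never as the implementation.
- All best-hit and representative selections carry deterministic
  tie-breaks (stated in each function's documentation), so results are
  order- and platform-stable.
- `run_pipeline()` keys stage resumption on MD5 checksums of stage
  outputs, not timestamps; a config change invalidates everything, and a
  deleted output re-runs its stage and all stages after it.
- Problem sizes in the shipped experiments (500-set calibrations, 25–50
  seed recovery loops, 1999-permutation nulls, a 1000-gene/500-node
  end-to-end study) were chosen as the smallest at which the calibration
  bands (±0.02 around 0.05) are statistically meaningful.

# Known limitations

Directionality of association (risk vs protective) is not modeled — only
p-values are consumed. The size-matched permutation null does not
stratify by per-gene marker count. Label-permutation wKDA does not
control degree bias on strongly heterogeneous real networks (a
degree-preserving rewiring null is a natural extension). The validation
DE test is not a substitute for count-based RNA-seq modeling on real
data.
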