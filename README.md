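# netage

Network analysis of hippocampal gene expression across brain aging and
Alzheimer's disease (AD).

Transcriptome studies of the aging and AD hippocampus typically compare
two groups at a time. `netage` treats young (20–50 y), aged (70–99 y)
and AD (70–99 y) samples as a progression and asks two network-level
questions:

* which groups of co-regulated genes (modules) track the young → aging
  → AD transition, which cell types do they represent, and do they
  replicate in independent datasets; and
* which individual protein–protein interactions change their importance
  for network communication between conditions.

It is written for computational biologists analysing normalized
expression matrices (microarray or otherwise) with grouped sample
metadata, plus optionally a protein-interaction edge list and cell-type
marker gene sets.

## What it computes

**Signed weighted co-expression modules.** Gene–gene similarity
S<sub>ij</sub> = (1 + cor(x<sub>i</sub>, x<sub>j</sub>))/2 is
soft-thresholded, A = S<sup>β</sup>, with β chosen by the scale-free
topology criterion; the topological overlap matrix

TOM<sub>ij</sub> = (Σ<sub>u</sub> a<sub>iu</sub>a<sub>uj</sub> + a<sub>ij</sub>) / (min(k<sub>i</sub>, k<sub>j</sub>) + 1 − a<sub>ij</sub>)

defines the clustering distance 1 − TOM; modules come from a
deterministic coherence-gated decomposition of the average-linkage
dendrogram. Each module is summarized by its SVD eigengene, correlated
with age, ordinal stage (young 0, aging 1, AD 2) and an AD indicator;
intramodular connectivity (kIM) ranks hub genes; Fisher exact tests
score cell-type marker enrichment; and permutation
Z<sub>summary</sub> = (Z<sub>density</sub> + Z<sub>connectivity</sub>)/2
quantifies module preservation in an independent dataset (< 2 none,
2–10 weak/moderate, > 10 strong).

**Differential interaction connectivity.** Expression is overlaid on a
PPI network as node weights N<sub>i</sub>; each edge gets weight
W<sub>ij</sub> = 1/(N<sub>i</sub>N<sub>j</sub>), treated as a distance,
so weighted edge betweenness concentrates on highly expressed
communication corridors. Per-sample networks give each edge a score
distribution per group; Welch t-tests (on log-stabilized scores) with
Benjamini–Hochberg correction plus an absolute difference threshold
flag differentially connected edges, which form up-/downregulated
subnetworks with degree-ranked hubs.

**Moderated differential expression** (empirical-Bayes variance
shrinkage, fold change ≥ 1.5 and BH p < 0.05 by default) links DEGs to
modules.

**Synthetic benchmarks.** `synthetic_spec()` plants correlated modules
with stage-monotone eigengenes, marker lists and a scale-free PPI with
condition-specific perturbations, emulating the three-group study
design (17/21/18 samples), so every stage can be scored against known
truth.

## Worked example

```r
library(netage)

spec <- synthetic_spec(seed = 42)     # 2,000 genes, 56 samples, 4 planted modules
ds   <- generate_expression(spec)
net  <- build_network(ds)             # similarity -> power -> adjacency -> TOM
mods <- cluster_modules(net$tom, power = net$power)
me   <- module_eigengenes(ds, mods)
module_trait_correlation(me, encode_traits(ds)) |>
  dplyr::filter(trait == "stage")
```

```
<expression_dataset> 2000 genes x 56 samples
groups: ad=18, aging=21, young=17
<coexpression_network> 2000 genes, power = 20 (knee fallback)
<module_set> 4 module(s) over 2000 genes (1100 unassigned)
# A tibble: 4 x 6
  module trait estimate statistic       p.value     n
1 M1     stage    0.697      7.14 0.00000000242    56
2 M2     stage    0.537      4.68 0.0000197        56
3 M3     stage   -0.527     -4.55 0.0000305        56
4 M4     stage   -0.509     -4.34 0.0000621        56
```

The four planted modules are recovered exactly (adjusted Rand index 1.0
against the generator's labels; the 1,100 background genes stay
unassigned), and the two up-shifted modules correlate positively — the
two down-shifted ones negatively — with disease stage, each with small
two-sided p-values at n = 56.

The same surface runs on real data: `read_expression()` +
`collapse_probes()` + `iqr_filter()` + `stratify()` produce the
`expression_dataset`, `read_ppi()` the network, `read_gmt()` the marker
sets; `run_pipeline(run_config(...))` orchestrates everything and
writes TSV/GraphML outputs plus a reproducible run manifest.
`inst/scripts/netage.R` wraps the pipeline for shell use.

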