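---
title: "Methods: network dissection of a small-cohort transcriptional response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network dissection of a small-cohort transcriptional response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altnet)
```

## The problem

altnet targets expression studies with a handful of individuals sampled
under two conditions ("low" and "high"), where between-individual
baselines are large, per-condition replicates are few, and one individual
may even lack a replicate. Classical per-gene tests have almost no power
here. The package instead follows a network strategy: a rank-based
within-individual statistic calls differentially expressed genes (DEGs),
a weighted functional network connects them, Markov clustering dissects
the network into modules, regulator maps and minimum-cost flow trace how
upstream regulators reach the concordantly responding genes, and bounded
cycle search finds feedback loops.

## Differential expression by rank products

For every individual, every (high sample, low sample) pair contributes a
log2 fold-change vector; pairing within individuals cancels the
individual's baseline. The default design — three individuals with 2 + 2
samples and one with 1 + 2 — yields 14 comparisons. Genes are ranked
within each comparison (rank 1 = most changed in the tested direction)
and the rank product of a gene is the geometric mean of its ranks.

Significance comes from a pooled gene-permutation null with a +1
pseudo-count. `permutation_pvalues()` supports two permutation schemes:

* **`"comparison"`** — every comparison's rank vector is permuted
  independently. This is the classic rank-product null and is exact when
  comparisons share no samples. It is also available in an exhaustive
  mode that enumerates every tuple of permutations on tiny inputs, which
  the unit tests compare against direct enumeration.
* **`"individual"`** — one gene-label permutation per individual's whole
  block of comparisons (the default for `call_degs()` and
  `call_concordant()`).

The distinction matters because the all-pairs comparison design reuses
samples: two comparisons sharing a low sample have fold-change
correlation $1/(1+s^2)$, where $s$ is the ratio of high- to low-condition
noise — above 0.9 at the default settings. Treating those rank vectors as
independent (the `"comparison"` scheme) overstates the evidence and, on
null data, calls 2–3% of genes at BH FDR 0.1. Under the null hypothesis
genes are exchangeable *within an individual*, so permuting gene labels
once per individual block preserves the within-block rank correlation
exactly and gives an exactly calibrated null for any comparison design;
it reduces to the classic scheme when every block is a single comparison.
On null synthetic studies the block scheme calls essentially no genes
(mean fraction about $10^{-4}$ across 20 seeds) while still recovering
100% of planted effects at the default effect size.

Direction is chosen per gene by the smaller of the up/down P-values,
Benjamini–Hochberg adjustment is applied within each direction, and DEGs
are genes at FDR $\le 0.1$. Node weights are the signed $-\log_{10} P$,
rescaled so the largest magnitude is 1 — a monotone rescaling that leaves
all rank-based downstream steps unchanged.

**Concordant (sink) genes.** A gene is concordant when its per-individual
rank-product P-value is at most $\alpha = 0.05$, with the same preferred
direction, in every individual. With the block null, a single
individual's permutation distribution is the observed rank-product
multiset itself, so the per-individual P-value is a rank quantile and
"P $\le \alpha$" reads "in the top $\alpha$ fraction of that
individual's ranking". This is exactly calibrated, and it implies at most
$\alpha n$ genes per direction can ever be concordant — appropriate
whenever the true response involves less than an $\alpha$ fraction of
the genome, as in the motivating design (about 3% per direction).

## The responsive network (ARN)

Candidate edges are interactome interactions whose endpoints are both
DEGs. Each is weighted
$W_{ij} = c_{ij}\,|r_{ij}|\,(|w_i|+|w_j|)/2$ — annotation confidence
times absolute expression correlation times mean endpoint significance —
and kept only if it beats an empirical null of $B$ randomly drawn
interactome edges at $P \le 0.1$. Nodes incident to no surviving edge
drop out. The network splits into up- and down-regulated subnetworks
(cross-direction edges belong to neither) before module dissection.

## Modules: MCL plus degree-one pruning

`mcl()` implements canonical Markov clustering: self-loops set to each
node's maximum incident weight, column normalization, then repeated
expansion (matrix squaring), inflation (entry-wise power, default 1.5)
and pruning of entries below $10^{-5}$ until convergence. Clusters are
read off the attractor structure deterministically. Each cluster is then
iteratively stripped of degree-one nodes (leaving its 2-core) and
modules below 3 nodes are discarded. On planted interactomes with
within-module edge probability 0.8 against background 0.02 the planted
partition is recovered with adjusted Rand index 1.0.

## Regulators, flow and loops

Transcription factors are scored by **prestige centrality**: the sum of
confidence-weighted DEG-target weights, $\sum_t c_{TF,t} |w_t|$ — a TF
matters for what it points at, not for its own expression change. An
optional damped fixed-point variant also lets regulators inherit prestige
from regulators they feed. The top 10% (by `ceiling`, with deterministic
tie-breaks) become hub TFs; 335 regulators yield exactly 34 hubs. Hub-TF
and DE-miRNA target edges are layered onto the ARN as directed edges (the
functional-edge weight formula with the correlation factor at 1), giving
the full regulatory network (FRN).

**Minimum-cost flow.** A super-source feeds every DE miRNA and every
concordant sink gene feeds a super-sink (cost 0, capacity 1); undirected
functional edges become antiparallel unit arcs and every network arc
costs $-\log(W/W_{\max})$, floored at $10^{-6}$. The requested flow
defaults to the number of sinks with automatic fallback to the maximum
feasible value. The solver uses successive shortest augmenting paths
(Bellman–Ford on the residual network with a fixed arc order, hence
deterministic) and is validated against brute-force enumeration of
edge-disjoint path combinations on all random problems with up to 10
nodes and flow up to 3. Nodes are ranked by throughput (in-flow) with
competition ranking; on synthetic data the planted miRNA→TF→gene
cascade's TF reaches the top 3 in 95% of seeded runs, because several
miRNA source units converge on it before fanning out to its sink
targets.

**Feedback loops** are all simple directed cycles of 2–5 nodes over the
regulatory edges (functional edges can optionally participate as
bidirectional steps), found by a depth-bounded search that visits only
nodes ordered after the start node, so each cycle appears exactly once in
canonical rotation. The enumeration is checked against an independent
igraph-based oracle on random digraphs.

## Enrichment and auxiliary statistics

Gene-set enrichment is a one-sided hypergeometric test against a GMT
collection restricted to the measured universe, BH-adjusted (flagged at
FDR 0.05). `geneset_shift_test()` compares a set's per-gene group means
between two replicate groups with a paired t-test across genes.
`hclust_samples()` clusters samples by average linkage on
$1 -$ Pearson correlation. `delta_delta_ct()` implements the
$2^{-\Delta\Delta C_T}$ fold change used for qPCR validation.

## The synthetic model

Every generator is a pure function of one master seed (fixed offsets
derive independent sub-streams, and the caller's RNG state is never
disturbed). An expression value is

$$x_{gis} = b_g + o_{gi} + \varepsilon_{gis} \; (\pm\,\text{effect in high columns for planted genes}),$$

with per-gene baselines $b_g \sim N(8, 2^2)$, per-gene-by-individual
offsets $o_{gi} \sim N(0, 1)$ present in *all* of an individual's
columns (so they cancel in within-individual fold changes), and residual
noise $\varepsilon \sim N(0, 0.5^2)$, shrunk by the factor 0.3 in
high-condition columns to emulate the more uniform high-condition
profiles. Planted truth comprises 60 up- and 40 down-regulated genes
(effect 2 log2 units), five 20-gene interactome modules that never mix
directions, 8 DE miRNAs, and a miRNA→TF→gene cascade whose TF draws its
remaining targets mostly from planted DE genes — which is what makes it
a genuine hub. Decoy regulator edges scale with `decoy_density`.

Limitations worth knowing: the generator is Gaussian on the log2 scale
(no count-level noise model), the interactome is Erdős–Rényi outside the
planted modules, and regulator confidences are uniform draws — it is a
test harness for the algorithms, not a biological simulator.

## Numerical and reproducibility choices

* Permutation and empirical P-values use the $(1+\#\{\text{null} \ge
  \text{obs}\})/(1+B)$ convention, so no P-value is ever 0.
* Rank-product comparisons happen on the log scale with a $10^{-9}$ tie
  tolerance; empirical edge thresholds use a $10^{-12}$ tolerance.
* `B = 1000` is the default for all permutation nulls. The 20-run
  cascade-recovery experiment in the acceptance material uses `B = 200`
  per run purely for runtime; the cascade ranking is insensitive to this
  because it depends on the called DEG sets, which are unambiguous at the
  default effect size.
* Module-recovery checks restrict the interactome to the planted module
  genes with uniform node weights, isolating the clustering question
  from the differential-expression question.
* The sample-clustering test uses a configuration sized a priori so the
  condition signal dominates the individual offsets
  (`indiv_sd = 0.2`, no high-condition noise shrink, 20% planted genes);
  at the default settings individual identity legitimately competes with
  condition.
* Every pipeline run logs its seed, sub-seeds, `B` and all thresholds
  (`run_log.json`), and rerunning a configuration reproduces all outputs
  bit-identically.

## End-to-end example

```r
cfg <- synthetic_config(seed = 7)
ds <- simulate_dataset(cfg)
res <- analyze_dataset(ds, seed = 7)
res
# altnet_results: 100 DEGs (60 up, 40 down); ARN 100 nodes / 825 edges;
#   3 + 2 modules; 3 hub TFs; flow value 7; 0 feedback loop(s)
```

The file-based equivalent (`write_fixtures()` + `pipeline_config()` +
`run_pipeline()`) writes per-stage TSV/JSON/DOT outputs and the run log.
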