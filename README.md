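# altnet

Network dissection of transcriptional responses in very small cohorts.

`altnet` implements an integrated analysis for two-condition expression
studies with only a handful of individuals — the regime where per-gene
statistics collapse but network structure still carries signal. The
chain is:

1. **Rank-product differential expression** over all within-individual
   high-vs-low sample pairs, with an exactly calibrated gene-permutation
   null (one permutation per individual's block of comparisons) and BH
   correction per direction (`call_degs`). Genes responding in the same
   direction in *every* individual become sink genes (`call_concordant`).
2. **Responsive network (ARN)**: interactome edges between DEGs weighted
   by confidence × |correlation| × mean endpoint significance, kept only
   above an empirical random-edge threshold (`build_arn`), and split
   into up-/down-regulated subnetworks (`split_updown`).
3. **Modules** by Markov clustering (inflation 1.5) plus iterative
   degree-one pruning (`dissect_modules`).
4. **Regulators**: TFs scored by prestige centrality over their DEG
   targets (`prestige_weights`), top 10% selected as hubs
   (`select_hubs`), and hub-TF / DE-miRNA edges layered onto the ARN
   (`build_frn`).
5. **Pathways** by ResponseNet-style minimum-cost flow from DE miRNAs to
   the concordant sinks, cost = −log(normalized weight)
   (`build_flow_problem`, `solve_min_cost_flow`, `rank_flow_nodes`).
6. **Feedback loops**: all simple directed cycles of ≤ 5 steps
   (`find_feedback_loops`).
7. **Enrichment**: hypergeometric tests against GMT gene sets with BH
   correction (`fisher_enrichment`), paired gene-set shift tests and
   correlation-distance sample clustering.

A fully seeded synthetic-data generator with planted ground truth
(`synthetic_config`, `simulate_dataset`) makes every stage testable end
to end; see the methods vignette (`vignettes/methods.Rmd`) for the model
and all statistical choices.

## Quick start

```r
library(altnet)

cfg <- synthetic_config(seed = 7)   # 2000 genes, 4 individuals, planted truth
ds  <- simulate_dataset(cfg)
res <- analyze_dataset(ds, seed = 7)
res
#> altnet_results: 100 DEGs (60 up, 40 down); ARN 100 nodes / 825 edges;
#>   3 + 2 modules; 3 hub TFs; flow value 7; 0 feedback loop(s)

head(res$flow_ranks)                   # high-throughput flow nodes
res$modules$up$modules$M1              # largest up-regulated module
subset(res$enrichment, enriched)       # enriched gene sets
```

The file-based pipeline reads TSV/GMT inputs and writes one output file
per stage plus a run log with every threshold, seed and sub-seed:

```r
paths <- write_fixtures(ds, "fixtures")
cfg <- pipeline_config(
  expression = paths[["expression"]], samples = paths[["samples"]],
  mirna_expression = paths[["mirna_expression"]],
  interactome = paths[["interactome"]],
  tf_targets = paths[["tf_targets"]],
  mirna_targets = paths[["mirna_targets"]],
  genesets = paths[["sets"]], out_dir = "results", seed = 7)
run_pipeline(cfg)   # reruns are bit-identical
```

Configurations can also be loaded from YAML (`read_pipeline_config`).

## Tests and acceptance checks

Unit, property and acceptance tests (testthat 3e, including brute-force
oracles for the flow solver and the cycle enumeration):

```r
testthat::test_dir("tests/testthat", package = "altnet",
                   load_package = "installed")
```

The headline quantitative properties — null calibration of the
rank-product caller, planted-truth recovery, module ARI, solver-vs-oracle
agreement, cascade ranking, closed-form statistics — can be recomputed
from scratch against the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

which writes a flat JSON object of the computed numbers.
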