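# essnet

Inductive essential-gene prediction from protein–protein interaction
networks and expression-derived node features.

## What it does

Essential genes — those whose loss compromises cell viability — can be
recognized from two complementary signals: their position in PPI networks
and their expression profiles across large tumor compendia.  `essnet`
implements the full desk-to-prediction pipeline:

* **Label construction** from knockout-screen gene-effect matrices
  (DepMap-style, more negative = stronger depletion): per-line percentile
  ranks, a per-gene 0.90-coverage quantile summary, a Gaussian-KDE valley
  threshold between the bimodal summary modes (≈0.3 on real screens),
  intersection across screening technologies, and a three-way
  essential / nonessential / unlabeled partition in which conditionally
  essential genes stay unlabeled.
* **Node features**: log2(x+1) normalization, PCA (genes as observations,
  50 components by default), per-component min–max scaling; the fitted
  transform projects genes unseen at fit time through the same affine map.
* **The classifier**: a sample-and-aggregate graph neural network.  Per
  hop $k \le K$ ($K = 3$, sample sizes $[30, 25, 10]$), a uniform neighbor
  sample is mean-aggregated, concatenated with the node's own
  representation, and passed through a learned ReLU layer,

  $$h_v^k = \mathrm{ReLU}\!\big(W^k [\,h_v^{k-1};\,
    \mathrm{mean}_{u \in S_k(v)} h_u^{k-1}\,]\big),$$

  followed by a learned linear head producing a logit.  Training minimizes
  class-weighted (4:1) binary cross-entropy with Adam (lr 0.01, ≤200
  epochs, early stopping).  Forward, backpropagation and Adam are
  implemented in R with sparse-matrix aggregation — no deep-learning
  framework required.  Because predictions depend only on a gene's K-hop
  sampled neighborhood, trained models score genes and edges added after
  training (inductive), with memory flat in global network size.
* **Evaluation** under class imbalance: 4:1 negative subsampling (random
  baseline AUPRC = 0.2), stratified repeated 5-fold CV, step-area AUPRC,
  midrank AUROC, Youden-J cutoff selection, four unseen-gene scenarios
  with instrumented proof that test nodes never leak into training, and
  edge/feature perturbation scans.
* **Synthetic generators** for scale-free networks, planted hub-biased
  labels, class-separable expression and bimodal gene-effect screens, so
  everything above is testable offline.

## Worked example

```r
library(essnet)

ds  <- make_reference_dataset(synthetic_config(seed = 7))
ds
#> aligned_dataset: 2000 nodes, 10000 edges, 50 features/node
#>   labels: 200 essential, 1800 nonessential, 0 unlabeled

cfg <- model_config(input_dim = ncol(ds$features), seed = 7)
res <- run_cross_validation(ds, cfg, k = 5, repeats = 2, seed = 1)
res
#> eval_result over 10 fold evaluations:
#>   AUPRC 1.000 +/- 0.000   AUROC 1.000 +/- 0.000

youden_cutoff(res$scores$score, res$scores$label)$threshold
#> [1] 0.9647254
```

AUPRC is read against the 0.2 random baseline of the 4:1 pool; on this
cleanly separable synthetic reference the model is near-perfect, and the
interesting numbers are the orderings: perturbing all edges *and* features
collapses AUPRC to ≈0.2, while hiding test genes completely during
training (`run_unseen_scenarios(..., "drop-test-completely")`) costs only
a bounded fraction of the transductive performance.

A command-line interface wrapping the same functions lives in
`inst/cli/essnet.R`:

```sh
Rscript inst/cli/essnet.R simulate --preset reference --seed 1 --out sim/
Rscript inst/cli/essnet.R label --crispr sim/gene_effects.csv --out lab/
Rscript inst/cli/essnet.R featurize --expression sim/expression.csv --out feat/
Rscript inst/cli/essnet.R train --graph sim/edges.tsv \
    --features feat/features.tsv --labels sim/labels.tsv --seed 1 --out fit/
Rscript inst/cli/essnet.R evaluate --graph sim/edges.tsv \
    --features feat/features.tsv --labels sim/labels.tsv --seed 1 --out eval/
```

Real data enters through the same readers: STRING/CPDB-style edge lists
(`read_edge_list`, `filter_by_confidence`), DepMap-style gene-effect CSVs
(`read_gene_effect`) and expression matrices (`read_expression`).

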