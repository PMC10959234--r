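# scMultiView

Multi-view cell-type detection for single-cell RNA-seq count matrices, in
pure R.

Most deep clustering tools look at a count matrix from a single angle:
per-cell expression profiles. `scMultiView` models two complementary views
and fuses them:

* **Temporal view.** Every cell becomes an ordered sequence of gene
  tokens. Each token is the element-wise sum of a skip-gram gene-identity
  embedding, a binned-expression embedding and a co-expression-network
  ("spatial") embedding learned by node2vec-style biased random walks. A
  transformer with kernelized linear attention — softmax attention
  approximated through positive random features φ(x) = exp(ωᵀx − ‖x‖²/2)/√m
  and evaluated as Q′(K′ᵀV) so cost is linear in sequence length —
  mean-pools the tokens and classifies each cell (probabilities **A**).
* **Spatial view.** A variational autoencoder compresses expression to
  latent cell vectors; cells are wired into a KNN graph under the
  exponential-Manhattan similarity
  `sim(x, y) = R_cor(x, y) · exp(−α · d_M(x, y))` (α = 0.25), and a
  multi-head graph attention network classifies cells on that graph
  (probabilities **B**).
* **Adaptive fusion.** With branch validation accuracies Perf_A and
  Perf_B, the fused prediction is `P = W1·A + W2·B`,
  `W1 = Perf_A / (Perf_A + Perf_B)`, `W2 = 1 − W1`; an MLP fusion variant
  is also provided. Results are scored with ACC, NMI and ARI.

A negative-binomial simulator with planted cell types, marker programs,
co-expressed gene modules and technical dropout makes the whole pipeline
testable offline; real data loads from Matrix Market or CSV via
`read_counts()`.

## Worked example

```r
library(scMultiView)

res <- run_pipeline(pipeline_config(seed = 2, verbose = TRUE))
#> [   0.0s] simulated dataset
#> [   0.0s] preprocessed counts
#> [   0.2s] trained gene embeddings
#> [   2.6s] trained network (spatial) embeddings
#> [  44.4s] trained transformer branch (val acc 0.983)
#> [  49.3s] trained VAE
#> [  54.8s] trained GAT branch (val acc 0.933)
#> [  54.8s] done: ACC 0.967 NMI 0.878 ARI 0.898
print(res)
#> PipelineResult (mode: full )
#> EvaluationReport (supervised): ACC 0.967  NMI 0.878  ARI 0.898
#>   transformer val acc: 0.983
#>   GAT val acc:         0.933
```

The run simulates 300 cells x 200 genes with three planted types (60%
dropout), trains both branches on an 80% stratified split and reports the
fused metrics on the held-out 20%: `ACC` is the fraction of validation
cells assigned their true type, `NMI` and `ARI` measure partition
agreement (1 = perfect). The transformer and GAT lines show each branch's
validation accuracy before fusion — the fusion weights are proportional
to them.

Individual stages are ordinary functions if you want the pieces:
`log_normalize()`, `bin_expression()`, `build_coexpression_network()`,
`train_skipgram()`, `generate_walks()`, `train_vae()`,
`build_knn_graph()`, `train_performer()`, `train_gat()`, `fuse()`,
`evaluate_labels()`. A thin command-line wrapper lives at
`inst/cli/scmultiview.R` (subcommands `simulate`, `run`, `ablate`).

See `vignettes/multiview-methods.Rmd` for the model account, parameter
semantics and design choices.

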