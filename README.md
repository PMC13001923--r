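# graphomix

Graph convolutional classifiers for multi-omics data represent patients
as nodes of a sample-similarity network — one network per molecular
modality — and propagate molecular profiles along its edges before
predicting a disease label. How that network is *constructed* is usually
an afterthought. `graphomix` makes it the experiment: six graph
constructions (cosine similarity, cosine distance, RBF similarity, RBF
distance, and hybrid convex combinations `β·cos + (1−β)·RBF` /
`α·cos_dist + (1−α)·RBF_dist`) are benchmarked inside an otherwise
identical architecture — per-view two-layer GCNs
`H⁽ˡ⁺¹⁾ = σ(D̃^{-1/2} Ã D̃^{-1/2} H⁽ˡ⁾ Θ⁽ˡ⁾)` fused by a
view-correlation tensor head that classifies the flattened outer product
of the per-view class-probability vectors.

Because real cohorts cannot tell *why* one similarity wins, the package
ships a synthetic multi-omics generator in which class signal is planted
as a shared **direction** in feature space while per-sample multiplicative
scale jitter (a batch-effect surrogate) corrupts magnitudes. Cosine
similarity is invariant to that jitter; Euclidean-based RBF kernels are
not — so the benchmark can attribute performance differences to the
geometry of the class signal. The harness runs five stratified 70/30
splits per configuration and reports mean ± SD with paired t-tests, 95%
confidence intervals and Cohen's d.

It is aimed at methods researchers in multi-omics integration who want a
controlled, fully reproducible test bed for patient-similarity-network
design, in plain R.

## Worked example

```r
library(graphomix)

spec <- synthetic_spec(n_samples = 60, n_classes = 2,
                       views = c(mrna = 40, mirna = 20),
                       noise_sd = 0.4, seed = 8)
ds <- generate_multiomics(spec)
graphs <- lapply(ds$views, build_graph,
                 config = similarity_config("cosine_similarity", k = 6))
graphs$mrna
#> <sample_graph: 60 nodes, 246 edges, metric cosine_similarity>

model <- train_pipeline(ds, graphs, "full", train_config(), seed = 0)
pred <- predict_pipeline(model, ds, graphs)
evaluate(pred$fused, ds$labels, model$split$test_idx)
#> <metrics_report: n=18  acc=0.778  f1_macro=0.775  f1_weighted=0.775  auc_macro=0.963>
```

The 60 samples give a graph of 246 union-symmetrized edges (each node
keeps its 6 strongest cosine neighbours). Training warms up the two view
classifiers, then jointly trains them with the tensor fusion head until
the fused validation cross-entropy stops improving (here at epoch 58,
best epoch 38). On the 18 held-out samples the fused prediction ranks
almost perfectly (AUC 0.963) while hard accuracy (0.778) reflects the
deliberately noisy regime.

The full study is scripted under `analysis/` (run in order):
`01_simulate.R` draws the binary, 5-class and low-noise cohorts,
`02_preprocess.R` exercises the log/filter/impute/quantile chain,
`03_build_graphs.R` exports all six graphs per view as Matrix Market
files, `04_benchmark.R` runs 6 graphs × 5 splits plus the ablations
(average fusion; fully connected), and `05_report.R` writes the paired
t-test / CI / Cohen's d comparison tables under `results/`. On the
bundled binary cohort, cosine-similarity graphs give the highest mean
test AUC with the smallest spread (0.911 ± 0.010, vs 0.891 ± 0.037 for
median-γ RBF), and the full tensor-fusion model beats average fusion —
the pattern the architecture predicts when class signal is directional
and magnitudes are nuisance.

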