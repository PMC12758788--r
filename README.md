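# labelbridge

Semi-supervised cross-modality cell type annotation for single-cell data.

Given a **reference** dataset with curated cell type labels and an unlabeled
**query** dataset — possibly from a different protocol or modality
(scRNA-seq counts, scATAC-seq gene activity, peak accessibility) —
labelbridge transfers the reference labels to the query, rejects cells of
types absent from the reference as `Unknown`, and explains each annotation
by the input features that drove it.

## The method

A shared feature extractor *f* embeds cells from both datasets into one
m-dimensional space, a linear softmax classifier *c* predicts over the K
reference types, and an auxiliary attention network *A* scores each
embedding dimension. All three are trained jointly on paired mini-batches
(B_r, B_q) under

```
L = L_CE + 0.1 · L_PR + α · L_CL + β · L_FA + γ · L_SC
```

- **L_CE** — cross-entropy on the labeled reference batch;
- **L_PR** — projection regularizer: reciprocal spread of the query
  embedding plus mean |off-diagonal Pearson correlation| and mean
  |per-dimension mean| of both batches;
- **L_CL** — InfoNCE contrastive loss (temperature τ, cosine similarity)
  preserving the query's raw-space k-nearest-neighbor graph (PCA-50,
  k = 15) in the embedding;
- **L_FA** — feature alignment: the top fraction of query cells by
  best-match cosine similarity are pulled toward their nearest reference
  cells;
- **L_SC** — sparse center loss: attention-weighted squared distance of
  each embedding to its (dynamically updated) class center, using true
  labels for reference cells and the classifier's own iteratively refined
  pseudo-labels for query cells.

Four built-in presets set (α, β, γ, τ) per scenario — matched or
unmatched RNA→ATAC (cap 3000 iterations), RNA→RNA and ATAC→ATAC (cap 200)
— with early stopping once the sparse loss plateaus for 20 consecutive
iterations. At prediction time the parameters are frozen and a cell is
assigned its argmax type only when the confidence strictly exceeds a
threshold (default 0.95), otherwise `Unknown`. The interpreter module
attributes each prediction to input features via integrated gradients
(exact for the default architecture thanks to a ReLU-kink-aware path
partition), aggregates per-cell top-100 features into per-type top-50
*determinant features*, and scores them against curated markers with the
key-gene hit rate (KGHR).

No deep-learning framework is required: the networks, their gradients
(reverse-mode tape) and the whole training loop are plain R matrix code,
bitwise reproducible for a fixed seed.

## Worked example

Everything below runs in about a minute on one CPU; the numbers are the
script's actual output.

```r
library(labelbridge)

# simulate a labeled reference and a domain-shifted unlabeled query
spec <- synthetic_spec(n_ref = 600, n_query = 600, n_features = 80, K = 4,
                       separation = 12, shift_strength = 0.3,
                       dropout_rate = 0.3, seed = 42)
sim <- generate_paired_domains(spec)

# shared feature space + log-normalization
common <- intersect_features(sim$ref, sim$query)
ref <- log_normalize(common$ref)
query <- log_normalize(common$query)

# train with the cross-modality preset, scaled to this problem size
cfg <- scenario_preset("unmatched_rna_atac")
cfg$batch_size <- 200L; cfg$hidden_dims <- 64L
cfg$max_iterations <- 200L; cfg$learning_rate <- 0.02
cfg$warmup <- 80L; cfg$seed <- 1L
fit <- fit_annotator(ref, query, cfg)
tail(fit$log, 2)
#>     iteration       l_ce      l_pr     l_cl       l_fa     l_sc    total
#> 199       199 0.01406905 0.6841612 4.804060 -0.9056214 7.987601 5.881953
#> 200       200 0.02411545 0.6353343 4.732613 -0.9036275 7.959421 5.801197

# annotate with open-set rejection at 0.95
pred <- annotate_cells(fit$model, query, threshold = 0.95)
pred
#> predictions for 600 cells (threshold 0.95):
#>   type3 Unknown   type1   type2   type4
#>     148     139     111     103      99

evaluation_report(sim$query_labels, pred)
#> accuracy: 0.7367  macro-F1: 0.8297
```

The reference cross-entropy has collapsed to ~0.02 (the model fits the
labeled side), the alignment loss sits near −0.9 (matched cross-domain
pairs are almost cosine-identical), and 139 shifted cells fall below the
0.95 confidence bar. With rejection disabled the same model force-assigns
every cell at 0.89 accuracy:

```r
annotation_accuracy(sim$query_labels,
                    annotate_cells(fit$model, query, 0)$assigned_type)
#> [1] 0.8916667
```

Which features drove the calls, and do they match the generator's planted
markers?

```r
cls <- classify_cells(fit$model, embed_cells(fit$model, query$values))
attr <- integrated_gradients(fit$model, query$values, cls$predicted_class,
                             n_steps = 20)
det <- determinant_features(attr, pred, query$feature_names,
                            n_per_cell = 20, n_per_type = 10)
head(det$per_type_top$type1, 3)
#>   feature frequency rank
#> 1   feat7 0.8378378    1
#> 2  feat14 0.8288288    2
#> 3  feat18 0.7837838    3

round(kghr(det, generate_marker_lists(spec, n_markers = 20)), 2)
#> type2 type1 type3 type4
#>   0.7   0.4   0.6   0.7
```

40–70% of each type's determinant features are planted markers (chance
level here is 25%).

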