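# tpmda

Tree-path attention models for miRNA–disease association prediction.

## What this is for

Curated databases of experimentally validated miRNA–disease associations
define a sparse bipartite 0/1 matrix `R` (about 2% of cells are known
associations at the scale of current curation: 1207 miRNAs × 889 diseases,
21,152 pairs, a correlation rate of 1.971%). Researchers prioritising
candidate miRNAs for a disease want the unknown cells ranked by how likely
they are to be true, yet-unobserved associations.

`tpmda` implements a predictor that uses **no similarity matrices** and sees
**beyond direct neighbourhoods**: each entity is represented by its
*association tree* — a breadth-first tree over `R` whose layers alternate
between miRNAs and diseases, so depth-k nodes are k association hops away —
and the root-to-leaf **tree-paths** are encoded with multi-head scaled
dot-product self-attention over learned node embeddings,

```
Attention(Q, K, V) = softmax(Q Kᵀ / √d_k) V,   Q = X W^Q, K = X W^K, V = X W^V,
```

with the `h` head outputs concatenated through `W^O`, mean-pooled over path
positions and over paths. The two entity encodings of a candidate pair are
concatenated and scored by a fully connected network (three ReLU hidden
layers, one sigmoid output), trained end to end with Adam on binary
cross-entropy under a balanced, fold-disjoint negative-sampling, 5-fold
cross-validation protocol. A matrix-flatten ablation mode (`mode =
"matrix"`: the pair's matrix row ++ column as the encoder input) is included
as the baseline the tree representation is measured against.

Everything is testable offline: a planted-block synthetic generator produces
sparse bipartite matrices with recoverable multi-hop structure, and the whole
pipeline — trees, attention, training, protocol, metrics — is validated
against independent oracles (graph-search BFS, a naive per-head attention
reference, the Mann–Whitney AUC estimator, numerical gradients).

## Worked example

Generate a planted-block dataset, hold out 20% of the within-block
positives, train the reduced configuration, and measure recovery:

```r
library(tpmda)
library(dplyr)

ds <- generate_associations(synthetic_spec(
  n_mirna = 100, n_disease = 80, n_blocks = 4,
  p_within = 0.3, p_between = 0.005, seed = 20260925
))
glance(ds)
#> # A tibble: 1 × 4
#>   n_mirna n_disease n_pairs density
#>     <int>     <int>   <int>   <dbl>
#> 1     100        80     662  0.0828

ho <- holdout_planted(ds, fraction = 0.2, seed = 11)
fit <- fit_tpmda(ho$train_pairs, ds, mode = "tree",
                 d_model = 32, heads = 4, max_depth = 2, max_paths = 16,
                 epochs = 200, learning_rate = 1e-3, seed = 7)

test <- bind_rows(mutate(ho$test_pos, label = 1L),
                  mutate(ho$test_neg_easy, label = 0L))
scored <- predict(fit, test)
roc_auc(scored$.score, scored$label)
#> <roc_curve> AUC 0.9128 (127 positives, 127 negatives, 233 points)
```

An AUC of 0.91 means a held-out within-block association outranks a random
between-block cell 91% of the time — the model has learned the planted
community structure from multi-hop co-association alone. The same pipeline
trained after shuffling the training labels scores AUC ≈ 0.52 (chance), and
the matrix-flatten ablation, which by construction can only see row/column
degree counts, also stays near chance — the qualitative tree-versus-matrix
gap the method claims.

Cross-validation and candidate ranking follow the same grammar:

```r
cv <- cv_tpmda(ds, k = 5, seed = 1, mode = "tree", d_model = 32, heads = 4,
               max_depth = 2, max_paths = 16, epochs = 200, learning_rate = 1e-3)
tidy(cv)     # per-fold AUC, MSE, both accuracy definitions
glance(cv)   # CV(k) = mean fold MSE, mean AUC
rank_candidates(fit, ds, disease = "d0017", top_k = 15)
```

`autoplot()` methods draw the training-loss curve, ROC curves and per-fold
metric summaries. A thin command-line wrapper with `build`, `synth`,
`tree`, `cv` and `rank` subcommands ships in `inst/cli/tpmda.R`.

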