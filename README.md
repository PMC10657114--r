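# duplexgnn

Graph neural network classification of miRNA–mRNA duplexes from
word-embedded nucleotide triplets.

## The problem

MicroRNAs (miRNAs) are ~22 nt non-coding RNAs that repress translation by
guiding the silencing complex to partially complementary sites on mRNAs.
Deciding whether a candidate miRNA–site pair (a *duplex*) is a true
interaction is a binary classification problem; experimental validation is
slow and costly, so sequence-based classifiers are used to rank candidates.
`duplexgnn` is for computational biologists who want a self-contained,
inspectable implementation of a graph-based duplex classifier: every stage —
encoding, graph construction, message passing, training protocol,
evaluation — is exposed as an R function with tests, and a synthetic
generator makes the whole pipeline runnable without any external data.

## The method

1. **Token sentences.** Each sequence is cut into consecutive 3-nt words
   (a trailing 1–2 nt remainder is kept as its own word), so a sequence
   becomes a "sentence" over a small vocabulary of triplets.
2. **Word embeddings.** A CBOW word2vec model (negative sampling, dimension
   16) is fitted per corpus — one on the training-split miRNA sentences, one
   on the training-split site sentences — and each word is replaced by its
   dense vector. Fitting on the training split only prevents test leakage.
3. **Duplex graph.** The embedded words are the graph's nodes. Consecutive
   words within each sequence are chained, and the two sequences are aligned
   at their first words with one cross edge per aligned position, giving
   `(n−1) + (m−1) + min(n, m)` undirected edges, max degree 3.
4. **Classifier.** A stack of `L_GNN` node-embedding layers of one family —
   spectral convolution `σ(D̃^{-1/2} Ã D̃^{-1/2} H W)`, sample-and-aggregate
   `σ(W·[h_v, mean_{u∈N(v)} h_u]) / ‖·‖₂`, or single-head attention
   `σ(Σ_u α_vu W h_u)` with `α_vu = softmax_u(LeakyReLU(a·[W h_v, W h_u]))`
   — followed by a global ADD/MEAN/MAX readout and fully connected layers
   with ReLU, dropout after every but the last layer, and a 2-way softmax.
5. **Protocol.** 0.7/0.15/0.15 stratified splits, Adam (lr 0.001),
   learning-rate reduction on validation-loss plateau, early stopping,
   best-epoch parameters; metrics are balanced accuracy
   `(TP/(TP+FN) + TN/(TN+FP))/2`, precision `TP/(TP+FP)` and recall
   `TP/(TP+FN)`, aggregated over replicate splits with normal-approximation
   95% confidence intervals.

There is no deep-learning framework dependency: the layers, backpropagation
(verified against central finite differences) and the Adam optimizer are
implemented in vectorized R, and the CBOW trainer in C++ via Rcpp.

## Worked example

```r
library(duplexgnn)

# 400 synthetic duplexes; positives carry the DNA reverse complement of the
# miRNA seed (nt 2-8) at a random offset inside the 40-nt site
duplexes <- generate_dataset(simulation_config(n_pairs = 400, rng_seed = 7))

config <- classifier_config("GAT", l_gnn = 2, d_gnn = 16, l_fc = 2,
                            d_fc = 16, pool = "ADD", dropout = 0.4)
tconf  <- train_config(max_epochs = 10, batch_size = 32, seed = 7)
spec   <- split_spec(n_replicates = 3, base_seed = 7)
res <- run_replicates(duplexes, config, tconf, spec,
                      embed_opts = list(epochs = 25))
print(res$summary, digits = 3)
#>              metric  mean ci_low ci_high
#> 1 balanced_accuracy 0.533  0.434   0.633
#> 2         precision 0.527  0.410   0.643
#> 3            recall 0.478  0.300   0.656

# upper bound on what the planted signal supports:
compute_metrics(duplexes$label, seed_match_classifier(duplexes))
#> TP=200 TN=200 FP=0 FN=0 | BACC=1.0000 Precision=1.0000 Recall=1.0000
```

The summary rows are means and 95% CIs over the three replicate splits. The
GNN hovers near chance here — the synthetic positives differ from negatives
*only* through the miRNA–site complementarity relation, which additive
message passing cannot extract at this scale (see the vignette) — while the
substring oracle confirms the planted signal itself is perfect. On real
benchmark collections, where binding sites also carry compositional signal,
this architecture family is reported to reach balanced accuracies above 0.9.

The tuned full-scale architectures are available as presets:

```r
optimal_config("GAT")   # 5 x 256 attention layers, 2 FC x 128, ADD, dropout 0.4
```

## Command line

```sh
exec/duplexgnn simulate --n-pairs 1000 --seed 1 --out-dir data/
exec/duplexgnn train --config run.json --out-dir run/        # checkpoint + log
exec/duplexgnn evaluate --checkpoint run/checkpoint.json --data data/dataset.tsv --out-dir run/
exec/duplexgnn predict  --checkpoint run/checkpoint.json --data data/dataset.tsv --out-dir run/
exec/duplexgnn replicates --config run.json --out-dir run/   # full experiment
exec/duplexgnn ablate --config run.json --param l_gnn --values 1,2,3 --out-dir run/
```

`run.json` mirrors the R constructors:

```json
{
  "data": "data/dataset.tsv",
  "classifier": {"e_gnn": "GAT", "l_gnn": 2, "d_gnn": 32, "l_fc": 2,
                 "d_fc": 32, "pool": "ADD", "dropout": 0.4},
  "training": {"max_epochs": 50, "batch_size": 64, "seed": 1},
  "split": {"n_replicates": 3, "base_seed": 1},
  "embedding": {"epochs": 100}
}
```

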