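# End-to-end learnability experiment on planted-signal synthetic data: the
# pipeline (simulate -> split -> CBOW -> graphs -> scaled-down attention
# classifier -> held-out metrics), plus a label-shuffled control that
# destroys the miRNA-site association while keeping both marginals intact.

#' Planted-signal learnability experiment
#'
#' Generates `n_pairs` noise-free synthetic duplexes, draws one 0.7/0.15/0.15
#' stratified split, fits the two CBOW models on the training portion, trains
#' a scaled-down attention classifier (2 layers, 32-dim embeddings, 32-dim FC,
#' ADD readout, dropout 0.4, batch 64, at most `max_epochs` epochs) and scores
#' the held-out test set. With `shuffle_labels = TRUE` the training/validation
#' labels are permuted first, which removes the planted association and gives
#' the chance-level control.
#'
#' @param n_pairs dataset size (default 2000).
#' @param seed seed driving generation, split, embedding and training.
#' @param max_epochs training epoch cap (default 50).
#' @param shuffle_labels run the label-shuffled control instead.
#' @return list with `metrics` (a `metrics_report` on the test set),
#'   `fit` (the training result) and `n_test`.
#' @export
learnability_experiment <- function(n_pairs = 2000L, seed = 1L,
                                    max_epochs = 50L,
                                    shuffle_labels = FALSE) {
  ds <- generate_dataset(simulation_config(n_pairs, label_noise = 0,
                                           rng_seed = seed))
  if (shuffle_labels) {
    old <- globalenv()$.Random.seed
    set.seed(seed + 31L)
    ds$label <- ds$label[sample.int(nrow(ds))]
    restore_seed(old)
  }
  rec <- split_dataset(ds, split_spec(n_replicates = 1L, base_seed = seed), 0L)
  tables <- fit_embeddings(rec, seed = seed)
  gds <- lapply(c(train = "train", val = "val", test = "test"), function(tg)
    build_graph_dataset(rec[rec$split == tg, , drop = FALSE], tables))
  config <- classifier_config("GAT", l_gnn = 2L, d_gnn = 32L,
                              l_fc = 2L, d_fc = 32L, pool = "ADD",
                              dropout = 0.4)
  tconf <- train_config(max_epochs = max_epochs, batch_size = 64L, seed = seed)
  fit <- train_model(gds$train, gds$val, config, tconf)
  probs <- predict_graphs(gds$test$graphs, fit$params, config)
  metrics <- compute_metrics(gds$test$labels,
                             as.integer(probs[, "positive"] > 0.5))
  list(metrics = metrics, fit = fit, n_test = length(gds$test$labels))
}
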