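test_that("split sizes are the rounded fractions (700/150/150 for 1,000 records)", {
  rec <- data.frame(mirna_seq = "ACG", site_seq = "TTT",
                    label = rep(0:1, each = 500))
  sp <- split_spec(base_seed = 4)
  out <- split_dataset(rec, sp, 0)
  expect_equal(as.vector(table(out$split)), c(700, 150, 150))
})

test_that("splits are deterministic, disjoint and stratified", {
  set.seed(30)
  for (i in 1:20) {
    n <- sample(seq(40, 400, by = 4), 1)
    rec <- data.frame(mirna_seq = "ACG", site_seq = "TTT",
                      label = rbinom(n, 1, 0.5))
    sp <- split_spec(n_replicates = 5, base_seed = i)
    r <- sample(0:4, 1)
    s1 <- split_dataset(rec, sp, r)
    s2 <- split_dataset(rec, sp, r)
    expect_identical(s1$split, s2$split)
    expect_false(any(is.na(s1$split)))                 # exhaustive
    expect_equal(nrow(s1), n)                          # disjoint by column
  }
  # balanced 500/500, stratified: each part within 1 record of 50% positives
  rec <- data.frame(mirna_seq = "ACG", site_seq = "TTT",
                    label = rep(0:1, each = 500))
  out <- split_dataset(rec, split_spec(base_seed = 11), 3)
  for (tg in c("train", "val", "test")) {
    part <- out[out$split == tg, ]
    expect_lte(abs(sum(part$label) - nrow(part) / 2), 1)
  }
  expect_error(split_spec(0.5, 0.2, 0.2), "sum to 1")
  expect_error(split_dataset(rec, split_spec(), 30), "out of range")
  expect_error(split_dataset(rec[1:5, ], split_spec(), 0), "at least 10")
})

test_that("compute_metrics reproduces the confusion-matrix formulas", {
  m <- compute_metrics(labels = rep(c(1, 0), c(10, 10)),
                       predictions = c(rep(1, 8), rep(0, 2),
                                       rep(0, 9), rep(1, 1)))
  expect_equal(m$tp, 8); expect_equal(m$fn, 2)
  expect_equal(m$tn, 9); expect_equal(m$fp, 1)
  expect_equal(m$balanced_accuracy, 0.85)
  expect_equal(m$precision, 8 / 9)
  expect_equal(m$recall, 0.8)

  perfect <- compute_metrics(c(0, 1, 1, 0), c(0, 1, 1, 0))
  expect_equal(perfect$balanced_accuracy, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)

  # no positive predictions: precision undefined, recall still computed
  none <- compute_metrics(c(1, 1, 0), c(0, 0, 0))
  expect_true(is.na(none$precision))
  expect_equal(none$recall, 0)

  expect_error(compute_metrics(c(0, 1), c(1)), "equal length")
  expect_error(compute_metrics(c(0, 2), c(1, 0)), "binary")
})

test_that("metrics agree with an independent recomputation on 1,000 random pairs", {
  set.seed(31)
  for (i in 1:1000) {
    n <- sample(4:60, 1)
    labels <- rbinom(n, 1, 0.5)
    preds <- rbinom(n, 1, runif(1, 0.2, 0.8))
    m <- compute_metrics(labels, preds)
    o <- oracle_metrics(labels, preds)
    expect_equal(m$tp + m$tn + m$fp + m$fn, n)
    cmp <- function(a, b) {
      if (is.nan(b)) expect_true(is.na(a)) else expect_equal(a, b, tolerance = 1e-12)
    }
    cmp(m$balanced_accuracy, o$bacc)
    cmp(m$precision, o$precision)
    cmp(m$recall, o$recall)
  }
})

make_separable_ds <- function(n, fdim = 16, seed = 5) {
  # planted linear signal in the node features themselves
  set.seed(seed)
  labels <- rep(0:1, length.out = n)
  graphs <- lapply(seq_len(n), function(i) {
    shift <- if (labels[i] == 1) 1.5 else -1.5
    build_duplex_graph(matrix(rnorm(2 * fdim, mean = shift), 2, fdim),
                       matrix(rnorm(3 * fdim, mean = shift), 3, fdim))
  })
  list(graphs = graphs, labels = labels)
}

test_that("training reduces the loss on a linearly separable set", {
  ds <- make_separable_ds(50)
  val <- make_separable_ds(20, seed = 6)
  cc <- classifier_config("GCN", 1, 4, 1, 4, "MEAN", 0)
  tc <- train_config(max_epochs = 15, batch_size = 10, seed = 3)
  fit <- train_model(ds, val, cc, tc)
  expect_lt(fit$log$train_loss[nrow(fit$log)], fit$log$train_loss[1])
  expect_lte(fit$best_epoch, fit$stopped_epoch)
})

test_that("early stopping halts exactly at the patience bound when nothing improves", {
  ds <- make_separable_ds(20)
  val <- make_separable_ds(10, seed = 7)
  cc <- classifier_config("GCN", 1, 4, 1, 4, "MEAN", 0)
  # frozen optimizer (lr = 0): validation loss is constant, best epoch is 1
  tc <- train_config(max_epochs = 50, initial_lr = 0, batch_size = 10,
                     early_stop_patience = 7, seed = 3)
  fit <- train_model(ds, val, cc, tc)
  expect_equal(fit$best_epoch, 1L)
  expect_equal(fit$stopped_epoch, 1L + 7L)
  # returned parameters are the best epoch's, never later
  expect_equal(fit$params, init_parameters(cc, 3))
})

test_that("identical seeds give identical training logs", {
  ds <- make_separable_ds(30)
  val <- make_separable_ds(10, seed = 8)
  cc <- classifier_config("GAT", 1, 4, 2, 4, "ADD", 0.3)
  tc <- train_config(max_epochs = 5, batch_size = 8, seed = 17)
  f1 <- train_model(ds, val, cc, tc)
  f2 <- train_model(ds, val, cc, tc)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$params, f2$params)
})

test_that("train_model validates inputs", {
  ds <- make_separable_ds(10)
  cc <- classifier_config("GCN", 1, 4, 1, 4, "MEAN", 0)
  tc <- train_config(max_epochs = 2, seed = 1)
  expect_error(train_model(list(graphs = list(), labels = integer(0)), ds, cc, tc),
               "empty")
})

test_that("replicate summaries: bookkeeping, zero variance, hand-computed CI", {
  # injected metrics {0.8, 0.9, 1.0}: mean 0.9, CI = 0.9 +- 1.96 * 0.1/sqrt(3)
  stub <- data.frame(balanced_accuracy = c(0.8, 0.9, 1.0),
                     precision = c(0.8, 0.9, 1.0), recall = c(0.8, 0.9, 1.0))
  s <- summarize_replicates(stub)
  expect_equal(nrow(s), 3)
  expect_equal(s$mean, rep(0.9, 3))
  se <- sd(c(0.8, 0.9, 1.0)) / sqrt(3)
  expect_equal(s$ci_low, rep(0.9 - 1.96 * se, 3), tolerance = 1e-12)
  expect_equal(s$ci_high, rep(0.9 + 1.96 * se, 3), tolerance = 1e-12)
  expect_equal(s$ci_high[1] - s$ci_low[1], 2 * 1.96 * 0.1 / sqrt(3),
               tolerance = 1e-12)

  zero <- summarize_replicates(stub[c(2, 2, 2), ])
  expect_equal(zero$ci_low, zero$ci_high)  # zero-variance: CI width 0
  expect_error(summarize_replicates(stub[0, ]), "nothing to summarize")
})

test_that("run_replicates produces one row per replicate plus a summary", {
  ds <- toy_records(60, seed = 12)
  cc <- classifier_config("GCN", 1, 4, 1, 4, "MEAN", 0)
  tc <- train_config(max_epochs = 3, batch_size = 16, seed = 2)
  sp <- split_spec(n_replicates = 3, base_seed = 5)
  res <- run_replicates(ds, cc, tc, sp, embed_opts = list(epochs = 5),
                        keep_predictions = TRUE)
  expect_equal(nrow(res$replicates), 3)
  expect_equal(res$replicates$replicate, 0:2)
  expect_equal(nrow(res$summary), 3)
  expect_true(all(is.na(res$replicates$error)))
  # predictions row count equals the test-set size
  n_test <- sum(split_dataset(ds, sp, 0)$split == "test")
  expect_equal(nrow(res$predictions[[1]]), n_test)
})
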