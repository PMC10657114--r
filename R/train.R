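# Training protocol: Adam on two-class cross-entropy, learning-rate
# reduction on validation-loss plateau, early stopping, best-epoch snapshot;
# plus dataset splitting, metrics and the multi-replicate driver.

#' Training configuration
#'
#' @param max_epochs maximum epochs (default 1000).
#' @param initial_lr Adam learning rate (default 0.001).
#' @param batch_size minibatch size B_s (default 64).
#' @param early_stop_patience epochs without validation-loss improvement
#'   before stopping (default 100).
#' @param lr_reduce_factor multiplier applied on plateau (default 0.1).
#' @param lr_reduce_patience plateau length in epochs (default 10).
#' @param lr_min learning-rate floor (default 1e-6).
#' @param seed seed controlling initialization, shuffling and dropout.
#' @return A `train_config`.
#' @export
train_config <- function(max_epochs = 1000L, initial_lr = 0.001,
                         batch_size = 64L, early_stop_patience = 100L,
                         lr_reduce_factor = 0.1, lr_reduce_patience = 10L,
                         lr_min = 1e-6, seed = 1L) {
  stopifnot(max_epochs >= 1, initial_lr >= 0, batch_size >= 1,
            early_stop_patience >= 1, lr_reduce_patience >= 1)
  structure(list(max_epochs = as.integer(max_epochs), initial_lr = initial_lr,
                 batch_size = as.integer(batch_size),
                 early_stop_patience = as.integer(early_stop_patience),
                 lr_reduce_factor = lr_reduce_factor,
                 lr_reduce_patience = as.integer(lr_reduce_patience),
                 lr_min = lr_min, seed = as.integer(seed)),
            class = "train_config")
}

#' Replicate split specification
#'
#' @param train_frac,val_frac,test_frac partition fractions; must sum to 1
#'   (default 0.7/0.15/0.15).
#' @param n_replicates number of independent splits (default 30).
#' @param stratified stratify the partition by label (default TRUE).
#' @param base_seed base seed; replicate r uses `base_seed + r`.
#' @return A `split_spec`.
#' @export
split_spec <- function(train_frac = 0.7, val_frac = 0.15, test_frac = 0.15,
                       n_replicates = 30L, stratified = TRUE, base_seed = 1L) {
  fr <- c(train_frac, val_frac, test_frac)
  if (any(fr <= 0) || any(fr >= 1)) stop("fractions must lie in (0, 1)")
  if (abs(sum(fr) - 1) > 1e-9) stop("fractions must sum to 1")
  structure(list(train_frac = train_frac, val_frac = val_frac,
                 test_frac = test_frac, n_replicates = as.integer(n_replicates),
                 stratified = isTRUE(stratified),
                 base_seed = as.integer(base_seed)),
            class = "split_spec")
}

#' Partition records into train/validation/test for one replicate
#'
#' Draws a random, optionally label-stratified partition at the configured
#' fractions. The partition is a deterministic function of
#' `(base_seed, replicate_index)`.
#'
#' @param records data.frame of duplex records (needs a `label` column when
#'   stratified).
#' @param spec a `split_spec`.
#' @param replicate_index 0-based replicate number, `< n_replicates`.
#' @return `records` with an added `split` factor column
#'   (`"train"`/`"val"`/`"test"`).
#' @export
split_dataset <- function(records, spec, replicate_index = 0L) {
  if (!inherits(spec, "split_spec")) stop("`spec` must be a split_spec")
  if (replicate_index < 0L || replicate_index >= spec$n_replicates)
    stop("replicate_index out of range")
  n <- nrow(records)
  if (n < 10L) stop("need at least 10 records to split")
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(spec$base_seed + as.integer(replicate_index))
  split <- character(n)
  strata <- if (spec$stratified) split(seq_len(n), records$label)
            else list(seq_len(n))
  for (ix in strata) {
    k <- length(ix)
    perm <- ix[sample.int(k)]
    n_tr <- round(k * spec$train_frac)
    n_va <- round(k * spec$val_frac)
    if (n_tr + n_va >= k) stop("fractions leave an empty test set in a stratum")
    split[perm[seq_len(n_tr)]] <- "train"
    split[perm[n_tr + seq_len(n_va)]] <- "val"
    split[perm[(n_tr + n_va + 1L):k]] <- "test"
  }
  records$split <- factor(split, levels = c("train", "val", "test"))
  records
}

#' Build embedded duplex graphs for a set of records
#'
#' Tokenizes each sequence, embeds the words through the corresponding
#' fitted table (miRNA words through the miRNA model, site words through the
#' mRNA model) and assembles the duplex graph.
#'
#' @param records duplex records (`mirna_seq`, `site_seq`, `label`).
#' @param tables list with `mirna` and `mrna` embedding tables, e.g. from
#'   [fit_embeddings()].
#' @return list with `graphs` (list of `duplex_graph`) and `labels`
#'   (integer vector).
#' @export
build_graph_dataset <- function(records, tables) {
  graphs <- lapply(seq_len(nrow(records)), function(i) {
    build_duplex_graph(
      embed_tokens(tokenize_sequence(records$mirna_seq[i]), tables$mirna),
      embed_tokens(tokenize_sequence(records$site_seq[i]), tables$mrna))
  })
  list(graphs = graphs, labels = as.integer(records$label))
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  zero <- function(x) if (is.list(x)) lapply(x, zero) else x * 0
  list(m = zero(unclass(params)), v = zero(unclass(params)), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      res <- Map(walk, p, g, m, v)
      list(p = lapply(res, `[[`, "p"), m = lapply(res, `[[`, "m"),
           v = lapply(res, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      list(p = p - lr * (m / bc1) / (sqrt(v / bc2) + eps), m = m, v = v)
    }
  }
  res <- walk(unclass(params), grads, state$m, state$v)
  params$gnn <- res$p$gnn
  params$fc <- res$p$fc
  list(params = params, state = list(m = res$m, v = res$v, t = state$t))
}

# ---- training loop ----------------------------------------------------------

#' Train a duplex classifier
#'
#' Minimizes two-class cross-entropy with Adam. The validation loss is
#' monitored each epoch: the learning rate is multiplied by
#' `lr_reduce_factor` after `lr_reduce_patience` epochs without improvement
#' (floored at `lr_min`), and training stops after `early_stop_patience`
#' epochs without improvement or at `max_epochs`. The returned parameters are
#' those of the best-validation-loss epoch, never a later one.
#'
#' @param train,val graph datasets from [build_graph_dataset()] (the
#'   embedding tables must have been fitted on the training split only).
#' @param config a `classifier_config`.
#' @param tconf a `train_config`.
#' @param verbose print per-epoch progress to stderr.
#' @return list with `params` (best epoch), `log` (data.frame: epoch,
#'   train_loss, val_loss, lr, val_bacc), `best_epoch`, `stopped_epoch`.
#' @export
train_model <- function(train, val, config, tconf, verbose = FALSE) {
  if (length(train$graphs) == 0L || length(val$graphs) == 0L)
    stop("empty train or validation set")
  check <- length(train$labels) == length(train$graphs) &&
    length(val$labels) == length(val$graphs)
  if (!check) stop("labels/graphs length mismatch")
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(tconf$seed)
  params <- init_parameters(config, seed = tconf$seed)
  state <- adam_init(params)
  n_tr <- length(train$graphs)
  val_batch <- collate_graphs(val$graphs)
  lr <- tconf$initial_lr
  best_loss <- Inf
  best_params <- params
  best_epoch <- 0L
  es_wait <- 0L
  lr_wait <- 0L
  log <- vector("list", tconf$max_epochs)
  epoch <- 0L
  for (epoch in seq_len(tconf$max_epochs)) {
    perm <- sample.int(n_tr)
    chunks <- split(perm, ceiling(seq_along(perm) / tconf$batch_size))
    tr_loss <- 0
    for (ix in chunks) {
      b <- collate_graphs(train$graphs[ix])
      lg <- engine_loss_grad(b, train$labels[ix], params, config,
                             training = TRUE)
      if (!is.finite(lg$loss))
        stop(sprintf("non-finite training loss at epoch %d; aborting", epoch))
      tr_loss <- tr_loss + lg$loss * length(ix)
      if (lr > 0) {
        up <- adam_step(params, lg$grads, state, lr)
        params <- up$params
        state <- up$state
      }
    }
    tr_loss <- tr_loss / n_tr
    ev <- engine_loss_grad(val_batch, val$labels, params, config,
                           training = FALSE, want_grad = FALSE)
    val_loss <- ev$loss
    if (!is.finite(val_loss))
      stop(sprintf("non-finite validation loss at epoch %d; aborting", epoch))
    pred <- as.integer(ev$probs[, 2] > 0.5)
    val_bacc <- compute_metrics(val$labels, pred)$balanced_accuracy
    log[[epoch]] <- data.frame(epoch = epoch, train_loss = tr_loss,
                               val_loss = val_loss, lr = lr,
                               val_bacc = val_bacc)
    if (verbose)
      message(sprintf("epoch %d: train %.4f val %.4f bacc %.3f lr %g",
                      epoch, tr_loss, val_loss, val_bacc, lr))
    if (val_loss < best_loss) {
      best_loss <- val_loss
      best_params <- params
      best_epoch <- epoch
      es_wait <- 0L
      lr_wait <- 0L
    } else {
      es_wait <- es_wait + 1L
      lr_wait <- lr_wait + 1L
      if (lr_wait >= tconf$lr_reduce_patience) {
        lr <- max(lr * tconf$lr_reduce_factor, tconf$lr_min)
        lr_wait <- 0L
      }
      if (es_wait >= tconf$early_stop_patience) break
    }
  }
  list(params = best_params, log = do.call(rbind, log[!vapply(log, is.null, TRUE)]),
       best_epoch = best_epoch, stopped_epoch = epoch)
}

# ---- metrics ----------------------------------------------------------------

#' Confusion-matrix metrics for binary predictions
#'
#' Balanced accuracy `(TP/(TP+FN) + TN/(TN+FP))/2`, precision `TP/(TP+FP)`
#' and recall `TP/(TP+FN)`. A zero denominator yields `NA` (undefined) for
#' the affected metric rather than a number.
#'
#' @param labels,predictions equal-length binary (0/1) vectors.
#' @return A `metrics_report`: list with `tp`, `tn`, `fp`, `fn`,
#'   `balanced_accuracy`, `precision`, `recall`.
#' @export
compute_metrics <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length")
  labels <- as.integer(labels)
  predictions <- as.integer(predictions)
  if (!all(labels %in% 0:1) || !all(predictions %in% 0:1))
    stop("labels and predictions must be binary (0/1)")
  tp <- sum(labels == 1L & predictions == 1L)
  tn <- sum(labels == 0L & predictions == 0L)
  fp <- sum(labels == 0L & predictions == 1L)
  fn <- sum(labels == 1L & predictions == 0L)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  bacc <- if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 balanced_accuracy = bacc,
                 precision = safe_div(tp, tp + fp),
                 recall = sens),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("TP=%d TN=%d FP=%d FN=%d | BACC=%.4f Precision=%.4f Recall=%.4f\n",
              x$tp, x$tn, x$fp, x$fn, x$balanced_accuracy, x$precision,
              x$recall))
  invisible(x)
}

#' Summarize replicate metrics with normal-approximation 95% CIs
#'
#' @param replicates data.frame with columns `balanced_accuracy`,
#'   `precision`, `recall` (one row per completed replicate).
#' @return data.frame with columns `metric`, `mean`, `ci_low`, `ci_high`.
#' @export
summarize_replicates <- function(replicates) {
  if (nrow(replicates) == 0L) stop("nothing to summarize: no completed replicates")
  metrics <- c("balanced_accuracy", "precision", "recall")
  do.call(rbind, lapply(metrics, function(m) {
    x <- replicates[[m]]
    x <- x[!is.na(x)]
    mu <- mean(x)
    se <- if (length(x) > 1L) sd(x) / sqrt(length(x)) else 0
    data.frame(metric = m, mean = mu,
               ci_low = mu - 1.96 * se, ci_high = mu + 1.96 * se)
  }))
}

# ---- replicate driver -------------------------------------------------------

#' Run the full multi-replicate experiment
#'
#' For each replicate: draw a fresh train/val/test split, fit the two CBOW
#' models on that replicate's training portion only, embed and assemble the
#' graphs, train the classifier, and score the held-out test set. Failures in
#' individual replicates are recorded and the summary is computed over
#' completed replicates only.
#'
#' @param records duplex records data.frame.
#' @param config a `classifier_config`.
#' @param tconf a `train_config` (its `seed` is combined with the replicate
#'   index).
#' @param spec a `split_spec`.
#' @param embed_opts list of [train_cbow()] hyperparameters
#'   (dimension/window/epochs/negative/min_count).
#' @param keep_predictions keep per-replicate test predictions.
#' @param verbose print progress to stderr.
#' @return list with `replicates` (data.frame: replicate, bacc, precision,
#'   recall, best_epoch, error), `summary` (from [summarize_replicates()]),
#'   and optionally `predictions` (list of data.frames).
#' @export
run_replicates <- function(records, config, tconf, spec,
                           embed_opts = list(), keep_predictions = FALSE,
                           verbose = FALSE) {
  eo <- modifyList(list(dimension = 16L, window = 5L, epochs = 100L,
                        negative = 5L, min_count = 1L), embed_opts)
  rows <- vector("list", spec$n_replicates)
  preds <- if (keep_predictions) vector("list", spec$n_replicates)
  for (r in seq_len(spec$n_replicates) - 1L) {
    res <- tryCatch({
      rec <- split_dataset(records, spec, r)
      tables <- fit_embeddings(rec, dimension = eo$dimension,
                               window = eo$window, epochs = eo$epochs,
                               negative = eo$negative,
                               min_count = eo$min_count,
                               seed = spec$base_seed + 2L * r)
      ds <- lapply(c(train = "train", val = "val", test = "test"),
                   function(tg) build_graph_dataset(
                     rec[rec$split == tg, , drop = FALSE], tables))
      tc <- tconf
      tc$seed <- tconf$seed + r
      fit <- train_model(ds$train, ds$val, config, tc, verbose = verbose)
      probs <- predict_graphs(ds$test$graphs, fit$params, config)
      pred <- as.integer(probs[, "positive"] > 0.5)
      mr <- compute_metrics(ds$test$labels, pred)
      if (keep_predictions) {
        tst <- rec[rec$split == "test", , drop = FALSE]
        preds[[r + 1L]] <- data.frame(
          mirna_id = tst$mirna_id, site_id = tst$site_id,
          probability_positive = probs[, "positive"],
          predicted_label = pred, label = tst$label)
      }
      data.frame(replicate = r, balanced_accuracy = mr$balanced_accuracy,
                 precision = mr$precision, recall = mr$recall,
                 best_epoch = fit$best_epoch, error = NA_character_)
    }, error = function(e) {
      warning(sprintf("replicate %d failed: %s", r, conditionMessage(e)))
      data.frame(replicate = r, balanced_accuracy = NA_real_,
                 precision = NA_real_, recall = NA_real_,
                 best_epoch = NA_integer_, error = conditionMessage(e))
    })
    rows[[r + 1L]] <- res
    if (verbose)
      message(sprintf("replicate %d: BACC %.4f", r, res$balanced_accuracy))
  }
  replicates <- do.call(rbind, rows)
  done <- replicates[is.na(replicates$error), , drop = FALSE]
  out <- list(replicates = replicates, summary = summarize_replicates(done))
  if (keep_predictions) out$predictions <- preds
  out
}
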