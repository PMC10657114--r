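# Classifier assembly: L_GNN node-embedding layers of one family, a global
# pooling readout, and a fully connected softmax head with dropout after
# every but the last FC layer.

#' Classifier configuration
#'
#' Houses the architecture hyperparameters: the node-embedding family
#' `e_gnn`, the number and width of GNN layers (`l_gnn`, `d_gnn`), the number
#' and width of fully connected layers (`l_fc`, `d_fc`; the last FC layer
#' always maps to 2 outputs), the pooling readout `pool`, the dropout rate
#' `dropout` applied after every but the last FC layer, and the node-feature
#' input dimension (16, the embedding dimensionality).
#'
#' @param e_gnn one of `"GCN"`, `"GAT"`, `"SAGE"`.
#' @param l_gnn,d_gnn number and output width of GNN layers (>= 1).
#' @param l_fc,d_fc number of FC layers (>= 1) and hidden width.
#' @param pool readout: `"ADD"`, `"MEAN"` or `"MAX"`.
#' @param dropout dropout rate in [0, 1).
#' @param input_dim node feature dimension (default 16).
#' @return A `classifier_config`.
#' @export
classifier_config <- function(e_gnn = c("GCN", "GAT", "SAGE"),
                              l_gnn = 2L, d_gnn = 32L,
                              l_fc = 2L, d_fc = 32L,
                              pool = c("ADD", "MEAN", "MAX"),
                              dropout = 0.4, input_dim = 16L) {
  e_gnn <- match.arg(toupper(e_gnn[1]), c("GCN", "GAT", "SAGE"))
  pool <- match.arg(toupper(pool[1]), c("ADD", "MEAN", "MAX"))
  stopifnot(l_gnn >= 1, d_gnn >= 1, l_fc >= 1, d_fc >= 1, input_dim >= 1)
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(e_gnn = e_gnn, l_gnn = as.integer(l_gnn),
                 d_gnn = as.integer(d_gnn), l_fc = as.integer(l_fc),
                 d_fc = as.integer(d_fc), pool = pool, dropout = dropout,
                 input_dim = as.integer(input_dim)),
            class = "classifier_config")
}

#' Tuned architecture for a node-embedding family
#'
#' The per-family architectures selected by grid search on a single
#' MirTarRAW split: GCN 3 layers x 128, 2 FC x 512, MAX readout; GAT 5 x
#' 256, 2 FC x 128, ADD; GraphSAGE 5 x 256, 3 FC x 256, ADD; dropout 0.4
#' throughout.
#'
#' @param e_gnn `"GCN"`, `"GAT"` or `"SAGE"`.
#' @return A `classifier_config`.
#' @export
optimal_config <- function(e_gnn = c("GCN", "GAT", "SAGE")) {
  e_gnn <- match.arg(toupper(e_gnn[1]), c("GCN", "GAT", "SAGE"))
  switch(e_gnn,
    GCN = classifier_config("GCN", 3, 128, 2, 512, "MAX", 0.4),
    GAT = classifier_config("GAT", 5, 256, 2, 128, "ADD", 0.4),
    SAGE = classifier_config("SAGE", 5, 256, 3, 256, "ADD", 0.4))
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize trainable parameters for a classifier configuration
#'
#' Glorot-uniform weight matrices (and attention vectors for the attention
#' family); FC biases start at zero. Layer 1 maps `input_dim -> d_gnn`,
#' layers 2..`l_gnn` map `d_gnn -> d_gnn`; the FC stack maps
#' `d_gnn -> d_fc (x l_fc - 1) -> 2`.
#'
#' @param config a `classifier_config`.
#' @param seed integer seed.
#' @return A `model_parameters` list with elements `gnn` and `fc`.
#' @export
init_parameters <- function(config, seed = 1L) {
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(seed)
  gnn <- vector("list", config$l_gnn)
  for (l in seq_len(config$l_gnn)) {
    fi <- if (l == 1L) config$input_dim else config$d_gnn
    fo <- config$d_gnn
    gnn[[l]] <- switch(config$e_gnn,
      GCN = list(W = glorot(fi, fo)),
      SAGE = list(W = glorot(2L * fi, fo)),
      GAT = list(W = glorot(fi, fo), a = as.vector(glorot(2L * fo, 1L))))
  }
  fc <- vector("list", config$l_fc)
  for (l in seq_len(config$l_fc)) {
    fi <- if (l == 1L) config$d_gnn else config$d_fc
    fo <- if (l == config$l_fc) 2L else config$d_fc
    fc[[l]] <- list(W = glorot(fi, fo), b = numeric(fo))
  }
  structure(list(gnn = gnn, fc = fc), class = "model_parameters")
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

check_parameters <- function(params, config) {
  if (length(params$gnn) != config$l_gnn || length(params$fc) != config$l_fc)
    stop("config/params mismatch: layer counts differ")
  for (l in seq_len(config$l_gnn)) {
    fi <- if (l == 1L) config$input_dim else config$d_gnn
    exp_rows <- if (config$e_gnn == "SAGE") 2L * fi else fi
    W <- params$gnn[[l]]$W
    if (nrow(W) != exp_rows || ncol(W) != config$d_gnn)
      stop(sprintf("config/params mismatch at GNN layer %d: W is %dx%d, expected %dx%d",
                   l, nrow(W), ncol(W), exp_rows, config$d_gnn))
    if (config$e_gnn == "GAT" && length(params$gnn[[l]]$a) != 2L * config$d_gnn)
      stop(sprintf("config/params mismatch at GAT layer %d: attention vector length", l))
  }
  for (l in seq_len(config$l_fc)) {
    fi <- if (l == 1L) config$d_gnn else config$d_fc
    fo <- if (l == config$l_fc) 2L else config$d_fc
    W <- params$fc[[l]]$W
    if (nrow(W) != fi || ncol(W) != fo)
      stop(sprintf("config/params mismatch at FC layer %d", l))
  }
  invisible(TRUE)
}

# ---- batched engine ---------------------------------------------------------

# structure precomputation shared by all layers of a batch
batch_structure <- function(batch, e_gnn) {
  switch(e_gnn,
    GCN = list(Ahat = gcn_adjacency(batch$V, batch$edges)),
    SAGE = list(Abar = sage_aggregator(batch$V, batch$edges)),
    GAT = list(arcs = gat_arcs(batch$V, batch$edges)))
}

engine_forward <- function(batch, params, config, training = FALSE) {
  st <- batch_structure(batch, config$e_gnn)
  H <- batch$X
  caches <- vector("list", config$l_gnn)
  for (l in seq_len(config$l_gnn)) {
    p <- params$gnn[[l]]
    fw <- switch(config$e_gnn,
      GCN = gcn_forward(H, st$Ahat, p$W),
      SAGE = sage_forward(H, st$Abar, p$W),
      GAT = gat_forward(H, st$arcs, p$W, p$a))
    H <- fw$out
    caches[[l]] <- fw$cache
  }
  pf <- pool_forward(H, batch$gid, batch$n_graphs, config$pool)
  X <- pf$G
  fc_caches <- vector("list", config$l_fc)
  for (l in seq_len(config$l_fc)) {
    p <- params$fc[[l]]
    A <- sweep(X %*% p$W, 2, p$b, "+")
    if (l < config$l_fc) {
      R <- relu(A)
      if (training && config$dropout > 0) {
        keep <- matrix(runif(length(R)) >= config$dropout, nrow(R), ncol(R))
        Xn <- R * keep / (1 - config$dropout)
      } else {
        keep <- NULL
        Xn <- R
      }
      fc_caches[[l]] <- list(X = X, mask = A > 0, keep = keep, W = p$W)
      X <- Xn
    } else {
      fc_caches[[l]] <- list(X = X, W = p$W)
      X <- A
    }
  }
  logits <- X
  mx <- apply(logits, 1, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  logp <- logits - lse
  list(probs = exp(logp), logp = logp, caches = caches,
       fc_caches = fc_caches, pool_cache = pf$cache)
}

# cross-entropy loss and full gradient for one batch
engine_loss_grad <- function(batch, labels, params, config, training = FALSE,
                             want_grad = TRUE) {
  fw <- engine_forward(batch, params, config, training = training)
  B <- batch$n_graphs
  yi <- cbind(seq_len(B), labels + 1L)
  loss <- -mean(fw$logp[yi])
  if (!want_grad) return(list(loss = loss, probs = fw$probs))
  Y <- matrix(0, B, 2)
  Y[yi] <- 1
  dX <- (fw$probs - Y) / B
  gfc <- vector("list", config$l_fc)
  for (l in rev(seq_len(config$l_fc))) {
    cc <- fw$fc_caches[[l]]
    if (l < config$l_fc) {
      if (!is.null(cc$keep)) dX <- dX * cc$keep / (1 - config$dropout)
      dX <- dX * cc$mask
    }
    gfc[[l]] <- list(W = crossprod(cc$X, dX), b = colSums(dX))
    dX <- tcrossprod(dX, cc$W)
  }
  dHn <- pool_backward(dX, fw$pool_cache)
  ggnn <- vector("list", config$l_gnn)
  for (l in rev(seq_len(config$l_gnn))) {
    bw <- switch(config$e_gnn,
      GCN = gcn_backward(dHn, fw$caches[[l]]),
      SAGE = sage_backward(dHn, fw$caches[[l]]),
      GAT = gat_backward(dHn, fw$caches[[l]]))
    ggnn[[l]] <- if (config$e_gnn == "GAT") list(W = bw$dW, a = bw$da)
                 else list(W = bw$dW)
    dHn <- bw$dH
  }
  list(loss = loss, probs = fw$probs, grads = list(gnn = ggnn, fc = gfc))
}

#' Run the classifier on one duplex graph
#'
#' Applies the configured GNN layers, the pooling readout and the fully
#' connected softmax head to a single graph. In `"TRAIN"` mode dropout is
#' active (stochastic); in `"EVAL"` mode the forward pass is deterministic.
#'
#' @param graph a `duplex_graph`.
#' @param params `model_parameters` matching `config`.
#' @param config a `classifier_config`.
#' @param mode `"EVAL"` (default) or `"TRAIN"`.
#' @return Named probability vector `c(negative=, positive=)` summing to 1.
#' @export
forward <- function(graph, params, config, mode = c("EVAL", "TRAIN")) {
  mode <- match.arg(mode)
  check_parameters(params, config)
  if (ncol(graph$node_features) != config$input_dim)
    stop("graph feature dimension does not match config$input_dim")
  batch <- collate_graphs(list(graph))
  fw <- engine_forward(batch, params, config, training = mode == "TRAIN")
  p <- as.vector(fw$probs[1, ])
  names(p) <- c("negative", "positive")
  p
}

#' Predict class probabilities for a list of duplex graphs
#'
#' @param graphs list of `duplex_graph` objects.
#' @param params,config trained parameters and their configuration.
#' @param batch_size graphs per forward batch (default 256).
#' @return numeric matrix `length(graphs) x 2` with columns
#'   `negative`, `positive`.
#' @export
predict_graphs <- function(graphs, params, config, batch_size = 256L) {
  check_parameters(params, config)
  n <- length(graphs)
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("negative", "positive")))
  for (s in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    b <- collate_graphs(graphs[s])
    out[s, ] <- engine_forward(b, params, config, training = FALSE)$probs
  }
  out
}

#' Report per-layer parameter shapes
#'
#' Inspection helper used to verify that an instantiated model has exactly
#' the layer counts and widths its configuration demands.
#'
#' @param params `model_parameters`.
#' @return data.frame with columns `block`, `layer`, `tensor`, `rows`, `cols`.
#' @export
parameter_shapes <- function(params) {
  rows <- list()
  for (l in seq_along(params$gnn)) {
    p <- params$gnn[[l]]
    rows[[length(rows) + 1]] <- data.frame(block = "gnn", layer = l,
      tensor = "W", rows = nrow(p$W), cols = ncol(p$W))
    if (!is.null(p$a))
      rows[[length(rows) + 1]] <- data.frame(block = "gnn", layer = l,
        tensor = "a", rows = length(p$a), cols = 1L)
  }
  for (l in seq_along(params$fc)) {
    p <- params$fc[[l]]
    rows[[length(rows) + 1]] <- data.frame(block = "fc", layer = l,
      tensor = "W", rows = nrow(p$W), cols = ncol(p$W))
    rows[[length(rows) + 1]] <- data.frame(block = "fc", layer = l,
      tensor = "b", rows = length(p$b), cols = 1L)
  }
  do.call(rbind, rows)
}
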