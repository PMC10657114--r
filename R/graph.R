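# Duplex graph construction: nodes are embedded triplet words of the two
# sequences; edges chain consecutive words within each sequence and pair
# index-aligned words across sequences (sequences aligned at their first
# word, one cross edge per aligned position).

#' Build the miRNA-mRNA duplex graph
#'
#' Stacks the embedded word vectors of the two sequences as node features and
#' connects (i) consecutive words within each sequence and (ii) word i of the
#' miRNA with word i of the target site for every aligned position
#' `i < min(n, m)`. Edges are stored undirected (each unordered pair once)
#' and expanded to both directed arcs inside the message-passing layers.
#' For n miRNA words and m site words the graph has `n + m` nodes and
#' `(n-1) + (m-1) + min(n, m)` edges, is connected, and has maximum degree 3.
#'
#' @param mirna_rows numeric matrix `n x F` of embedded miRNA words.
#' @param mrna_rows numeric matrix `m x F` of embedded target-site words.
#' @return A `duplex_graph`: list with `node_features` (`(n+m) x F`; miRNA
#'   nodes first), `edges` (two-column integer matrix of unordered pairs,
#'   1-based), `node_origin` (`"MIRNA"`/`"MRNA"` per node), `node_position`
#'   (0-based word index within its sequence), `n_mirna`, `n_mrna`.
#' @export
build_duplex_graph <- function(mirna_rows, mrna_rows) {
  if (is.vector(mirna_rows)) mirna_rows <- matrix(mirna_rows, nrow = 1)
  if (is.vector(mrna_rows)) mrna_rows <- matrix(mrna_rows, nrow = 1)
  n <- nrow(mirna_rows); m <- nrow(mrna_rows)
  if (n < 1L || m < 1L) stop("both sequences must contribute at least one word")
  if (ncol(mirna_rows) != ncol(mrna_rows))
    stop(sprintf("feature dimension mismatch: %d vs %d",
                 ncol(mirna_rows), ncol(mrna_rows)))
  chain <- function(k, off) if (k > 1L) cbind(off + 1:(k - 1L), off + 2:k)
  k <- min(n, m)
  edges <- rbind(chain(n, 0L), chain(m, n),
                 cbind(seq_len(k), n + seq_len(k)))
  storage.mode(edges) <- "integer"
  structure(list(
    node_features = rbind(mirna_rows, mrna_rows),
    edges = edges,
    node_origin = rep(c("MIRNA", "MRNA"), c(n, m)),
    node_position = c(seq_len(n), seq_len(m)) - 1L,
    n_mirna = n, n_mrna = m
  ), class = "duplex_graph")
}

#' @export
print.duplex_graph <- function(x, ...) {
  cat(sprintf("<duplex_graph %d+%d nodes, %d undirected edges, F=%d>\n",
              x$n_mirna, x$n_mrna, nrow(x$edges), ncol(x$node_features)))
  invisible(x)
}

#' Dump a duplex graph as plain-text files
#'
#' Writes `<prefix>_edges.tsv` (columns `from`, `to`, 1-based) and
#' `<prefix>_nodes.tsv` (origin, position and the feature columns), for
#' inspection and golden tests.
#'
#' @param graph a `duplex_graph`.
#' @param prefix output path prefix.
#' @return The two paths, invisibly.
#' @export
write_graph_files <- function(graph, prefix) {
  ep <- paste0(prefix, "_edges.tsv")
  np <- paste0(prefix, "_nodes.tsv")
  write.table(data.frame(from = graph$edges[, 1], to = graph$edges[, 2]),
              ep, sep = "\t", quote = FALSE, row.names = FALSE)
  nf <- as.data.frame(signif(graph$node_features, 6))
  names(nf) <- paste0("f", seq_len(ncol(nf)))
  write.table(cbind(data.frame(origin = graph$node_origin,
                               position = graph$node_position), nf),
              np, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(ep, np))
}

# ---- batching -------------------------------------------------------------
# Graphs in a batch are merged into one block-diagonal graph; per-graph
# readout is recovered through the node->graph index map.

collate_graphs <- function(graphs) {
  Vs <- vapply(graphs, function(g) nrow(g$node_features), integer(1))
  offs <- cumsum(c(0L, Vs[-length(Vs)]))
  X <- do.call(rbind, lapply(graphs, `[[`, "node_features"))
  edges <- do.call(rbind, Map(function(g, o) g$edges + o, graphs, offs))
  list(X = X, edges = edges, gid = rep(seq_along(graphs), Vs),
       V = sum(Vs), n_graphs = length(graphs), sizes = Vs)
}

# normalized adjacency with self-loops for the spectral layer:
# D^{-1/2} (A + I) D^{-1/2}
gcn_adjacency <- function(V, edges) {
  i <- c(edges[, 1], edges[, 2], seq_len(V))
  j <- c(edges[, 2], edges[, 1], seq_len(V))
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(V, V))
  d <- Matrix::rowSums(A)
  s <- 1 / sqrt(d)
  Matrix::Diagonal(x = s) %*% A %*% Matrix::Diagonal(x = s)
}

# row-normalized neighbour mean (self excluded) for sample-and-aggregate;
# isolated nodes get an all-zero row.
sage_aggregator <- function(V, edges) {
  if (is.null(edges) || nrow(edges) == 0L)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(V, V)))
  i <- c(edges[, 1], edges[, 2])
  j <- c(edges[, 2], edges[, 1])
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(V, V))
  d <- Matrix::rowSums(A)
  s <- ifelse(d > 0, 1 / d, 0)
  Matrix::Diagonal(x = s) %*% A
}

# directed arc list with self-loops for attention (v attends over N(v) u {v})
gat_arcs <- function(V, edges) {
  if (is.null(edges) || nrow(edges) == 0L)
    return(list(src = seq_len(V), dst = seq_len(V)))
  list(src = c(edges[, 1], edges[, 2], seq_len(V)),
       dst = c(edges[, 2], edges[, 1], seq_len(V)))
}

# grouped scatter helpers (groups are 1..n integers)
group_sum_mat <- function(X, g, n) {
  out <- matrix(0, n, ncol(X))
  rs <- rowsum(X, group = g, reorder = TRUE)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

group_sum_vec <- function(x, g, n) {
  out <- numeric(n)
  rs <- rowsum(x, group = g, reorder = TRUE)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}

# per-group maximum via ordered assignment (last write wins = maximum);
# also returns the argmax row index when requested.
group_max_vec <- function(x, g, n, want_argmax = FALSE) {
  o <- order(x)
  v <- rep(-Inf, n)
  v[g[o]] <- x[o]
  if (!want_argmax) return(v)
  a <- rep(NA_integer_, n)
  a[g[o]] <- o
  list(max = v, argmax = a)
}
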