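# Independent brute-force oracles and small fixture builders. The oracles
# are written against the stated mathematical definitions, not against the
# package internals, and use only base R dense arithmetic.

identity_act <- function(x) x

# dense spectral-convolution oracle: sigma(D^-1/2 (A+I) D^-1/2 H W)
oracle_gcn <- function(H, edges, W, act = identity_act) {
  V <- nrow(H)
  A <- matrix(0, V, V)
  if (!is.null(edges) && nrow(edges) > 0)
    for (r in seq_len(nrow(edges))) {
      A[edges[r, 1], edges[r, 2]] <- 1
      A[edges[r, 2], edges[r, 1]] <- 1
    }
  At <- A + diag(V)
  Dm <- diag(1 / sqrt(rowSums(At)), V)
  act(Dm %*% At %*% Dm %*% H %*% W)
}

# per-node loop oracle for sample-and-aggregate with mean aggregator:
# sigma(W . [h_v, mean_{u in N(v)} h_u]) then row L2 normalization
oracle_sage <- function(H, edges, W, act = identity_act) {
  V <- nrow(H)
  nbrs <- lapply(seq_len(V), function(v) integer(0))
  if (!is.null(edges) && nrow(edges) > 0)
    for (r in seq_len(nrow(edges))) {
      nbrs[[edges[r, 1]]] <- c(nbrs[[edges[r, 1]]], edges[r, 2])
      nbrs[[edges[r, 2]]] <- c(nbrs[[edges[r, 2]]], edges[r, 1])
    }
  out <- matrix(0, V, ncol(W))
  for (v in seq_len(V)) {
    hn <- if (length(nbrs[[v]]) == 0) numeric(ncol(H))
          else colMeans(H[nbrs[[v]], , drop = FALSE])
    hv <- act(c(H[v, ], hn) %*% W)
    nr <- sqrt(sum(hv^2))
    out[v, ] <- if (nr > 0) hv / nr else hv
  }
  out
}

# exhaustive pairwise attention oracle: materializes every e_vu and alpha_vu
oracle_gat <- function(H, edges, W, a, act = identity_act, slope = 0.2) {
  V <- nrow(H)
  Fo <- ncol(W)
  nbrs <- lapply(seq_len(V), function(v) v)  # self-loop
  if (!is.null(edges) && nrow(edges) > 0)
    for (r in seq_len(nrow(edges))) {
      nbrs[[edges[r, 1]]] <- c(nbrs[[edges[r, 1]]], edges[r, 2])
      nbrs[[edges[r, 2]]] <- c(nbrs[[edges[r, 2]]], edges[r, 1])
    }
  Z <- H %*% W
  leaky <- function(x) ifelse(x > 0, x, slope * x)
  out <- matrix(0, V, Fo)
  for (v in seq_len(V)) {
    e <- vapply(nbrs[[v]], function(u)
      leaky(sum(a * c(Z[v, ], Z[u, ]))), numeric(1))
    al <- exp(e - max(e))
    al <- al / sum(al)
    s <- numeric(Fo)
    for (k in seq_along(nbrs[[v]])) s <- s + al[k] * Z[nbrs[[v]][k], ]
    out[v, ] <- act(s)
  }
  out
}

# independent confusion-matrix recomputation
oracle_metrics <- function(labels, predictions) {
  tab <- table(factor(labels, 0:1), factor(predictions, 0:1))
  tp <- tab["1", "1"]; tn <- tab["0", "0"]
  fp <- tab["0", "1"]; fn <- tab["1", "0"]
  list(bacc = (tp / (tp + fn) + tn / (tn + fp)) / 2,
       precision = tp / (tp + fp), recall = tp / (tp + fn))
}

# random connected-ish test graph: a duplex graph with random sizes, or an
# arbitrary random graph when free = TRUE
random_graph_case <- function(fdim = 5, vmax = 10, free = FALSE) {
  if (free) {
    V <- sample(2:vmax, 1)
    pairs <- t(combn(V, 2))
    keep <- runif(nrow(pairs)) < 0.5
    edges <- pairs[keep, , drop = FALSE]
    H <- matrix(rnorm(V * fdim), V, fdim)
    return(list(H = H, edges = edges, V = V))
  }
  n <- sample(1:(vmax %/% 2), 1)
  m <- sample(1:(vmax %/% 2), 1)
  g <- build_duplex_graph(matrix(rnorm(n * fdim), n, fdim),
                          matrix(rnorm(m * fdim), m, fdim))
  list(H = g$node_features, edges = g$edges, V = n + m, graph = g)
}

random_sequence <- function(len, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# small deterministic record table for io/split tests
toy_records <- function(n = 20, seed = 99) {
  cfg <- simulation_config(n, rng_seed = seed)
  generate_dataset(cfg)
}

# tiny trained setup shared by a few tests
tiny_graph <- function(seed = 7, fdim = 16) {
  set.seed(seed)
  build_duplex_graph(matrix(rnorm(3 * fdim), 3, fdim),
                     matrix(rnorm(4 * fdim), 4, fdim))
}

# connected-component count via BFS (no graph library needed)
igraph_free_components <- function(V, edges) {
  adj <- lapply(seq_len(V), function(v) integer(0))
  if (!is.null(edges) && nrow(edges) > 0)
    for (r in seq_len(nrow(edges))) {
      adj[[edges[r, 1]]] <- c(adj[[edges[r, 1]]], edges[r, 2])
      adj[[edges[r, 2]]] <- c(adj[[edges[r, 2]]], edges[r, 1])
    }
  seen <- logical(V)
  comps <- 0L
  for (s in seq_len(V)) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s; seen[s] <- TRUE
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      new <- adj[[v]][!seen[adj[[v]]]]
      seen[new] <- TRUE
      queue <- c(queue, new)
    }
  }
  comps
}
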