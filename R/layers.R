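# The three node-embedding layer families. Each has an exported functional
# form operating on an explicit (H, edges) pair -- the contract the oracle
# tests exercise -- and internal forward/backward routines sharing the same
# arithmetic, used by the batched training engine.

relu <- function(x) pmax(x, 0)

# ---- spectral convolution (GCN) --------------------------------------------

gcn_forward <- function(H, Ahat, W, act = TRUE) {
  M <- as.matrix(Ahat %*% H)
  S <- M %*% W
  out <- if (act) relu(S) else S
  list(out = out, cache = list(M = M, mask = S > 0, W = W, Ahat = Ahat))
}

gcn_backward <- function(dOut, cache) {
  dS <- dOut * cache$mask
  dW <- crossprod(cache$M, dS)
  dM <- tcrossprod(dS, cache$W)
  dH <- as.matrix(cache$Ahat %*% dM)  # Ahat is symmetric
  list(dH = dH, dW = dW)
}

#' Spectral graph convolution layer
#'
#' One propagation step `sigma(D^{-1/2} (A+I) D^{-1/2} H W)`: the adjacency
#' matrix is augmented with self-loops and symmetrically normalized by the
#' resulting degree matrix before mixing node features and applying the
#' trainable weight matrix.
#'
#' @param H numeric matrix `V x F_in` of node features.
#' @param edges two-column integer matrix of undirected edges (1-based); may
#'   have zero rows.
#' @param W numeric weight matrix `F_in x F_out`.
#' @param activation elementwise activation function (default ReLU).
#' @return numeric matrix `V x F_out`.
#' @export
gcn_layer <- function(H, edges, W, activation = relu) {
  if (ncol(H) != nrow(W))
    stop(sprintf("shape mismatch: H has %d columns, W has %d rows",
                 ncol(H), nrow(W)))
  check_edges(edges, nrow(H))
  Ahat <- gcn_adjacency(nrow(H), edges)
  activation(gcn_forward(H, Ahat, W, act = FALSE)$out)
}

# ---- sample-and-aggregate (GraphSAGE) --------------------------------------

sage_forward <- function(H, Abar, W, act = TRUE) {
  N <- as.matrix(Abar %*% H)
  C <- cbind(H, N)
  P <- C %*% W
  Q <- if (act) relu(P) else P
  rn <- sqrt(rowSums(Q * Q))
  nz <- rn > 0
  rs <- ifelse(nz, rn, 1)
  out <- Q / rs
  list(out = out,
       cache = list(C = C, Q = Q, rn = rs, nz = nz, mask = P > 0,
                    W = W, Abar = Abar, F_in = ncol(H)))
}

sage_backward <- function(dOut, cache) {
  Q <- cache$Q; rn <- cache$rn
  dQ <- (dOut / rn - Q * (rowSums(dOut * Q) / rn^3)) * cache$nz
  dP <- dQ * cache$mask
  dW <- crossprod(cache$C, dP)
  dC <- tcrossprod(dP, cache$W)
  Fi <- cache$F_in
  dH <- dC[, seq_len(Fi), drop = FALSE] +
    as.matrix(Matrix::t(cache$Abar) %*% dC[, Fi + seq_len(Fi), drop = FALSE])
  list(dH = dH, dW = dW)
}

#' Sample-and-aggregate layer (GraphSAGE, mean aggregator)
#'
#' For each node v: the element-wise mean of its neighbours' features (self
#' excluded; isolated nodes aggregate to the zero vector) is concatenated
#' with v's own features, multiplied by the shared weight matrix, passed
#' through the activation, and finally L2-normalized to unit length
#' (all-zero rows stay zero). Full neighbourhoods are always used: duplex
#' graphs have maximum degree 3, so neighbour sampling is unnecessary.
#'
#' @param H numeric matrix `V x F_in`.
#' @param edges two-column undirected edge matrix.
#' @param W numeric weight matrix `(2*F_in) x F_out`.
#' @param aggregator only `"MEAN"` is implemented.
#' @param activation elementwise activation (default ReLU).
#' @return numeric matrix `V x F_out`; every non-zero row has unit L2 norm.
#' @export
sage_layer <- function(H, edges, W, aggregator = "MEAN", activation = relu) {
  match.arg(aggregator, "MEAN")
  if (nrow(W) != 2L * ncol(H))
    stop(sprintf("shape mismatch: W must have 2*F_in = %d rows, has %d",
                 2L * ncol(H), nrow(W)))
  check_edges(edges, nrow(H))
  Abar <- sage_aggregator(nrow(H), edges)
  fw <- sage_forward(H, Abar, W, act = FALSE)
  Q <- activation(fw$cache$Q)
  rn <- sqrt(rowSums(Q * Q))
  Q / ifelse(rn > 0, rn, 1)
}

# ---- attention (GAT, single head) ------------------------------------------

gat_forward <- function(H, arcs, W, a, act = TRUE, slope = 0.2) {
  V <- nrow(H)
  Fo <- ncol(W)
  Z <- H %*% W
  a1 <- a[seq_len(Fo)]            # scores the target (attending) node
  a2 <- a[Fo + seq_len(Fo)]       # scores the source (attended) node
  qd <- as.vector(Z %*% a1)
  qs <- as.vector(Z %*% a2)
  src <- arcs$src; dst <- arcs$dst
  epre <- qd[dst] + qs[src]
  e <- ifelse(epre > 0, epre, slope * epre)
  mx <- group_max_vec(e, dst, V)
  ex <- exp(e - mx[dst])
  den <- group_sum_vec(ex, dst, V)
  alpha <- ex / den[dst]
  S <- group_sum_mat(alpha * Z[src, , drop = FALSE], dst, V)
  out <- if (act) relu(S) else S
  list(out = out,
       cache = list(H = H, Z = Z, W = W, a1 = a1, a2 = a2, epre = epre,
                    alpha = alpha, src = src, dst = dst, V = V,
                    mask = S > 0, slope = slope),
       alpha = alpha)
}

gat_backward <- function(dOut, cache) {
  with(cache, {
    dS <- dOut * mask
    dalpha <- rowSums(dS[dst, , drop = FALSE] * Z[src, , drop = FALSE])
    dZ <- group_sum_mat(alpha * dS[dst, , drop = FALSE], src, V)
    tsum <- group_sum_vec(alpha * dalpha, dst, V)
    de <- alpha * (dalpha - tsum[dst])
    depre <- de * ifelse(epre > 0, 1, slope)
    gd <- group_sum_vec(depre, dst, V)
    gs <- group_sum_vec(depre, src, V)
    dZ <- dZ + outer(gd, a1) + outer(gs, a2)
    da <- c(as.vector(crossprod(Z, gd)), as.vector(crossprod(Z, gs)))
    dW <- crossprod(H, dZ)
    dH <- tcrossprod(dZ, W)
    list(dH = dH, dW = dW, da = da)
  })
}

#' Graph attention layer (single head)
#'
#' Computes attention logits `e_vu = LeakyReLU(a . [W h_v, W h_u])` for every
#' neighbour u of v (self-loops are added, so v attends over itself too),
#' normalizes them with a softmax over each neighbourhood, and outputs
#' `sigma(sum_u alpha_vu W h_u)`. The LeakyReLU negative slope is 0.2.
#'
#' @param H numeric matrix `V x F_in`.
#' @param edges two-column undirected edge matrix.
#' @param W numeric weight matrix `F_in x F_out`.
#' @param a attention vector of length `2 * F_out` (target part first).
#' @param activation elementwise activation (default ReLU).
#' @param return_attention if `TRUE`, also return the per-arc attention
#'   coefficients (columns `src`, `dst`, `alpha`).
#' @return numeric matrix `V x F_out`, or a list `(out, attention)` when
#'   `return_attention` is `TRUE`.
#' @export
gat_layer <- function(H, edges, W, a, activation = relu,
                      return_attention = FALSE) {
  if (ncol(H) != nrow(W))
    stop(sprintf("shape mismatch: H has %d columns, W has %d rows",
                 ncol(H), nrow(W)))
  if (length(a) != 2L * ncol(W))
    stop(sprintf("attention vector must have length 2*F_out = %d, has %d",
                 2L * ncol(W), length(a)))
  check_edges(edges, nrow(H))
  arcs <- gat_arcs(nrow(H), edges)
  fw <- gat_forward(H, arcs, W, a, act = FALSE)
  out <- activation(fw$out)
  if (!return_attention) return(out)
  list(out = out,
       attention = data.frame(src = arcs$src, dst = arcs$dst,
                              alpha = fw$alpha))
}

check_edges <- function(edges, V) {
  if (is.null(edges) || nrow(edges) == 0L) return(invisible(TRUE))
  if (ncol(edges) != 2L) stop("edges must be a two-column matrix")
  if (any(edges < 1L) || any(edges > V))
    stop("edge endpoint out of node range")
  invisible(TRUE)
}

# ---- readout ---------------------------------------------------------------

#' Global pooling readout
#'
#' Collapses the node-embedding matrix into a single graph vector by
#' element-wise sum, mean, or maximum over nodes.
#'
#' @param node_embeddings numeric matrix `V x D`, `V >= 1`.
#' @param P_h one of `"ADD"`, `"MEAN"`, `"MAX"`.
#' @return numeric vector of length `D`.
#' @export
global_pool <- function(node_embeddings, P_h = c("ADD", "MEAN", "MAX")) {
  P_h <- match.arg(P_h)
  if (is.vector(node_embeddings))
    node_embeddings <- matrix(node_embeddings, nrow = 1)
  if (nrow(node_embeddings) == 0L) stop("cannot pool an empty graph")
  switch(P_h,
         ADD = colSums(node_embeddings),
         MEAN = colMeans(node_embeddings),
         MAX = apply(node_embeddings, 2, max))
}

# batched pooling over the block-diagonal graph
pool_forward <- function(Hn, gid, B, P_h) {
  if (P_h == "ADD") {
    G <- group_sum_mat(Hn, gid, B)
    return(list(G = G, cache = list(type = "ADD", gid = gid)))
  }
  if (P_h == "MEAN") {
    cnt <- tabulate(gid, B)
    G <- group_sum_mat(Hn, gid, B) / cnt
    return(list(G = G, cache = list(type = "MEAN", gid = gid, cnt = cnt)))
  }
  D <- ncol(Hn)
  G <- matrix(0, B, D)
  AM <- matrix(NA_integer_, B, D)
  for (j in seq_len(D)) {
    gm <- group_max_vec(Hn[, j], gid, B, want_argmax = TRUE)
    G[, j] <- gm$max
    AM[, j] <- gm$argmax
  }
  list(G = G, cache = list(type = "MAX", gid = gid, argmax = AM, V = nrow(Hn)))
}

pool_backward <- function(dG, cache) {
  if (cache$type == "ADD") return(dG[cache$gid, , drop = FALSE])
  if (cache$type == "MEAN") return((dG / cache$cnt)[cache$gid, , drop = FALSE])
  dHn <- matrix(0, cache$V, ncol(dG))
  for (j in seq_len(ncol(dG))) {
    idx <- cache$argmax[, j]
    dHn[idx, j] <- dHn[idx, j] + dG[, j]
  }
  dHn
}
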