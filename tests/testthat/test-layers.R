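test_that("gcn_layer: identity case, symmetry, and dense oracle on a path graph", {
  # single node, no edges, identity weights and activation -> input unchanged
  H1 <- matrix(rnorm(3), 1, 3)
  expect_equal(gcn_layer(H1, matrix(0L, 0, 2), diag(3), identity_act), H1)

  # 3-node path graph vs independent dense computation
  set.seed(11)
  H <- matrix(rnorm(9), 3, 3)
  W <- matrix(rnorm(6), 3, 2)
  edges <- rbind(c(1, 2), c(2, 3))
  expect_equal(gcn_layer(H, edges, W, identity_act),
               oracle_gcn(H, edges, W), tolerance = 1e-10)

  # automorphic nodes with identical features get identical rows
  Hs <- matrix(rep(c(1, 2, 0.5), each = 3), 3, 3)
  out <- gcn_layer(Hs, edges, matrix(rnorm(9), 3, 3))
  expect_equal(out[1, ], out[3, ], tolerance = 1e-12)

  expect_error(gcn_layer(H, edges, matrix(0, 4, 2)), "shape mismatch")
})

test_that("sage_layer: unit norms, single-neighbour case, star-graph oracle", {
  set.seed(12)
  # star graph: centre 1 connected to 2,3,4
  H <- matrix(rnorm(16), 4, 4)
  W <- matrix(rnorm(8 * 3), 8, 3)
  edges <- rbind(c(1, 2), c(1, 3), c(1, 4))
  out <- sage_layer(H, edges, W)
  norms <- sqrt(rowSums(out^2))
  expect_true(all(abs(norms[norms > 0] - 1) < 1e-12))
  expect_equal(out, oracle_sage(H, edges, W, relu <- function(x) pmax(x, 0)),
               tolerance = 1e-10)

  # a node whose single neighbour carries identical features:
  # pre-normalization output equals sigma(W . [h, h])
  h <- rnorm(4)
  H2 <- rbind(h, h)
  pre <- pmax(c(h, h) %*% W, 0)
  got <- sage_layer(H2, rbind(c(1, 2)), W)
  expect_equal(as.vector(got[1, ]),
               as.vector(pre / sqrt(sum(pre^2))), tolerance = 1e-10)

  expect_error(sage_layer(H, edges, matrix(0, 5, 3)), "2\\*F_in")
})

test_that("gat_layer: attention rows sum to 1, uniform case, triangle oracle", {
  set.seed(13)
  H <- matrix(rnorm(12), 3, 4)
  W <- matrix(rnorm(8), 4, 2)
  a <- rnorm(4)
  edges <- rbind(c(1, 2), c(2, 3), c(1, 3))  # triangle
  res <- gat_layer(H, edges, W, a, return_attention = TRUE)
  sums <- tapply(res$attention$alpha, res$attention$dst, sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_equal(res$out, oracle_gat(H, edges, W, a, function(x) pmax(x, 0)),
               tolerance = 1e-10)

  # identical features everywhere -> uniform attention 1/|N(v)|
  Hu <- matrix(rep(rnorm(4), each = 3), 3, 4)
  ru <- gat_layer(Hu, edges, W, a, return_attention = TRUE)
  expect_true(all(abs(ru$attention$alpha - 1 / 3) < 1e-9))

  expect_error(gat_layer(H, edges, W, rnorm(3)), "2\\*F_out")
})

test_that("all three families match their brute-force oracles on 100 random graphs", {
  set.seed(14)
  for (i in 1:100) {
    cs <- random_graph_case(fdim = 5, vmax = 10, free = TRUE)
    W <- matrix(rnorm(5 * 4), 5, 4)
    Ws <- matrix(rnorm(10 * 4), 10, 4)
    a <- rnorm(8)
    act <- if (i %% 2 == 0) identity_act else function(x) pmax(x, 0)
    expect_equal(gcn_layer(cs$H, cs$edges, W, act),
                 oracle_gcn(cs$H, cs$edges, W, act), tolerance = 1e-5)
    expect_equal(sage_layer(cs$H, cs$edges, Ws, activation = act),
                 oracle_sage(cs$H, cs$edges, Ws, act), tolerance = 1e-5)
    expect_equal(gat_layer(cs$H, cs$edges, W, a, activation = act),
                 oracle_gat(cs$H, cs$edges, W, a, act), tolerance = 1e-5)
  }
})

test_that("global_pool arithmetic and ADD = MEAN * V", {
  M <- rbind(c(1, 2), c(3, 4))
  expect_equal(global_pool(M, "ADD"), c(4, 6))
  expect_equal(global_pool(M, "MEAN"), c(2, 3))
  expect_equal(global_pool(M, "MAX"), c(3, 4))
  expect_error(global_pool(matrix(0, 0, 2), "ADD"), "empty")
  set.seed(15)
  for (i in 1:20) {
    V <- sample(1:12, 1)
    M <- matrix(rnorm(V * 3), V, 3)
    expect_equal(global_pool(M, "ADD"), global_pool(M, "MEAN") * V,
                 tolerance = 1e-12)
  }
})
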