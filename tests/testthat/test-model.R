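test_that("forward returns a softmax pair and is deterministic in EVAL mode", {
  g <- tiny_graph()
  set.seed(20)
  for (fam in c("GCN", "GAT", "SAGE")) for (ph in c("ADD", "MEAN", "MAX")) {
    cc <- classifier_config(fam, 2, 6, 2, 5, ph, 0.4)
    pp <- init_parameters(cc, 8)
    p1 <- forward(g, pp, cc, mode = "EVAL")
    expect_equal(sum(p1), 1, tolerance = 1e-6)
    expect_true(all(p1 >= 0))
    p2 <- forward(g, pp, cc, mode = "EVAL")
    expect_identical(p1, p2)  # dropout off: bit-identical
  }
})

test_that("softmax conservation holds for 1,000 random inputs", {
  cc <- classifier_config("GCN", 1, 4, 1, 4, "MEAN", 0)
  pp <- init_parameters(cc, 2)
  set.seed(21)
  for (i in 1:1000) {
    g <- build_duplex_graph(matrix(rnorm(16), 1, 16), matrix(rnorm(16), 1, 16))
    expect_equal(sum(forward(g, pp, cc)), 1, tolerance = 1e-6)
  }
})

test_that("tuned configurations instantiate with the specified shapes", {
  # attention model: exactly 5 attention layers and 2 FC layers
  cc <- optimal_config("GAT")
  expect_equal(cc[c("l_gnn", "d_gnn", "l_fc", "d_fc", "pool", "dropout")],
               list(l_gnn = 5L, d_gnn = 256L, l_fc = 2L, d_fc = 128L,
                    pool = "ADD", dropout = 0.4))
  pp <- init_parameters(cc, 1)
  expect_length(pp$gnn, 5)
  expect_length(pp$fc, 2)
  expect_true(all(vapply(pp$gnn, function(l) !is.null(l$a), TRUE)))
  sh <- parameter_shapes(pp)
  gW <- sh[sh$block == "gnn" & sh$tensor == "W", ]
  expect_equal(gW$rows, c(16L, rep(256L, 4)))
  expect_equal(gW$cols, rep(256L, 5))
  expect_equal(sh[sh$block == "fc" & sh$tensor == "W", "rows"], c(256L, 128L))
  expect_equal(sh[sh$block == "fc" & sh$tensor == "W", "cols"], c(128L, 2L))
})

test_that("parameter/config mismatches are rejected", {
  g <- tiny_graph()
  cc <- classifier_config("GCN", 2, 6, 2, 5, "ADD", 0)
  pp <- init_parameters(cc, 8)
  cc2 <- classifier_config("GCN", 3, 6, 2, 5, "ADD", 0)
  expect_error(forward(g, pp, cc2), "mismatch")
  pp$gnn[[1]]$W <- matrix(0, 16, 7)
  expect_error(forward(g, pp, cc), "mismatch")
})

test_that("forward is invariant to node permutation for all families and poolings", {
  set.seed(22)
  g <- tiny_graph(seed = 23)
  V <- nrow(g$node_features)
  perm <- sample(V)
  gp <- g
  gp$node_features <- g$node_features[perm, ]
  inv <- order(perm)
  gp$edges <- matrix(inv[g$edges], ncol = 2)
  gp$node_origin <- g$node_origin[perm]
  gp$node_position <- g$node_position[perm]
  for (fam in c("GCN", "GAT", "SAGE")) for (ph in c("ADD", "MEAN", "MAX")) {
    cc <- classifier_config(fam, 2, 6, 2, 5, ph, 0)
    pp <- init_parameters(cc, 9)
    expect_equal(forward(g, pp, cc), forward(gp, pp, cc), tolerance = 1e-6)
  }
})

test_that("analytic gradients match central finite differences for every family", {
  set.seed(42)
  graphs <- lapply(1:3, function(i) {
    n <- sample(2:4, 1); m <- sample(2:5, 1)
    build_duplex_graph(matrix(rnorm(n * 6), n, 6), matrix(rnorm(m * 6), m, 6))
  })
  labels <- c(0L, 1L, 1L)
  batch <- duplexgnn:::collate_graphs(graphs)
  h <- 1e-5
  for (fam in c("GCN", "SAGE", "GAT")) {
    pool <- sample(c("ADD", "MEAN", "MAX"), 1)
    cc <- classifier_config(fam, 2, 5, 2, 4, pool, 0, input_dim = 6)
    pp <- init_parameters(cc, 11)
    lg <- duplexgnn:::engine_loss_grad(batch, labels, pp, cc)
    for (blk in c("gnn", "fc")) for (l in seq_along(pp[[blk]]))
      for (tn in names(pp[[blk]][[l]])) {
        arr <- pp[[blk]][[l]][[tn]]
        for (k in sample(length(arr), min(4, length(arr)))) {
          p2 <- pp
          p2[[blk]][[l]][[tn]][k] <- arr[k] + h
          lp <- duplexgnn:::engine_loss_grad(batch, labels, p2, cc,
                                             want_grad = FALSE)$loss
          p2[[blk]][[l]][[tn]][k] <- arr[k] - h
          lm <- duplexgnn:::engine_loss_grad(batch, labels, p2, cc,
                                             want_grad = FALSE)$loss
          num <- (lp - lm) / (2 * h)
          ana <- lg$grads[[blk]][[l]][[tn]][k]
          expect_lt(abs(num - ana) / max(1e-6, abs(num), abs(ana)), 1e-4)
        }
      }
  }
})
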