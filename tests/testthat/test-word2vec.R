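mk_corpus <- function(sentences, origin = "MIRNA")
  duplexgnn:::new_corpus(sentences, origin)

test_that("train_cbow vocabulary closure, dimension and error contracts", {
  corp <- mk_corpus(list(c("ACG", "UAC"), c("ACG", "GUA")))
  tb <- train_cbow(corp, dimension = 16, seed = 3)
  expect_s3_class(tb, "embedding_table")
  expect_setequal(rownames(tb$vectors), c("ACG", "UAC", "GUA"))
  expect_equal(dim(tb$vectors), c(3L, 16L))

  one <- train_cbow(mk_corpus(list(c("ACG", "UAC"))), min_count = 1, seed = 1)
  expect_setequal(rownames(one$vectors), c("ACG", "UAC"))

  expect_error(train_cbow(mk_corpus(list())), "zero sentences")
  expect_error(train_cbow(corp, dimension = 0), "dimension")
  # min_count excludes rare words from the vocabulary
  tb2 <- train_cbow(corp, min_count = 2, seed = 1)
  expect_identical(rownames(tb2$vectors), "ACG")
})

test_that("train_cbow is deterministic given corpus, hyperparameters and seed", {
  set.seed(10)
  sent <- replicate(30, sample(c("AAA","CCC","GGG","UUU","ACG"),
                               sample(3:8, 1), replace = TRUE),
                    simplify = FALSE)
  corp <- mk_corpus(sent)
  t1 <- train_cbow(corp, epochs = 20, seed = 77)
  t2 <- train_cbow(corp, epochs = 20, seed = 77)
  expect_identical(t1$vectors, t2$vectors)
  t3 <- train_cbow(corp, epochs = 20, seed = 78)
  expect_false(identical(t1$vectors, t3$vectors))
})

test_that("words sharing contexts embed closer than words in disjoint contexts", {
  # X and Y always occur in identical contexts; Z only in a disjoint context
  set.seed(5)
  ctx <- c("AAA", "CCC", "GGG")
  zctx <- c("UUU", "UUA", "UAU")
  sent <- vector("list", 200)
  for (i in 1:200) {
    sent[[i]] <- if (i %% 2 == 0) c(ctx[1:2], sample(c("ACG", "UAC"), 1), ctx[3])
                 else c(zctx[1:2], "GUA", zctx[3])
  }
  corp <- mk_corpus(sent)
  cos <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  cxy <- czx <- numeric(5)
  for (s in 1:5) {
    tb <- train_cbow(corp, dimension = 16, epochs = 50, seed = s)$vectors
    cxy[s] <- cos(tb["ACG", ], tb["UAC", ])
    czx[s] <- cos(tb["ACG", ], tb["GUA", ])
  }
  expect_gt(mean(cxy), mean(czx))
})

test_that("embed_tokens: lookup identity, ZERO OOV policy, shape contract", {
  corp <- mk_corpus(list(c("ACG", "UAC"), c("ACG", "GUA")))
  tb <- train_cbow(corp, dimension = 16, seed = 3)
  m <- embed_tokens(c("ACG"), tb)
  expect_equal(m[1, ], unname(tb$vectors["ACG", ]))
  oov <- embed_tokens(c("NNN"), tb)  # word never seen
  expect_equal(oov[1, ], rep(0, 16))
  big <- embed_tokens(rep(c("ACG", "UAC"), 4), tb)
  expect_equal(dim(big), c(8L, 16L))
  expect_error(embed_tokens(character(0), tb), "empty")
})

test_that("embedding vocabulary is restricted to training-split words", {
  # test-only records contain triplets absent from every training sequence
  rec <- data.frame(
    mirna_seq = c("ACGACGACG", "ACGUACACG", "GGGUUUGGG"),
    site_seq = c("TTTAAATTT", "AAATTTAAA", "CCCGGGCCC"),
    split = c("train", "train", "test"))
  tables <- fit_embeddings(rec, epochs = 5)
  train_words <- unique(unlist(lapply(rec$mirna_seq[1:2], tokenize_sequence)))
  expect_true(all(rownames(tables$mirna$vectors) %in% train_words))
  expect_false("GGG" %in% rownames(tables$mirna$vectors))
  expect_false("CCC" %in% rownames(tables$mrna$vectors))
})

test_that("embedding tables round trip through the text format", {
  corp <- mk_corpus(list(c("ACG", "UAC", "GU"), c("ACG", "A")))
  tb <- train_cbow(corp, dimension = 8, epochs = 10, seed = 2)
  path <- file.path(withr::local_tempdir(), "vec.txt")
  write_embedding_table(tb, path)
  tb2 <- read_embedding_table(path)
  expect_equal(tb2$vectors, tb$vectors, tolerance = 1e-12)
  expect_equal(tb2$origin, tb$origin)
  expect_equal(tb2$dimension, tb$dimension)
  expect_equal(tb2$fingerprint$seed, tb$fingerprint$seed)
})
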