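new_embedding_table <- function(vectors, origin, fingerprint) {
  structure(list(origin = origin,
                 dimension = ncol(vectors),
                 vectors = vectors,
                 fingerprint = fingerprint),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table origin=%s, %d words x %d dims>\n",
              x$origin, nrow(x$vectors), x$dimension))
  invisible(x)
}

#' Fit a CBOW word-embedding model on a token corpus
#'
#' Trains a continuous-bag-of-words model with negative sampling on the
#' corpus sentences and returns the learned lookup table mapping each
#' vocabulary word (triplet or 1-2 nt remainder) to a dense vector. One model
#' is fitted per corpus: miRNA words and target-site words never share a
#' vocabulary or a latent space. The fit is fully deterministic given the
#' corpus, hyperparameters and seed (single-threaded, own RNG).
#'
#' @param corpus a `corpus` from [build_corpora()].
#' @param dimension embedding dimensionality (default 16).
#' @param window maximum context window; the effective window shrinks
#'   uniformly at random per position, as in the classic implementation.
#'   Default 5 covers a whole ~8-word miRNA sentence.
#' @param epochs passes over the corpus (default 100; sentences are short).
#' @param negative negative samples per centre word (default 5).
#' @param min_count discard words occurring fewer times (default 1: the
#'   triplet vocabulary is tiny and dropping words would create avoidable
#'   out-of-vocabulary tokens).
#' @param seed integer seed for the trainer's internal RNG.
#' @param lr0,lr_min initial and floor learning rate of the linear decay.
#' @return An `embedding_table` whose vocabulary is exactly the set of words
#'   occurring at least `min_count` times.
#' @export
train_cbow <- function(corpus, dimension = 16L, window = 5L, epochs = 100L,
                       negative = 5L, min_count = 1L, seed = 1L,
                       lr0 = 0.025, lr_min = 1e-4) {
  if (!inherits(corpus, "corpus")) stop("`corpus` must be a corpus object")
  if (length(corpus$sentences) == 0L) stop("corpus has zero sentences")
  if (dimension < 1L) stop("dimension must be >= 1")
  tokens <- unlist(corpus$sentences, use.names = FALSE)
  counts <- table(tokens)
  # deterministic vocabulary order: decreasing count, ties alphabetical
  counts <- counts[counts >= min_count]
  if (length(counts) == 0L) stop("min_count leaves an empty vocabulary")
  ord <- order(-as.integer(counts), names(counts))
  vocab <- names(counts)[ord]
  freq <- as.numeric(counts)[ord]
  idx <- seq_along(vocab) - 1L
  names(idx) <- vocab
  sent_idx <- lapply(corpus$sentences, function(s) {
    i <- idx[s]
    as.integer(i[!is.na(i)])
  })
  mat <- cbow_train_cpp(sent_idx, length(vocab), freq,
                        as.integer(dimension), as.integer(window),
                        as.integer(epochs), as.integer(negative),
                        lr0, lr_min, as.integer(seed))
  rownames(mat) <- vocab
  new_embedding_table(mat, corpus$origin,
                      fingerprint = list(dimension = as.integer(dimension),
                                         window = as.integer(window),
                                         epochs = as.integer(epochs),
                                         negative = as.integer(negative),
                                         min_count = as.integer(min_count),
                                         lr0 = lr0, lr_min = lr_min,
                                         seed = as.integer(seed)))
}

#' Embed a token sentence as a matrix of word vectors
#'
#' Looks each word up in the fitted table; row i of the result is the vector
#' of word i. Words absent from the vocabulary map to the all-zeros vector
#' (neutral under sum/mean readout and message passing).
#'
#' @param sentence character vector of words (see [tokenize_sequence()]).
#' @param table an `embedding_table`.
#' @param oov_policy only `"ZERO"` is supported.
#' @return numeric matrix `length(sentence) x table$dimension`.
#' @export
embed_tokens <- function(sentence, table, oov_policy = "ZERO") {
  oov_policy <- match.arg(oov_policy, "ZERO")
  if (!inherits(table, "embedding_table")) stop("`table` must be an embedding_table")
  if (length(sentence) == 0L) stop("empty sentence")
  out <- matrix(0, nrow = length(sentence), ncol = table$dimension)
  hit <- sentence %in% rownames(table$vectors)
  if (any(hit)) out[hit, ] <- table$vectors[sentence[hit], , drop = FALSE]
  out
}

#' Write an embedding table as plain text
#'
#' One word per line followed by its vector components
#' (whitespace-separated), plus a JSON metadata sidecar at `<path>.meta.json`
#' recording origin, dimension, hyperparameters and seed.
#'
#' @param table an `embedding_table`.
#' @param path output file path for the vectors.
#' @return `path`, invisibly.
#' @export
write_embedding_table <- function(table, path) {
  lines <- vapply(seq_len(nrow(table$vectors)), function(i) {
    paste(c(rownames(table$vectors)[i],
            formatC(table$vectors[i, ], format = "g", digits = 17)),
          collapse = " ")
  }, character(1))
  writeLines(lines, path)
  meta <- c(list(origin = table$origin, dimension = table$dimension),
            table$fingerprint)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an embedding table written by [write_embedding_table()]
#' @param path vectors file path (sidecar expected at `<path>.meta.json`).
#' @return An `embedding_table`.
#' @export
read_embedding_table <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "[[:space:]]+")
  words <- vapply(parts, `[[`, character(1), 1L)
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1]),
                   numeric(length(parts[[1]]) - 1L)))
  rownames(vecs) <- words
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  fp <- meta[setdiff(names(meta), c("origin", "dimension"))]
  new_embedding_table(vecs, meta$origin, fingerprint = fp)
}

#' Fit the pair of embedding tables for one training split
#'
#' Convenience wrapper: builds the miRNA and target-site corpora from the
#' training-split records and fits one CBOW model on each.
#'
#' @param records dataset records with a `split` column.
#' @param dimension,window,epochs,negative,min_count passed to [train_cbow()].
#' @param seed base seed; the two fits use `seed` and `seed + 1`.
#' @param tag split tag to fit on (default `"train"`).
#' @return list with `mirna` and `mrna` embedding tables.
#' @export
fit_embeddings <- function(records, dimension = 16L, window = 5L,
                           epochs = 100L, negative = 5L, min_count = 1L,
                           seed = 1L, tag = "train") {
  corp <- build_corpora(records, tag = tag)
  list(
    mirna = train_cbow(corp$mirna, dimension, window, epochs, negative,
                       min_count, seed = seed),
    mrna = train_cbow(corp$mrna, dimension, window, epochs, negative,
                      min_count, seed = seed + 1L)
  )
}
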