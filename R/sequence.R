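#' duplexgnn: graph neural network classification of miRNA-mRNA duplexes
#'
#' Encodes a candidate miRNA-mRNA duplex as a graph whose nodes are
#' word2vec-embedded nucleotide triplets and classifies it with a graph
#' neural network (spectral convolution, sample-and-aggregate, or attention
#' layers; sum/mean/max readout; fully connected softmax head). Includes the
#' full training and multi-replicate evaluation protocol and a planted-signal
#' synthetic duplex generator.
#'
#' @useDynLib duplexgnn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import Matrix
#' @importFrom stats runif rnorm sd
#' @importFrom utils read.delim write.table modifyList
#' @keywords internal
"_PACKAGE"

NUCLEOTIDES <- c("A", "C", "G", "T", "U")

#' Normalize a nucleotide sequence
#'
#' Uppercases the input and validates it against the nucleic-acid alphabet
#' \{A, C, G, T, U\}. T and U are deliberately not unified: miRNA and mRNA
#' words live in separate corpora with separate embedding models.
#'
#' @param seq single character string, length >= 1.
#' @return The normalized (uppercase) sequence.
#' @export
normalize_sequence <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("sequence must be a single character string")
  s <- toupper(seq)
  if (nchar(s) == 0L) stop("invalid sequence: empty string")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% NUCLEOTIDES))
  if (length(bad) > 0L)
    stop(sprintf("invalid character '%s' at position %d (alphabet is A/C/G/T/U)",
                 chars[bad[1]], bad[1]))
  s
}

#' Split a sequence into triplet words
#'
#' Cuts the sequence into consecutive, non-overlapping 3-nucleotide words,
#' left to right. When the length is not divisible by 3 the trailing 1- or
#' 2-nucleotide remainder is kept as its own word, so that the concatenation
#' of the words always reproduces the input.
#'
#' @param seq nucleotide string over \{A,C,G,T,U\} (case-insensitive).
#' @return Character vector of words ("token sentence"); all words have
#'   length 3 except possibly the last.
#' @examples
#' tokenize_sequence("ACGUACGUA") # "ACG" "UAC" "GUA"
#' tokenize_sequence("ACGT")      # "ACG" "T"
#' @export
tokenize_sequence <- function(seq) {
  s <- normalize_sequence(seq)
  n <- nchar(s)
  starts <- seq.int(1L, n, by = 3L)
  substring(s, starts, pmin(starts + 2L, n))
}

new_corpus <- function(sentences, origin) {
  origin <- match.arg(origin, c("MIRNA", "MRNA"))
  structure(list(sentences = sentences, origin = origin), class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("<corpus origin=%s, %d sentences, %d tokens>\n",
              x$origin, length(x$sentences),
              sum(lengths(x$sentences))))
  invisible(x)
}

#' Build per-origin token corpora from the training split
#'
#' Tokenizes the miRNA and target-site sequences of the records belonging to
#' the requested split and collects them into two separate corpora (one per
#' origin), the units on which the two CBOW models are fitted. Restricting
#' the corpora to the training split prevents information from the validation
#' or test samples leaking into the embeddings.
#'
#' @param records data.frame with columns `mirna_seq`, `site_seq` and a
#'   `split` column (e.g. as added by [split_dataset()]), or pass `split`
#'   explicitly.
#' @param split character vector of per-record split tags; defaults to
#'   `records$split`.
#' @param tag which split to keep (default `"train"`).
#' @return list with elements `mirna` and `mrna`, each a `corpus`.
#' @export
build_corpora <- function(records, split = records$split, tag = "train") {
  if (is.null(split))
    stop("records carry no split membership; run split_dataset() first or pass `split`")
  if (length(split) != nrow(records))
    stop("`split` length must match the number of records")
  keep <- which(split == tag)
  if (length(keep) == 0L)
    stop(sprintf("configuration error: no records in split '%s'", tag))
  sub <- records[keep, , drop = FALSE]
  list(
    mirna = new_corpus(lapply(sub$mirna_seq, tokenize_sequence), "MIRNA"),
    mrna  = new_corpus(lapply(sub$site_seq, tokenize_sequence), "MRNA")
  )
}
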