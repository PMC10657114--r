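# Dataset, results and checkpoint serialization. The canonical dataset
# format is a five-column TSV; a FASTA pair (miRNA file + site file + label
# file in matched order) is accepted as an alternative input.

DATASET_COLUMNS <- c("mirna_id", "mirna_seq", "site_id", "site_seq", "label")

validate_records <- function(df, source = "dataset") {
  for (col in DATASET_COLUMNS)
    if (!col %in% names(df)) stop(sprintf("%s: missing column '%s'", source, col))
  lab_chr <- as.character(df$label)
  bad <- which(!lab_chr %in% c("0", "1"))
  if (length(bad) > 0L)
    stop(sprintf("%s: invalid label '%s' at line %d (must be 0 or 1)",
                 source, lab_chr[bad[1]], bad[1] + 1L))
  df$label <- as.integer(lab_chr)
  for (i in seq_len(nrow(df))) {
    for (col in c("mirna_seq", "site_seq")) {
      ok <- tryCatch({ normalize_sequence(df[[col]][i]); TRUE },
                     error = function(e) conditionMessage(e))
      if (!isTRUE(ok))
        stop(sprintf("%s: record '%s'/'%s': %s",
                     source, df$mirna_id[i], df$site_id[i], ok))
    }
  }
  key <- paste(df$mirna_id, df$site_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L)
    stop(sprintf("%s: duplicate key (%s, %s) at line %d", source,
                 df$mirna_id[dup[1]], df$site_id[dup[1]], dup[1] + 1L))
  df
}

#' Read a duplex dataset
#'
#' TSV dialect: UTF-8, tab-separated, header
#' `mirna_id mirna_seq site_id site_seq label` (an optional `split` column is
#' preserved). FASTA_PAIR dialect: `path` is a prefix; `<prefix>_mirna.fa`
#' and `<prefix>_sites.fa` hold the sequences in matched record order and
#' `<prefix>_labels.tsv` one 0/1 label per line. Sequences are validated
#' against the \{A,C,G,T,U\} alphabet, labels against \{0,1\}, and duplicate
#' `(mirna_id, site_id)` keys are rejected.
#'
#' @param path file path (TSV) or path prefix (FASTA_PAIR).
#' @param format `"TSV"` (default) or `"FASTA_PAIR"`.
#' @return data.frame of validated records.
#' @export
read_dataset <- function(path, format = c("TSV", "FASTA_PAIR")) {
  format <- match.arg(toupper(format[1]), c("TSV", "FASTA_PAIR"))
  if (format == "TSV") {
    if (!file.exists(path)) stop(sprintf("no such file: %s", path))
    df <- read.delim(path, sep = "\t", colClasses = "character",
                     check.names = FALSE, stringsAsFactors = FALSE)
    df <- validate_records(df, source = path)
    return(df)
  }
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("FASTA_PAIR input requires the Biostrings package")
  fa_m <- paste0(path, "_mirna.fa")
  fa_s <- paste0(path, "_sites.fa")
  fl <- paste0(path, "_labels.tsv")
  for (f in c(fa_m, fa_s, fl))
    if (!file.exists(f)) stop(sprintf("no such file: %s", f))
  mir <- Biostrings::readBStringSet(fa_m)
  sit <- Biostrings::readBStringSet(fa_s)
  if (length(mir) != length(sit))
    stop("FASTA_PAIR: miRNA and site files differ in record count")
  labels <- readLines(fl)
  labels <- labels[nzchar(labels)]
  if (length(labels) != length(mir))
    stop("FASTA_PAIR: label count does not match record count")
  df <- data.frame(mirna_id = names(mir),
                   mirna_seq = as.character(mir),
                   site_id = names(sit),
                   site_seq = as.character(sit),
                   label = labels, row.names = NULL)
  validate_records(df, source = path)
}

#' Write a duplex dataset
#'
#' @param records validated records data.frame.
#' @param path output path (TSV) or prefix (FASTA_PAIR).
#' @param format `"TSV"` or `"FASTA_PAIR"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(records, path, format = c("TSV", "FASTA_PAIR")) {
  format <- match.arg(toupper(format[1]), c("TSV", "FASTA_PAIR"))
  if (format == "TSV") {
    cols <- intersect(c(DATASET_COLUMNS, "split"), names(records))
    write.table(records[, cols], path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    return(invisible(path))
  }
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("FASTA_PAIR output requires the Biostrings package")
  mir <- Biostrings::BStringSet(setNames(records$mirna_seq, records$mirna_id))
  sit <- Biostrings::BStringSet(setNames(records$site_seq, records$site_id))
  Biostrings::writeXStringSet(mir, paste0(path, "_mirna.fa"))
  Biostrings::writeXStringSet(sit, paste0(path, "_sites.fa"))
  writeLines(as.character(records$label), paste0(path, "_labels.tsv"))
  invisible(path)
}

fmt6 <- function(x) {
  if (is.numeric(x)) signif(x, 6) else x
}

#' Write experiment result files
#'
#' Writes (into `out_dir`) `replicates.tsv` (replicate, balanced_accuracy,
#' precision, recall, ...), `summary.tsv` (metric, mean, ci_low, ci_high) and,
#' when given, `predictions.tsv` (record key, probability_positive,
#' predicted_label). Numeric fields are serialized at 6 significant digits
#' for diff-stable golden files.
#'
#' @param out_dir output directory (created if needed).
#' @param replicates per-replicate metric table.
#' @param summary summary table from [summarize_replicates()].
#' @param predictions optional predictions data.frame.
#' @return named character vector of the written paths, invisibly.
#' @export
write_results <- function(out_dir, replicates, summary, predictions = NULL) {
  if (is.null(replicates) || nrow(replicates) == 0L)
    stop("empty replicate table: nothing to write")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create directory %s", out_dir))
  wt <- function(df, name) {
    p <- file.path(out_dir, name)
    df[] <- lapply(df, fmt6)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(replicates = wt(replicates, "replicates.tsv"),
             summary = wt(summary, "summary.tsv"))
  if (!is.null(predictions))
    paths <- c(paths, predictions = wt(predictions, "predictions.tsv"))
  invisible(paths)
}

#' Save a model checkpoint as JSON
#'
#' Stores the classifier configuration, the trained parameters and the two
#' embedding tables in one plain-text JSON file, so a checkpoint is
#' self-contained for later evaluation or prediction.
#'
#' @param path output path.
#' @param params `model_parameters`.
#' @param config `classifier_config`.
#' @param tables list with `mirna` and `mrna` embedding tables.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(path, params, config, tables) {
  ser_table <- function(tb) list(origin = tb$origin, dimension = tb$dimension,
                                 words = rownames(tb$vectors),
                                 vectors = unname(tb$vectors),
                                 fingerprint = tb$fingerprint)
  obj <- list(config = unclass(config),
              params = rapply(unclass(params), identity, how = "list"),
              tables = list(mirna = ser_table(tables$mirna),
                            mrna = ser_table(tables$mrna)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#' @param path checkpoint path.
#' @return list with `params`, `config`, `tables`.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  cfg <- do.call(classifier_config, obj$config[c("e_gnn", "l_gnn", "d_gnn",
                                                 "l_fc", "d_fc", "pool",
                                                 "dropout", "input_dim")])
  as_mat <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)
  gnn <- lapply(seq_len(cfg$l_gnn), function(l) {
    p <- list(W = as_mat(obj$params$gnn[[l]]$W))
    if (!is.null(obj$params$gnn[[l]]$a)) p$a <- as.numeric(obj$params$gnn[[l]]$a)
    p
  })
  fc <- lapply(seq_len(cfg$l_fc), function(l)
    list(W = as_mat(obj$params$fc[[l]]$W),
         b = as.numeric(obj$params$fc[[l]]$b)))
  params <- structure(list(gnn = gnn, fc = fc), class = "model_parameters")
  de_table <- function(tb) {
    vec <- as_mat(tb$vectors)
    rownames(vec) <- tb$words
    new_embedding_table(vec, tb$origin, as.list(tb$fingerprint))
  }
  list(params = params, config = cfg,
       tables = list(mirna = de_table(obj$tables$mirna),
                     mrna = de_table(obj$tables$mrna)))
}

#' Read a JSON run configuration
#'
#' One file describing a whole experiment: `data` (dataset path), and
#' optional `classifier`, `training`, `split`, `embedding` blocks whose
#' fields mirror [classifier_config()], [train_config()], [split_spec()] and
#' the [train_cbow()] hyperparameters.
#'
#' @param path JSON file path.
#' @return list with `data`, `classifier`, `training`, `split`, `embedding`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config file: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(
    data = obj$data,
    classifier = do.call(classifier_config,
                         as.list(obj$classifier %||% list())),
    training = do.call(train_config, as.list(obj$training %||% list())),
    split = do.call(split_spec, as.list(obj$split %||% list())),
    embedding = as.list(obj$embedding %||% list())
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
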