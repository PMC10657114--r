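# Planted-signal duplex simulator. Positives carry the DNA reverse
# complement of the miRNA seed region (canonical binding determinant,
# nucleotides 2-8) at a uniformly random offset inside the target site;
# negatives are rejection-sampled to contain no exact seed match.

#' Simulation configuration for synthetic duplex datasets
#'
#' @param n_pairs number of miRNA-site pairs to generate.
#' @param positive_fraction fraction of positives in (0, 1); default 0.5
#'   (the curated benchmark collections are balanced).
#' @param mirna_length_range inclusive length interval for miRNAs,
#'   default `c(20, 24)` nt.
#' @param site_length target-site length, default 40 nt.
#' @param seed_region 1-based inclusive nucleotide interval of the miRNA seed,
#'   default `c(2, 8)`.
#' @param label_noise probability in [0, 0.5) of independently flipping each
#'   label after planting (default 0).
#' @param rng_seed integer seed; the dataset is a pure function of the config.
#' @return A `simulation_config`.
#' @export
simulation_config <- function(n_pairs, positive_fraction = 0.5,
                              mirna_length_range = c(20L, 24L),
                              site_length = 40L, seed_region = c(2L, 8L),
                              label_noise = 0, rng_seed = 1L) {
  stopifnot(n_pairs >= 1, positive_fraction > 0, positive_fraction < 1,
            length(mirna_length_range) == 2L,
            mirna_length_range[1] >= 1,
            mirna_length_range[2] >= mirna_length_range[1],
            length(seed_region) == 2L, seed_region[1] >= 1)
  seed_len <- seed_region[2] - seed_region[1] + 1L
  if (seed_len < 1L) stop("seed_region must be a non-empty interval")
  if (seed_region[2] > mirna_length_range[1])
    stop("seed_region must fit inside the shortest miRNA")
  if (site_length < seed_len)
    stop("config conflict: site_length is shorter than the seed region")
  if (label_noise < 0 || label_noise >= 0.5)
    stop("label_noise must be in [0, 0.5)")
  structure(list(n_pairs = as.integer(n_pairs),
                 positive_fraction = positive_fraction,
                 mirna_length_range = as.integer(mirna_length_range),
                 site_length = as.integer(site_length),
                 seed_region = as.integer(seed_region),
                 label_noise = label_noise,
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_config")
}

RNA_ALPHABET <- c("A", "C", "G", "U")
DNA_ALPHABET <- c("A", "C", "G", "T")

#' DNA reverse complement of an RNA fragment
#'
#' Pairs A-T, C-G, G-C and U-A (the miRNA's uracil pairs with the mRNA's
#' adenine) and reverses, yielding the target-site substring a perfectly
#' complementary site would contain.
#'
#' @param rna RNA string over \{A,C,G,U\}.
#' @return DNA string over \{A,C,G,T\}.
#' @export
seed_match_site <- function(rna) {
  comp <- c(A = "T", C = "G", G = "C", U = "A")
  chars <- strsplit(toupper(rna), "", fixed = TRUE)[[1]]
  if (any(!chars %in% names(comp)))
    stop("seed must be RNA over {A,C,G,U}")
  paste(rev(unname(comp[chars])), collapse = "")
}

random_string <- function(len, alphabet) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

#' Generate a synthetic duplex dataset with a planted seed signal
#'
#' Draws `n_pairs` records: random miRNAs over \{A,C,G,U\} with lengths in
#' `mirna_length_range` and random target sites over \{A,C,G,T\} of
#' `site_length` nt. Exactly `round(n_pairs * positive_fraction)` records are
#' planted positives: their site contains, at a uniformly random offset, the
#' DNA reverse complement of the miRNA's seed region. Negative sites are
#' rejection-sampled until they contain no exact seed match for their miRNA.
#' Labels are then flipped independently with probability `label_noise`.
#' The result is byte-identical for identical configs.
#'
#' @param config a `simulation_config`.
#' @param max_attempts rejection-sampling bound per negative before erroring.
#' @return data.frame with columns `mirna_id`, `mirna_seq`, `site_id`,
#'   `site_seq`, `label`.
#' @export
generate_dataset <- function(config, max_attempts = 100L) {
  if (!inherits(config, "simulation_config"))
    stop("`config` must be a simulation_config")
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(config$rng_seed)
  n <- config$n_pairs
  n_pos <- round(n * config$positive_fraction)
  labels <- integer(n)
  labels[sample.int(n, n_pos)] <- 1L
  sr <- config$seed_region
  slen <- config$site_length
  motif_len <- sr[2] - sr[1] + 1L
  mirna <- character(n)
  site <- character(n)
  for (i in seq_len(n)) {
    len <- sample(config$mirna_length_range[1]:config$mirna_length_range[2], 1L)
    mirna[i] <- random_string(len, RNA_ALPHABET)
    motif <- seed_match_site(substr(mirna[i], sr[1], sr[2]))
    if (labels[i] == 1L) {
      s <- random_string(slen, DNA_ALPHABET)
      off <- sample.int(slen - motif_len + 1L, 1L) - 1L
      site[i] <- paste0(substr(s, 1, off), motif,
                        substr(s, off + motif_len + 1L, slen))
    } else {
      ok <- FALSE
      for (a in seq_len(max_attempts)) {
        s <- random_string(slen, DNA_ALPHABET)
        if (!grepl(motif, s, fixed = TRUE)) { ok <- TRUE; break }
      }
      if (!ok)
        stop(sprintf(paste0("rejection sampling failed after %d attempts: ",
                            "site_length %d cannot avoid the %d-nt seed match"),
                     max_attempts, slen, motif_len))
      site[i] <- s
    }
  }
  if (config$label_noise > 0) {
    flip <- runif(n) < config$label_noise
    labels[flip] <- 1L - labels[flip]
  }
  data.frame(mirna_id = sprintf("mir%05d", seq_len(n)),
             mirna_seq = mirna,
             site_id = sprintf("site%05d", seq_len(n)),
             site_seq = site,
             label = labels)
}

#' Oracle substring classifier for planted-signal data
#'
#' Predicts positive iff the site contains the exact reverse-complement match
#' of the record's miRNA seed region. On noise-free generated data this
#' attains balanced accuracy 1 by construction; it upper-bounds what any
#' classifier can learn from the planted signal.
#'
#' @param records duplex records.
#' @param seed_region seed interval (default `c(2, 8)`).
#' @return integer vector of 0/1 predictions.
#' @export
seed_match_classifier <- function(records, seed_region = c(2L, 8L)) {
  vapply(seq_len(nrow(records)), function(i) {
    motif <- seed_match_site(substr(records$mirna_seq[i],
                                    seed_region[1], seed_region[2]))
    as.integer(grepl(motif, records$site_seq[i], fixed = TRUE))
  }, integer(1))
}
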