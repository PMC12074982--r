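# Deterministic synthetic-data generators: random wild-type sequences,
# residue-compatible PTM annotation records, and labeled task tables with a
# plantable signal. Every generator is a pure function of (spec, seed).

#' Specification for the synthetic fixture generators
#'
#' Defaults emulate a small Swiss-Prot-like corpus: uniform random
#' sequences over the 20 amino acids, PTM records at a 5% rate per eligible
#' residue with a skewed type distribution in which the two most abundant
#' PTM types dominate, and logistic-link task labels.
#'
#' @param n_sequences number of sequences
#' @param min_length,max_length sequence length bounds (uniform)
#' @param ptm_rate probability that an eligible residue receives a record
#' @param effect_size strength of the planted task signal (log-odds per
#'   standardized feature unit; 0 = labels independent of the input)
#' @param seed integer seed
#' @return list of class `fixture_spec`
#' @export
fixture_spec <- function(n_sequences = 50L, min_length = 50L,
                         max_length = 200L, ptm_rate = 0.05,
                         effect_size = 1, seed = 1L) {
  stopifnot(n_sequences > 0, min_length > 0, max_length >= min_length,
            ptm_rate >= 0, ptm_rate <= 1, effect_size >= 0)
  structure(list(n_sequences = as.integer(n_sequences),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 ptm_rate = ptm_rate, effect_size = effect_size,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate random wild-type protein sequences
#'
#' Uniform over the 20 amino acids; lengths uniform in
#' `[min_length, max_length]`; accessions `SYN0001`, `SYN0002`, ...
#'
#' @param spec a [fixture_spec()]
#' @return named character vector (FASTA-ready)
#' @export
gen_sequences <- function(spec) {
  withr_seed(spec$seed, {
    span <- spec$max_length - spec$min_length + 1L
    lens <- spec$min_length +
      sample.int(span, spec$n_sequences, replace = TRUE) - 1L
    seqs <- vapply(lens, function(L)
      paste(sample(.wt_tokens, L, replace = TRUE), collapse = ""),
      character(1))
    stats::setNames(seqs, sprintf("SYN%04d", seq_len(spec$n_sequences)))
  })
}

# skewed PTM-type weights: the two most abundant types dominate
.ptm_type_weights <- function(vocab) {
  w <- rep(1, length(vocab$ptm_tokens))
  names(w) <- names(vocab$ptm_tokens)
  dominant <- intersect(c("<N-linked (GlcNAc\u2026) asparagine>",
                          "<Phosphoserine>"), names(w))
  w[dominant] <- 8
  w
}

#' Generate residue-compatible PTM annotation records
#'
#' For each sequence, every position whose residue is modifiable by at
#' least one vocabulary PTM token receives a record with probability
#' `ptm_rate`; the PTM type is drawn among the compatible tokens with
#' skewed weights (two dominant types). By construction every record passes
#' strict curation.
#'
#' @param spec a [fixture_spec()]
#' @param sequences named character vector from [gen_sequences()]
#' @param vocab a `ptm_vocab`
#' @return records `data.frame` as from [ptm_records()]
#' @export
gen_ptm_records <- function(spec, sequences, vocab) {
  wts <- .ptm_type_weights(vocab)
  by_res <- split(names(vocab$ptm_tokens), vocab$ptm_tokens)
  withr_seed(spec$seed + 1L, {
    acc <- character(0); pos <- integer(0); ptm <- character(0)
    res <- character(0)
    for (a in names(sequences)) {
      toks <- split_residues(sequences[[a]])
      eligible <- which(toks %in% names(by_res))
      hit <- eligible[stats::runif(length(eligible)) < spec$ptm_rate]
      for (p in hit) {
        cand <- by_res[[toks[p]]]
        pick <- if (length(cand) == 1L) cand
                else sample(cand, 1L, prob = wts[cand])
        acc <- c(acc, a); pos <- c(pos, p); ptm <- c(ptm, pick)
        res <- c(res, toks[p])
      }
    }
    if (!length(acc))
      return(ptm_records(character(0), integer(0), character(0),
                         character(0)))
    ptm_records(acc, pos, ptm, res)
  })
}

#' Generate a labeled binary task with a planted signal
#'
#' The planted feature is the PTM-token count of each sequence — all PTM
#' types by default, or one chosen type via `target_token`; labels are
#' Bernoulli with `P(y = 1) = plogis(effect_size * standardized_count)`, so
#' effect 0 makes labels independent of the input. Splits are stratified by
#' label.
#'
#' @param spec a [fixture_spec()] (`effect_size` and `seed` are used)
#' @param modified_sequences named list of token vectors (e.g.
#'   `curate_dataset(...)$sequences`)
#' @param vocab a `ptm_vocab` identifying the PTM tokens
#' @param target_token `NULL` (count every PTM token) or one PTM token name
#' @param split_fractions train/valid/test fractions (sum to 1)
#' @return list of class `task_dataset`: `tokens` (list), `labels` (0/1),
#'   `feature` (planted counts), `split` (factor train/valid/test)
#' @export
gen_task <- function(spec, modified_sequences,
                     vocab = build_default_vocab(), target_token = NULL,
                     split_fractions = c(train = 0.7, valid = 0.15,
                                         test = 0.15)) {
  stopifnot(abs(sum(split_fractions) - 1) < 1e-8)
  counts <- if (is.null(target_token))
    vapply(modified_sequences,
           function(t) sum(t %in% names(vocab$ptm_tokens)), numeric(1))
  else
    vapply(modified_sequences,
           function(t) sum(t == target_token), numeric(1))
  z <- if (stats::sd(counts) > 0) (counts - mean(counts)) / stats::sd(counts)
       else counts * 0
  withr_seed(spec$seed + 2L, {
    p <- stats::plogis(spec$effect_size * z)
    y <- as.integer(stats::runif(length(p)) < p)
    split <- rep(NA_character_, length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      n <- length(idx)
      n_tr <- round(split_fractions[["train"]] * n)
      n_va <- round(split_fractions[["valid"]] * n)
      split[idx[seq_len(n_tr)]] <- "train"
      if (n_va > 0) split[idx[n_tr + seq_len(min(n_va, n - n_tr))]] <- "valid"
      split[is.na(split) & seq_along(split) %in% idx] <- "test"
    }
    structure(list(tokens = modified_sequences, labels = y,
                   feature = counts,
                   split = factor(split, levels = c("train", "valid",
                                                    "test"))),
              class = "task_dataset")
  })
}

#' Write a fixture bundle (FASTA + records TSV) to a directory
#'
#' @param spec a [fixture_spec()]
#' @param dir output directory (created if needed)
#' @param vocab a `ptm_vocab`
#' @return invisibly, a list with the generated `sequences` and `records`
#' @export
write_fixture_bundle <- function(spec, dir, vocab = build_default_vocab()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- gen_sequences(spec)
  recs <- gen_ptm_records(spec, seqs, vocab)
  write_protein_fasta(seqs, file.path(dir, "sequences.fasta"))
  write_ptm_records(recs, file.path(dir, "records.tsv"))
  invisible(list(sequences = seqs, records = recs))
}
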