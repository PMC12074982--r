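# Benchmark harness: frozen-embedding classification heads with the
# replicate protocol (n = 5) and seven binary metrics, plus zero-shot PTM
# discovery from masked-position logits and pair-task features.

#' Extract frozen embeddings from a model
#'
#' Residue level returns one `[length, model_dim]` matrix per sequence;
#' sequence level mean-pools the final hidden states over non-pad
#' positions. Deterministic given the model and backend.
#'
#' @param model a `ptm_lm`
#' @param sequences list of sequences (see [predict.ptm_lm()] for accepted
#'   forms)
#' @param backend backend object (default: seeded mock)
#' @param level `"sequence"` or `"residue"`
#' @return `"sequence"`: `[n, model_dim]` matrix; `"residue"`: list of
#'   per-position matrices
#' @export
extract_embeddings <- function(model, sequences, backend = NULL,
                               level = c("sequence", "residue")) {
  level <- match.arg(level)
  predict(model, sequences, backend = backend,
          type = if (level == "sequence") "pooled" else "embedding")
}

#' Binary classification metrics
#'
#' Thresholded metrics (accuracy, precision, recall, F1, MCC at the given
#' score threshold) plus threshold-free ranking metrics (AUROC via the
#' rank/Mann-Whitney formulation; AUPRC as average precision). With a
#' single-class `y_true` the ranking metrics are undefined and returned as
#' `NA` with a warning rather than silently zero.
#'
#' @param y_true 0/1 labels
#' @param y_score scores in \[0, 1\]
#' @param threshold decision threshold for the thresholded metrics
#' @return named list: accuracy, precision, recall, f1, mcc, auroc, auprc
#' @export
compute_metrics <- function(y_true, y_score, threshold = 0.5) {
  stopifnot(length(y_true) == length(y_score))
  y_true <- as.integer(y_true)
  pred <- as.integer(y_score >= threshold)
  tp <- sum(pred == 1 & y_true == 1); fp <- sum(pred == 1 & y_true == 0)
  fn <- sum(pred == 0 & y_true == 1); tn <- sum(pred == 0 & y_true == 0)
  acc <- (tp + tn) / length(y_true)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  if (n1 == 0L || n0 == 0L) {
    warning("single-class y_true: AUROC/AUPRC undefined")
    auroc <- NA_real_; auprc <- NA_real_
  } else {
    r <- rank(y_score)                       # midranks handle ties
    auroc <- (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    ord <- order(y_score, decreasing = TRUE)
    yt <- y_true[ord]
    cum_tp <- cumsum(yt)
    prec_k <- cum_tp / seq_along(yt)
    rec_k <- cum_tp / n1
    drec <- diff(c(0, rec_k))
    auprc <- sum(prec_k * drec)              # average precision
  }
  list(accuracy = acc, precision = prec, recall = rec, f1 = f1, mcc = mcc,
       auroc = auroc, auprc = auprc)
}

#' Head configuration for frozen-embedding benchmarks
#'
#' @param hidden_units hidden layer width of the default 2-layer perceptron
#' @param maxit training iterations
#' @param decay L2 penalty passed to the optimizer (0 = none)
#' @return list of class `head_config`
#' @export
head_config <- function(hidden_units = 16L, maxit = 200L, decay = 0) {
  structure(list(hidden_units = as.integer(hidden_units),
                 maxit = as.integer(maxit), decay = decay),
            class = "head_config")
}

#' Train a classification head on frozen embeddings, with replicates
#'
#' Fits the configured head (default: a 2-layer perceptron, i.e. one hidden
#' layer with sigmoid output) on the training split once per replicate seed
#' and evaluates all seven metrics on the test split. Per-replicate values
#' and their means are reported; identical seeds give identical reports.
#'
#' @param train_x `[n_train, p]` embedding matrix
#' @param train_y 0/1 labels
#' @param test_x `[n_test, p]` embedding matrix
#' @param test_y 0/1 labels
#' @param config a [head_config()]
#' @param n_replicates number of independently seeded fits (default 5)
#' @param seeds integer seeds, one per replicate
#' @return object of class `metrics_report`: `replicates` (data.frame, one
#'   row per replicate) and `mean` (named numeric)
#' @export
fit_head <- function(train_x, train_y, test_x, test_y,
                     config = head_config(), n_replicates = 5L,
                     seeds = seq_len(n_replicates)) {
  if (length(unique(train_y)) < 2L)
    stop("training split contains a single class")
  stopifnot(length(seeds) == n_replicates)
  rows <- lapply(seq_len(n_replicates), function(i) {
    fit <- withr_seed(seeds[i],
      nnet::nnet(x = train_x, y = as.numeric(train_y),
                 size = config$hidden_units, decay = config$decay,
                 maxit = config$maxit, entropy = TRUE, trace = FALSE))
    score <- as.numeric(stats::predict(fit, test_x))
    m <- compute_metrics(test_y, score)
    data.frame(replicate = i, seed = seeds[i], as.data.frame(m))
  })
  reps <- do.call(rbind, rows)
  metric_cols <- setdiff(names(reps), c("replicate", "seed"))
  structure(list(replicates = reps,
                 mean = colMeans(reps[metric_cols], na.rm = TRUE),
                 n_replicates = n_replicates),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Frozen-embedding benchmark (", x$n_replicates, "replicates )\n")
  print(round(x$mean, 4))
  invisible(x)
}

#' Zero-shot PTM discovery at one position
#'
#' Masks the given position of a wild-type sequence, runs the language
#' model, and ranks the PTM-token logits at that position in descending
#' order. By default only PTM tokens compatible with the wild-type residue
#' at the position are ranked (PTMs are residue specific); set
#' `restrict_to_residue = FALSE` for all PTM tokens.
#'
#' @param model a `ptm_lm`
#' @param sequence wild-type amino-acid string or token vector
#' @param position 1-based position to interrogate
#' @param backend backend object (default: seeded mock)
#' @param restrict_to_residue limit ranking to residue-compatible PTM tokens
#' @return data.frame with `token` and `logit`, sorted descending
#' @export
zero_shot_ptm_discovery <- function(model, sequence, position,
                                    backend = NULL,
                                    restrict_to_residue = TRUE) {
  vocab <- model$vocab
  ids <- .as_ids(model, sequence)
  if (position < 1L || position > length(ids))
    stop("position ", position, " outside sequence of length ", length(ids))
  if (is.null(backend))
    backend <- mock_backend(vocab, dim = model$config$backend_dim)
  residue <- decode_tokens(vocab, ids[position])
  masked <- unclass(ids)
  masked[position] <- .mask_id(vocab)
  h <- model_forward(model$weights, model$config, vocab,
                     structure(masked, class = "token_seq"), backend)
  logits <- lm_logits(model$weights$head, h)[position, ]
  cand <- names(vocab$ptm_tokens)
  if (restrict_to_residue && residue %in% vocab$wt_tokens)
    cand <- cand[vocab$ptm_tokens == residue]
  df <- data.frame(token = cand,
                   logit = logits[token_id(vocab, cand) + 1L],
                   stringsAsFactors = FALSE)
  df[order(df$logit, decreasing = TRUE), , drop = FALSE]
}

#' Features for a protein-pair task
#'
#' Mean-pooled embedding of each sequence, concatenated with the modified
#' protein first. Swapping the inputs exactly swaps the two halves.
#'
#' @param model a `ptm_lm`
#' @param seq_a modified sequence (first half)
#' @param seq_b partner sequence (second half)
#' @param backend backend object
#' @return numeric vector of length `2 * model_dim`
#' @export
pair_task_features <- function(model, seq_a, seq_b, backend = NULL) {
  emb <- extract_embeddings(model, list(seq_a, seq_b), backend = backend,
                            level = "sequence")
  c(emb[1L, ], emb[2L, ])
}
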