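# User-facing model object: configuration + vocabulary + weights, with the
# usual print/summary/predict methods.

#' Construct a PTM-aware bidirectional language model
#'
#' Bundles a configuration, a vocabulary, and freshly initialized weights
#' into a `ptm_lm` object. Train with [train_lm()]; run with
#' [predict.ptm_lm()], [extract_embeddings()] or
#' [zero_shot_ptm_discovery()].
#'
#' @param config an [lm_config()]; its `vocab_size` is forced to match
#'   `vocab`
#' @param vocab a `ptm_vocab`
#' @param seed integer seed for weight initialization
#' @return object of class `ptm_lm`
#' @examples
#' m <- ptm_lm(lm_config(preset = "tiny"), build_default_vocab(), seed = 1)
#' @export
ptm_lm <- function(config = lm_config(preset = "tiny"),
                   vocab = build_default_vocab(), seed = 1L) {
  config$vocab_size <- vocab_size(vocab)
  weights <- withr_seed(seed, init_lm_weights(config))
  structure(list(config = config, vocab = vocab, weights = weights),
            class = "ptm_lm")
}

.n_params <- function(w) {
  if (is.null(w)) return(0L)
  if (is.list(w)) return(sum(vapply(w, .n_params, numeric(1))))
  length(w)
}

#' @export
print.ptm_lm <- function(x, ...) {
  cat("PTM-aware bidirectional state-space language model\n")
  cat(sprintf("  %d bidirectional layers, dim %d, state %d, vocab %d (%s parameters)\n",
              x$config$n_layers, x$config$model_dim, x$config$ssm$state_dim,
              x$config$vocab_size,
              format(.n_params(x$weights), big.mark = ",")))
  invisible(x)
}

#' @export
summary.ptm_lm <- function(object, ...) {
  print(object)
  cat("  backend dim:", object$config$backend_dim, "\n")
  cat("  PTM tokens:", length(object$vocab$ptm_tokens), "\n")
  invisible(object)
}

.as_ids <- function(model, x) {
  if (is.character(x) && length(x) == 1L && !x %in% model$vocab$tokens)
    x <- split_residues(x)               # plain residue string
  if (is.character(x)) return(encode_tokens(model$vocab, x))
  structure(as.integer(unclass(x)), class = "token_seq")
}

#' Predict method: hidden states or vocabulary logits
#'
#' @param object a `ptm_lm`
#' @param sequences one sequence or a list: plain amino-acid strings,
#'   character token vectors (mixed wild-type/PTM), or 0-based id vectors
#' @param backend backend object (defaults to a seeded [mock_backend()])
#' @param type `"embedding"` (per-position final hidden states),
#'   `"pooled"` (mean over non-pad positions) or `"logits"`
#' @param ... unused
#' @return a matrix for one input, else a list of matrices (or a matrix of
#'   pooled rows)
#' @export
predict.ptm_lm <- function(object, sequences, backend = NULL,
                           type = c("embedding", "pooled", "logits"), ...) {
  type <- match.arg(type)
  if (is.null(backend))
    backend <- mock_backend(object$vocab, dim = object$config$backend_dim)
  single <- !is.list(sequences)
  if (single) sequences <- list(sequences)
  out <- lapply(sequences, function(s) {
    ids <- .as_ids(object, s)
    h <- model_forward(object$weights, object$config, object$vocab, ids,
                       backend)
    switch(type,
           embedding = h,
           logits = lm_logits(object$weights$head, h),
           pooled = {
             keep <- as.integer(unclass(ids)) != .pad_id(object$vocab)
             colMeans(h[keep, , drop = FALSE])
           })
  })
  if (type == "pooled") out <- do.call(rbind, out)
  if (single && is.list(out)) out <- out[[1L]]
  out
}
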