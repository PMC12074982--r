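# Sigmoid-gated fusion of the model's own PTM-aware token embeddings with
# wild-type embeddings from an external backend, plus the pluggable backend
# contract and a deterministic mock backend used throughout the tests.

#' Parameters of the sigmoid gate
#' @param model_dim embedding width
#' @return list with `W` (`[2*model_dim, model_dim]`) and `b` (length
#'   `model_dim`), zero-initialized unless `init = "random"`
#' @param init `"zero"` (gate = 0.5 everywhere) or `"random"`
#' @export
gate_params <- function(model_dim, init = c("zero", "random")) {
  init <- match.arg(init)
  D <- as.integer(model_dim)
  if (init == "zero") list(W = matrix(0, 2L * D, D), b = rep(0, D))
  else list(W = .init_mat(2L * D, D), b = rep(0, D))
}

#' Gated fusion of token and backend embeddings
#'
#' Computes `gate = sigmoid(concat(token, backend) %*% W + b)` and returns the
#' elementwise convex combination `token * gate + backend * (1 - gate)`.
#' Every output element therefore lies between the two inputs; with
#' zero gate weights the output is exactly their midpoint.
#'
#' @param gate parameters from [gate_params()]
#' @param token_embedding `[length, model_dim]` matrix
#' @param backend_embedding `[length, model_dim]` matrix (already projected)
#' @return fused `[length, model_dim]` matrix
#' @export
gated_fuse <- function(gate, token_embedding, backend_embedding) {
  .fuse_forward(gate, token_embedding, backend_embedding)$out
}

.fuse_forward <- function(gate, tok, bke) {
  if (!identical(dim(tok), dim(bke)))
    stop("fusion inputs must have identical shape: got ",
         paste(dim(tok), collapse = "x"), " vs ",
         paste(dim(bke), collapse = "x"))
  cat2 <- cbind(tok, bke)
  pre <- cat2 %*% gate$W + rep(gate$b, each = nrow(tok))
  g <- .sigmoid(pre)
  out <- tok * g + bke * (1 - g)
  list(out = out, cache = list(tok = tok, bke = bke, cat2 = cat2, g = g))
}

.fuse_backward <- function(gate, cache, dOut) {
  tok <- cache$tok; bke <- cache$bke; g <- cache$g
  D <- ncol(tok)
  dtok <- dOut * g
  dbke <- dOut * (1 - g)
  dg <- dOut * (tok - bke)
  dpre <- dg * g * (1 - g)
  dW <- crossprod(cache$cat2, dpre)
  db <- colSums(dpre)
  dcat <- tcrossprod(dpre, gate$W)
  dtok <- dtok + dcat[, seq_len(D), drop = FALSE]
  dbke <- dbke + dcat[, D + seq_len(D), drop = FALSE]
  list(dtok = dtok, dbke = dbke, grads = list(W = dW, b = db))
}

#' Deterministic mock wild-type embedding backend
#'
#' A drop-in stand-in for an external wild-type protein LM behind the same
#' contract (`embed(ids)` + `dim`). Each token id gets a fixed unit-norm
#' pseudo-random vector derived from `seed`, independent of position and of
#' the surrounding sequence, so identical tokens always embed identically
#' and the whole pipeline stays reproducible without any external model.
#'
#' @param vocab a `ptm_vocab` (the backend only ever sees wild-type/special
#'   ids, but the table covers the full vocabulary)
#' @param dim backend embedding width
#' @param seed integer seed for the embedding table
#' @return list of class `wt_backend` with `embed(ids)` returning a
#'   `[length(ids), dim]` matrix, `dim`, and `id` ("mock")
#' @export
mock_backend <- function(vocab, dim = 16L, seed = 42L) {
  n <- vocab_size(vocab)
  tab <- withr_seed(seed, {
    m <- matrix(stats::rnorm(n * dim), n, dim)
    m / sqrt(rowSums(m^2))
  })
  structure(list(
    embed = function(ids) tab[as.integer(unclass(ids)) + 1L, , drop = FALSE],
    dim = as.integer(dim),
    id = "mock"
  ), class = "wt_backend")
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Project backend embeddings to the model width
#'
#' Affine map `backend_dim -> model_dim`. When the two widths already agree
#' and `adapter` is `NULL`, the embeddings pass through unchanged.
#'
#' @param adapter `NULL` (identity, requires equal dims) or a list with
#'   `W` (`[backend_dim, model_dim]`) and `b` (length `model_dim`)
#' @param backend_embedding `[length, backend_dim]` matrix
#' @param model_dim target width
#' @return `[length, model_dim]` matrix
#' @export
backend_project <- function(adapter, backend_embedding, model_dim) {
  if (is.null(adapter)) {
    if (ncol(backend_embedding) != model_dim)
      stop("backend dim ", ncol(backend_embedding), " != model dim ",
           model_dim, " and no adapter given")
    return(backend_embedding)
  }
  backend_embedding %*% adapter$W + rep(adapter$b, each = nrow(backend_embedding))
}
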