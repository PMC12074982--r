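# Bidirectional wrapper and full language model. Each bidirectional layer
# runs a forward-direction block on the sequence and a backward-direction
# block on the flipped sequence, concatenates the two hidden streams
# (un-flipping the backward one), maps 2*D -> D through a fully connected
# layer, and averages the two residual streams:
#   residual = 0.5 * (residual_f + flip(residual_b)).

.flip <- function(X) X[rev(seq_len(nrow(X))), , drop = FALSE]

# arithmetic mean of the forward residual stream and the un-flipped backward
# residual stream; the only way the two directions' residuals are merged
.combine_residual <- function(residual_f, residual_b) {
  0.5 * (residual_f + .flip(residual_b))
}

#' Language-model configuration
#'
#' @param n_layers number of bidirectional layers (each contains one
#'   forward and one backward single-direction block)
#' @param model_dim hidden width D (must be even)
#' @param vocab_size number of tokens in the mixed vocabulary
#' @param state_dim scan state size per channel
#' @param expand inner expansion factor
#' @param conv_width causal convolution kernel width
#' @param backend_dim width of the wild-type backend embeddings (an affine
#'   adapter bridges it to `model_dim` when they differ)
#' @param preset `"tiny"` (2 layers, dim 32, state 8 — the desk-scale default
#'   used in tests), `"full-24x768"` (24 bidirectional layers, dim 768,
#'   state 16) or `"full-12x768"` (the same budget read as 12 bidirectional
#'   layers, i.e. 24 direction-wise layers). Explicit arguments override the
#'   preset.
#' @return list of class `lm_config`
#' @export
lm_config <- function(n_layers = NULL, model_dim = NULL, vocab_size = 50L,
                      state_dim = NULL, expand = 2L, conv_width = 4L,
                      backend_dim = NULL, preset = c("tiny", "full-24x768",
                                                     "full-12x768")) {
  preset <- match.arg(preset)
  def <- switch(preset,
    "tiny"        = list(n_layers = 2L,  model_dim = 32L,  state_dim = 8L),
    "full-24x768" = list(n_layers = 24L, model_dim = 768L, state_dim = 16L),
    "full-12x768" = list(n_layers = 12L, model_dim = 768L, state_dim = 16L))
  n_layers <- as.integer(n_layers %||% def$n_layers)
  model_dim <- as.integer(model_dim %||% def$model_dim)
  state_dim <- as.integer(state_dim %||% def$state_dim)
  if (n_layers < 1L) stop("n_layers must be >= 1")
  if (model_dim %% 2L != 0L) stop("model_dim must be even")
  cfg <- list(n_layers = n_layers, model_dim = model_dim,
              vocab_size = as.integer(vocab_size),
              backend_dim = as.integer(backend_dim %||% model_dim),
              ssm = mamba_block_config(model_dim, state_dim = state_dim,
                                       expand = expand,
                                       conv_width = conv_width))
  class(cfg) <- "lm_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Initialize all language-model weights
#'
#' Embedding table, gate, backend adapter (identity omitted when the
#' backend width equals the model width), per-layer forward/backward blocks
#' with their fully connected fusion, final norm, and the untied LM head.
#' Draws from R's RNG; seed with `set.seed()` for reproducibility.
#'
#' @param cfg an [lm_config()]
#' @return nested list of weight arrays
#' @export
init_lm_weights <- function(cfg) {
  D <- cfg$model_dim; V <- cfg$vocab_size
  layers <- lapply(seq_len(cfg$n_layers), function(i) {
    list(f = .init_block(cfg$ssm), b = .init_block(cfg$ssm),
         fc = list(W = .init_mat(2L * D, D), b = rep(0, D)))
  })
  proj <- if (cfg$backend_dim == D) NULL
          else list(W = .init_mat(cfg$backend_dim, D), b = rep(0, D))
  list(E_tok = matrix(stats::rnorm(V * D, sd = 0.02), V, D),
       gate = gate_params(D, init = "random"),
       proj = proj,
       layers = layers,
       w_final = rep(1, D),
       head = list(W = matrix(stats::rnorm(D * V, sd = 0.02), D, V),
                   b = rep(0, V)))
}

# --- one bidirectional layer ------------------------------------------------

.bidir_forward <- function(lw, cfg, hidden, residual = NULL) {
  had_res <- !is.null(residual)
  fw <- .block_forward(lw$f, cfg$ssm, hidden, residual)
  flip_res <- if (had_res) .flip(residual) else NULL
  bw <- .block_forward(lw$b, cfg$ssm, .flip(hidden), flip_res)
  cat2 <- cbind(fw$hidden, .flip(bw$hidden))
  hidden_new <- cat2 %*% lw$fc$W + rep(lw$fc$b, each = nrow(hidden))
  residual_new <- .combine_residual(fw$residual, bw$residual)
  list(hidden = hidden_new, residual = residual_new,
       cache = list(f = fw$cache, b = bw$cache, cat2 = cat2,
                    had_res = had_res))
}

.bidir_backward <- function(lw, cfg, cache, dhidden, dresidual) {
  D <- cfg$model_dim
  dfc_W <- crossprod(cache$cat2, dhidden)
  dfc_b <- colSums(dhidden)
  dcat <- tcrossprod(dhidden, lw$fc$W)
  dhf <- dcat[, seq_len(D), drop = FALSE]
  dhb <- .flip(dcat[, D + seq_len(D), drop = FALSE])
  dres_half <- 0.5 * dresidual
  fb <- .block_backward(lw$f, cfg$ssm, cache$f, dhf, dres_half)
  bb <- .block_backward(lw$b, cfg$ssm, cache$b, dhb, .flip(dres_half))
  dh <- fb$dhidden + .flip(bb$dhidden)
  dr <- fb$dresidual + .flip(bb$dresidual)
  # without a residual input, hidden feeds residual_new exactly once and the
  # block's dhidden already carries that path
  if (!cache$had_res) dr <- NULL
  list(dhidden = dh, dresidual = dr,
       grads = list(f = fb$grads, b = bb$grads,
                    fc = list(W = dfc_W, b = dfc_b)))
}

#' Forward pass of one bidirectional layer
#'
#' @param layer_weights one element of `weights$layers` from
#'   [init_lm_weights()]: forward block `f`, backward block `b`, fusion `fc`
#' @param cfg an [lm_config()]
#' @param hidden `[length, model_dim]` matrix or `[batch, length, model_dim]`
#'   array
#' @param residual same shape, or `NULL` for the first layer
#' @return list with fused `hidden` and averaged `residual`
#' @export
bidirectional_layer_forward <- function(layer_weights, cfg, hidden,
                                        residual = NULL) {
  if (is.matrix(hidden)) {
    fw <- .bidir_forward(layer_weights, cfg, hidden, residual)
    return(list(hidden = fw$hidden, residual = fw$residual))
  }
  outh <- hidden; outr <- hidden
  for (b in seq_len(dim(hidden)[1L])) {
    rb <- if (is.null(residual)) NULL else residual[b, , ]
    fw <- .bidir_forward(layer_weights, cfg, hidden[b, , ], rb)
    outh[b, , ] <- fw$hidden; outr[b, , ] <- fw$residual
  }
  list(hidden = outh, residual = outr)
}

# --- full model core (one sequence) -----------------------------------------
#
# input_ids are the *masked* model input; backend ids are derived from them
# by PTM->mask conversion. Pad positions get zero fused embeddings and are
# excluded from the loss; the scans still traverse them.

.model_forward <- function(weights, cfg, vocab, input_ids, backend,
                           want_cache = FALSE) {
  ids1 <- as.integer(unclass(input_ids)) + 1L
  if (length(ids1) == 0L) stop("empty input sequence")
  tok <- weights$E_tok[ids1, , drop = FALSE]
  bids <- to_backend_tokens(vocab, input_ids)
  bemb <- backend$embed(bids)
  bproj <- backend_project(weights$proj, bemb, cfg$model_dim)
  fu <- .fuse_forward(weights$gate, tok, bproj)
  fused <- fu$out
  pad_rows <- which(as.integer(unclass(input_ids)) == .pad_id(vocab))
  if (length(pad_rows)) fused[pad_rows, ] <- 0
  hidden <- fused; residual <- NULL
  caches <- if (want_cache) vector("list", cfg$n_layers) else NULL
  for (l in seq_len(cfg$n_layers)) {
    st <- .bidir_forward(weights$layers[[l]], cfg, hidden, residual)
    hidden <- st$hidden; residual <- st$residual
    if (want_cache) caches[[l]] <- st$cache
  }
  res_final <- hidden + residual
  nf <- .rmsnorm_forward(res_final, weights$w_final)
  out <- nf$y
  list(hidden = out,
       cache = if (want_cache)
         list(ids1 = ids1, bemb = bemb, fuse = fu$cache, pad_rows = pad_rows,
              layers = caches, norm = nf$cache) else NULL)
}

.model_backward <- function(weights, cfg, cache, dout) {
  nb <- .rmsnorm_backward(cache$norm, dout)
  dhidden <- nb$dX; dresidual <- nb$dX
  gl <- vector("list", cfg$n_layers)
  for (l in rev(seq_len(cfg$n_layers))) {
    bk <- .bidir_backward(weights$layers[[l]], cfg, cache$layers[[l]],
                          dhidden, dresidual)
    dhidden <- bk$dhidden; dresidual <- bk$dresidual
    gl[[l]] <- bk$grads
  }
  dfused <- dhidden   # first layer folds residual grad into dhidden
  if (length(cache$pad_rows)) dfused[cache$pad_rows, ] <- 0
  fb <- .fuse_backward(weights$gate, cache$fuse, dfused)
  dE <- matrix(0, nrow(weights$E_tok), ncol(weights$E_tok))
  for (i in seq_along(cache$ids1))
    dE[cache$ids1[i], ] <- dE[cache$ids1[i], ] + fb$dtok[i, ]
  dproj <- NULL
  if (!is.null(weights$proj))
    dproj <- list(W = crossprod(cache$bemb, fb$dbke),
                  b = colSums(fb$dbke))
  list(grads = list(E_tok = dE, gate = fb$grads, proj = dproj,
                    layers = gl, w_final = nb$dw, head = NULL))
}

#' Run the full bidirectional language model
#'
#' Fuses token and backend embeddings at the input, applies all
#' bidirectional layers and the final normalization. Deterministic given
#' weights and inputs.
#'
#' @param weights from [init_lm_weights()]
#' @param cfg an [lm_config()]
#' @param vocab a `ptm_vocab`
#' @param input_ids 0-based token ids (possibly containing mask/pad)
#' @param backend a backend object (see [mock_backend()])
#' @return `[length, model_dim]` matrix of final hidden states
#' @export
model_forward <- function(weights, cfg, vocab, input_ids, backend) {
  .model_forward(weights, cfg, vocab, input_ids, backend)$hidden
}

#' Language-model logits over the mixed vocabulary
#'
#' Affine head mapping hidden states to one logit per vocabulary token, so
#' PTM tokens can be predicted at any position.
#'
#' @param head list with `W` (`[model_dim, vocab_size]`) and `b`
#' @param hidden `[length, model_dim]` matrix
#' @return `[length, vocab_size]` logits
#' @export
lm_logits <- function(head, hidden) {
  hidden %*% head$W + rep(head$b, each = nrow(hidden))
}
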