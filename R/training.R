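# Biased masked-LM training: masking sampler (standard branch with
# probability 0.8, PTM-biased branch with probability 0.2), negative
# log-likelihood loss at masked positions, random crop / end-pad to a fixed
# length, length-bucketed batches fed shortest-first, and Adam with no
# weight decay at a constant learning rate.

#' Training configuration
#'
#' Defaults follow the published procedure: standard-branch probability 0.8,
#' 15% mask rate, crop/pad length 1024, Adam (no weight decay) at a constant
#' learning rate of 2e-4, batch size 256. Desk-scale runs override
#' `max_length`, `batch_size` and `n_steps`.
#'
#' @param p_standard probability of the standard masking branch
#' @param mask_rate per-position masking probability r
#' @param max_length crop/pad target length
#' @param batch_size sequences per batch (upper bound under a token budget)
#' @param token_budget optional per-batch token budget; when set, batch size
#'   shrinks to `floor(token_budget / sequence_length)` for long buckets
#'   ("dynamic batching")
#' @param lr constant Adam learning rate
#' @param n_steps number of optimizer steps
#' @param n_buckets number of length clusters for batching
#' @param seed integer seed for all training randomness
#' @param log_every record metrics every this many steps
#' @return list of class `train_config`
#' @export
training_config <- function(p_standard = 0.8, mask_rate = 0.15,
                            max_length = 1024L, batch_size = 256L,
                            token_budget = NULL, lr = 2e-4, n_steps = 100L,
                            n_buckets = 4L, seed = 1L, log_every = 10L) {
  stopifnot(p_standard >= 0, p_standard <= 1, mask_rate > 0, mask_rate < 1,
            max_length >= 1)
  structure(list(p_standard = p_standard, mask_rate = mask_rate,
                 max_length = as.integer(max_length),
                 batch_size = as.integer(batch_size),
                 token_budget = token_budget, lr = lr,
                 n_steps = as.integer(n_steps),
                 n_buckets = as.integer(n_buckets),
                 seed = as.integer(seed),
                 log_every = as.integer(log_every)),
            class = "train_config")
}

#' Sample a masking plan for one sequence
#'
#' With probability `p_standard` the plan takes the standard branch: every
#' non-pad, non-special position is masked independently with probability
#' `mask_rate`. Otherwise it takes the PTM-biased branch: every PTM-token
#' position is masked (always), and each wild-type position independently
#' with probability `mask_rate`. Masked positions are replaced by the mask
#' id in the returned model input; their original ids are kept as targets.
#' If a draw selects no position at all, one maskable position is forced so
#' the loss is defined. Special tokens are never maskable. Uses R's RNG.
#'
#' @param cfg a [training_config()]
#' @param ids 0-based token ids (may include pads)
#' @param vocab a `ptm_vocab`
#' @return list of class `masking_plan`: `branch`, `masked_positions`
#'   (1-based), `targets` (original ids at those positions), `input_ids`
#'   (ids with masks substituted)
#' @export
sample_masking_plan <- function(cfg, ids, vocab) {
  ids <- as.integer(unclass(ids))
  if (length(ids) == 0L) stop("cannot mask an empty sequence")
  special <- ids %in% vocab$special_ids
  is_ptm <- ids %in% vocab$ptm_ids
  is_wt <- !special & !is_ptm
  branch <- if (stats::runif(1) < cfg$p_standard) "standard" else "ptm_biased"
  if (branch == "standard") {
    cand <- which(!special)
    masked <- cand[stats::runif(length(cand)) < cfg$mask_rate]
  } else {
    wt_pos <- which(is_wt)
    masked <- sort(c(which(is_ptm),
                     wt_pos[stats::runif(length(wt_pos)) < cfg$mask_rate]))
  }
  if (length(masked) == 0L) {
    cand <- which(!special)
    if (length(cand)) masked <- cand[sample.int(length(cand), 1L)]
  }
  input <- ids
  input[masked] <- .mask_id(vocab)
  structure(list(branch = branch, masked_positions = as.integer(masked),
                 targets = ids[masked],
                 input_ids = structure(input, class = "token_seq")),
            class = "masking_plan")
}

#' Masked-LM loss at the masked positions
#'
#' Negative log likelihood of the original tokens under the softmax over the
#' vocabulary, summed over masked positions; the per-token average is
#' reported alongside.
#'
#' @param logits `[length, vocab_size]` matrix
#' @param plan a `masking_plan` (or any list with `masked_positions` and
#'   `targets`)
#' @return list with `sum`, `mean` and `n` (masked position count)
#' @export
mlm_loss <- function(logits, plan) {
  pos <- plan$masked_positions; tgt <- plan$targets
  if (length(pos) == 0L) stop("mlm_loss requires at least one masked position")
  l <- logits[pos, , drop = FALSE]
  m <- apply(l, 1L, max)
  logZ <- m + log(rowSums(exp(l - m)))
  picked <- l[cbind(seq_along(pos), tgt + 1L)]
  s <- sum(logZ - picked)
  list(sum = s, mean = s / length(pos), n = length(pos))
}

# loss gradient wrt logits: rows at masked positions get softmax - onehot
.mlm_loss_grad <- function(logits, plan) {
  pos <- plan$masked_positions; tgt <- plan$targets
  d <- matrix(0, nrow(logits), ncol(logits))
  l <- logits[pos, , drop = FALSE]
  m <- apply(l, 1L, max)
  p <- exp(l - m); p <- p / rowSums(p)
  p[cbind(seq_along(pos), tgt + 1L)] <- p[cbind(seq_along(pos), tgt + 1L)] - 1
  d[pos, ] <- p
  d
}

#' Randomly crop or end-pad a sequence to a fixed length
#'
#' Sequences longer than `max_length` are cut to a contiguous window whose
#' start is uniform random; shorter ones get a suffix of pad ids. The output
#' always has exactly `max_length` positions.
#'
#' @param vocab a `ptm_vocab`
#' @param ids 0-based token ids
#' @param max_length target length
#' @return token ids of length `max_length`
#' @export
crop_or_pad <- function(vocab, ids, max_length) {
  ids <- as.integer(unclass(ids))
  L <- length(ids)
  out <- if (L > max_length) {
    start <- sample.int(L - max_length + 1L, 1L)
    ids[start:(start + max_length - 1L)]
  } else {
    c(ids, rep(.pad_id(vocab), max_length - L))
  }
  structure(out, class = "token_seq")
}

#' Length-bucketed batch order
#'
#' Clusters sequences by length into `n_buckets` quantile bins and emits
#' batches in ascending order of bucket length (shortest first). Within a
#' bucket the order is shuffled; every sequence appears in exactly one
#' batch. With a `token_budget`, the per-batch sequence count shrinks for
#' long buckets.
#'
#' @param lengths integer sequence lengths
#' @param batch_size maximum sequences per batch
#' @param n_buckets number of length clusters
#' @param token_budget optional max tokens (length x count) per batch
#' @return list of integer index vectors, in feed order
#' @export
length_bucketed_batches <- function(lengths, batch_size, n_buckets = 4L,
                                    token_budget = NULL) {
  n <- length(lengths)
  if (n == 0L) stop("empty dataset")
  n_buckets <- min(n_buckets, length(unique(lengths)))
  breaks <- unique(stats::quantile(lengths, probs = seq(0, 1,
                                                        length.out = n_buckets + 1L)))
  bucket <- cut(lengths, breaks = breaks, include.lowest = TRUE,
                labels = FALSE)
  batches <- list()
  for (bk in sort(unique(bucket))) {   # ascending bucket length
    idx <- which(bucket == bk)
    idx <- idx[sample.int(length(idx))]
    bs <- batch_size
    if (!is.null(token_budget))
      bs <- max(1L, min(batch_size, floor(token_budget / max(lengths[idx]))))
    starts <- seq(1L, length(idx), by = bs)
    for (s in starts)
      batches[[length(batches) + 1L]] <- idx[s:min(s + bs - 1L, length(idx))]
  }
  batches
}

# --- Adam on nested weight trees --------------------------------------------

.tree_map <- function(f, a) {
  if (is.list(a)) return(lapply(a, function(x) .tree_map(f, x)))
  if (is.null(a)) return(NULL)
  f(a)
}

.tree_map2 <- function(f, a, b) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) {
    keys <- if (!is.null(names(a)) && all(nzchar(names(a)))) names(a)
            else seq_along(a)
    out <- a
    for (nm in keys) out[[nm]] <- .tree_map2(f, a[[nm]], b[[nm]])
    return(out)
  }
  f(a, b)
}

.zeros_like <- function(p) .tree_map(function(x) x * 0, p)

.adam_init <- function(params)
  list(m = .zeros_like(params), v = .zeros_like(params), t = 0L)

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- .tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g,
                        state$v, grads)
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  upd <- .tree_map2(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                    state$m, state$v)
  params <- .tree_map2(`-`, params, upd)
  list(params = params, state = state)
}

# forward + loss + full gradient tree for one (input, plan) pair
.sequence_loss_grads <- function(weights, cfg, vocab, backend, plan) {
  fw <- .model_forward(weights, cfg, vocab, plan$input_ids, backend,
                       want_cache = TRUE)
  logits <- lm_logits(weights$head, fw$hidden)
  loss <- mlm_loss(logits, plan)
  dlogits <- .mlm_loss_grad(logits, plan)
  dW_head <- crossprod(fw$hidden, dlogits)
  db_head <- colSums(dlogits)
  dhidden <- tcrossprod(dlogits, weights$head$W)
  bk <- .model_backward(weights, cfg, fw$cache, dhidden)
  grads <- bk$grads
  grads$head <- list(W = dW_head, b = db_head)
  pred <- max.col(logits[plan$masked_positions, , drop = FALSE]) - 1L
  list(loss = loss, grads = grads, n_correct = sum(pred == plan$targets))
}

#' Train the language model with the biased masked-LM objective
#'
#' Per step: crop/pad each batch sequence, sample a masking plan, derive
#' backend tokens, embed and project through the backend, fuse with the
#' token embeddings, run the bidirectional model, and take one Adam step on
#' the per-masked-token mean negative log likelihood (constant learning
#' rate, no weight decay). Batches follow the shortest-first length-bucketed
#' order, re-shuffled each epoch. Fully seeded and deterministic.
#'
#' @param model a [ptm_lm()] object
#' @param dataset list of 0-based token id sequences (uncropped)
#' @param backend a backend object, e.g. [mock_backend()]
#' @param cfg a [training_config()]
#' @param quiet suppress progress messages
#' @return object of class `ptm_lm_fit`: the trained `model`, the metrics
#'   `log` (data.frame: step, loss, acc, lr) and `cfg`
#' @export
train_lm <- function(model, dataset, backend, cfg = training_config(),
                     quiet = TRUE) {
  stopifnot(inherits(model, "ptm_lm"), length(dataset) >= 1L)
  vocab <- model$vocab; mcfg <- model$config
  weights <- model$weights
  set.seed(cfg$seed)
  adam <- .adam_init(weights)
  log <- list()
  step <- 0L
  while (step < cfg$n_steps) {
    lens <- vapply(dataset, function(s) min(length(s), cfg$max_length),
                   integer(1))
    batches <- length_bucketed_batches(lens, cfg$batch_size, cfg$n_buckets,
                                       cfg$token_budget)
    for (batch in batches) {
      if (step >= cfg$n_steps) break
      step <- step + 1L
      total <- NULL; loss_sum <- 0; n_mask <- 0L; n_corr <- 0L
      for (i in batch) {
        ids <- crop_or_pad(vocab, dataset[[i]], cfg$max_length)
        plan <- sample_masking_plan(cfg, ids, vocab)
        sg <- .sequence_loss_grads(weights, mcfg, vocab, backend, plan)
        loss_sum <- loss_sum + sg$loss$sum
        n_mask <- n_mask + sg$loss$n
        n_corr <- n_corr + sg$n_correct
        total <- if (is.null(total)) sg$grads
                 else .tree_map2(`+`, total, sg$grads)
      }
      if (!is.finite(loss_sum))
        stop("training diverged at step ", step, ": non-finite loss")
      total <- .tree_map(function(g) g / n_mask, total)
      st <- .adam_step(weights, total, adam, cfg$lr)
      weights <- st$params; adam <- st$state
      if (step %% cfg$log_every == 0L || step == cfg$n_steps) {
        rec <- data.frame(step = step, loss = loss_sum / n_mask,
                          acc = n_corr / n_mask, lr = cfg$lr)
        log[[length(log) + 1L]] <- rec
        if (!quiet)
          message(sprintf("step %d  loss %.4f  acc %.3f", step,
                          rec$loss, rec$acc))
      }
    }
  }
  model$weights <- weights
  structure(list(model = model, log = do.call(rbind, log), cfg = cfg),
            class = "ptm_lm_fit")
}

#' @export
print.ptm_lm_fit <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  cat("Masked-LM fit:", last$step, "steps; final loss",
      sprintf("%.4f", last$loss), "; masked-token accuracy",
      sprintf("%.3f", last$acc), "\n")
  invisible(x)
}

#' @export
plot.ptm_lm_fit <- function(x, ...) {
  graphics::plot(x$log$step, x$log$loss, type = "l", xlab = "step",
                 ylab = "mean masked-token NLL", ...)
  invisible(x)
}

#' Masked-token accuracy of a model on a dataset
#'
#' Samples one masking plan per sequence (seeded) and reports the fraction
#' of masked positions whose argmax prediction equals the original token.
#'
#' @param model a `ptm_lm`
#' @param dataset list of token id sequences
#' @param backend backend object
#' @param cfg a [training_config()] (masking settings + max_length)
#' @param seed RNG seed for the evaluation plans
#' @return numeric accuracy in \[0, 1\]
#' @export
masked_token_accuracy <- function(model, dataset, backend,
                                  cfg = training_config(), seed = 1L) {
  set.seed(seed)
  n_ok <- 0L; n <- 0L
  for (s in dataset) {
    ids <- crop_or_pad(model$vocab, s, cfg$max_length)
    plan <- sample_masking_plan(cfg, ids, model$vocab)
    h <- model_forward(model$weights, model$config, model$vocab,
                       plan$input_ids, backend)
    logits <- lm_logits(model$weights$head, h)
    pred <- max.col(logits[plan$masked_positions, , drop = FALSE]) - 1L
    n_ok <- n_ok + sum(pred == plan$targets)
    n <- n + length(plan$targets)
  }
  n_ok / n
}
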