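test_that("residual combination is the mean of forward and un-flipped backward streams", {
  ones <- matrix(1, 6, 4)
  zeros <- matrix(0, 6, 4)
  expect_identical(ptmlm:::.combine_residual(ones, zeros),
                   matrix(0.5, 6, 4))
  # within a full layer the combination equals the independently computed mean
  set.seed(20)
  cfg <- lm_config(n_layers = 1L, model_dim = 8L, state_dim = 4L)
  w <- init_lm_weights(cfg)
  h <- matrix(stats::rnorm(48), 6, 8)
  r <- matrix(stats::rnorm(48), 6, 8)
  lay <- w$layers[[1L]]
  out <- bidirectional_layer_forward(lay, cfg, h, r)
  fwd <- ptmlm:::.block_forward(lay$f, cfg$ssm, h, r)
  flip <- ptmlm:::.flip
  bwd <- ptmlm:::.block_forward(lay$b, cfg$ssm, flip(h), flip(r))
  expect_equal(out$residual, 0.5 * (fwd$residual + flip(bwd$residual)),
               tolerance = 1e-12)
})

test_that("tied weights on a palindromic input give a palindromic output", {
  set.seed(21)
  cfg <- lm_config(n_layers = 1L, model_dim = 8L, state_dim = 4L)
  w <- init_lm_weights(cfg)
  lay <- w$layers[[1L]]
  lay$b <- lay$f                       # tie the two directions
  D <- cfg$model_dim                   # and the two halves of the fusion map
  lay$fc$W[D + seq_len(D), ] <- lay$fc$W[seq_len(D), ]
  half <- matrix(stats::rnorm(24), 3, 8)
  x <- rbind(half, half[3:1, ])        # palindrome along the length axis
  out <- bidirectional_layer_forward(lay, cfg, x)
  expect_lt(max(abs(out$hidden - ptmlm:::.flip(out$hidden))), 1e-5)
  expect_lt(max(abs(out$residual - ptmlm:::.flip(out$residual))), 1e-5)
})

test_that("flip equivariance: swapping directions mirrors the output", {
  set.seed(22)
  cfg <- lm_config(n_layers = 1L, model_dim = 8L, state_dim = 4L)
  w <- init_lm_weights(cfg)
  lay <- w$layers[[1L]]
  swapped <- lay
  swapped$f <- lay$b
  swapped$b <- lay$f
  # the 2D->D fusion consumes (forward, backward) halves; swap them too
  D <- cfg$model_dim
  swapped$fc$W <- rbind(lay$fc$W[D + seq_len(D), , drop = FALSE],
                        lay$fc$W[seq_len(D), , drop = FALSE])
  x <- matrix(stats::rnorm(80), 10, 8)
  out <- bidirectional_layer_forward(lay, cfg, x)
  out_sw <- bidirectional_layer_forward(swapped, cfg, ptmlm:::.flip(x))
  expect_lt(max(abs(ptmlm:::.flip(out_sw$hidden) - out$hidden)), 1e-5)
  expect_lt(max(abs(ptmlm:::.flip(out_sw$residual) - out$residual)), 1e-5)
})

test_that("the bidirectional layer sees both directions", {
  set.seed(23)
  cfg <- lm_config(n_layers = 1L, model_dim = 8L, state_dim = 4L)
  w <- init_lm_weights(cfg)
  L <- 9L
  x <- matrix(stats::rnorm(L * 8), L, 8)
  base <- bidirectional_layer_forward(w$layers[[1L]], cfg, x)$hidden
  t <- 5L
  xp <- x
  xp[t, ] <- xp[t, ] + 0.1
  pert <- bidirectional_layer_forward(w$layers[[1L]], cfg, xp)$hidden
  moved <- rowSums(abs(pert - base)) > 1e-9
  expect_true(any(moved[seq_len(t - 1L)]))   # upstream positions move
  expect_true(any(moved[(t + 1L):L]))        # downstream positions move
})

test_that("model forward is deterministic and rejects empty input", {
  m <- tiny_model(seed = 4)
  bk <- tiny_backend()
  set.seed(24)
  ids <- random_token_ids(15)
  h1 <- model_forward(m$weights, m$config, m$vocab, ids, bk)
  h2 <- model_forward(m$weights, m$config, m$vocab, ids, bk)
  expect_identical(h1, h2)
  expect_identical(dim(h1), c(15L, 32L))
  expect_error(model_forward(m$weights, m$config, m$vocab,
                             structure(integer(0), class = "token_seq"), bk),
               "empty")
})

test_that("a silenced single layer reduces the model to the normalized fused embedding", {
  m <- tiny_model(seed = 5, n_layers = 1L)
  bk <- tiny_backend()
  w <- m$weights
  w$layers[[1L]]$f$W_out[] <- 0
  w$layers[[1L]]$b$W_out[] <- 0
  w$layers[[1L]]$fc$W[] <- 0
  w$layers[[1L]]$fc$b[] <- 0
  set.seed(25)
  ids <- random_token_ids(7)
  got <- model_forward(w, m$config, m$vocab, ids, bk)
  # mixers silenced: hidden after the layer is 0, residual carries the fused
  # embedding, so the output is just the final norm of that embedding
  tok <- w$E_tok[unclass(ids) + 1L, , drop = FALSE]
  bemb <- bk$embed(to_backend_tokens(m$vocab, ids))
  fused <- gated_fuse(w$gate, tok, bemb)
  want <- ptmlm:::.rmsnorm_forward(fused, w$w_final)$y
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("LM head exposes logits over the full mixed vocabulary", {
  m <- tiny_model(seed = 6)
  bk <- tiny_backend()
  set.seed(26)
  ids <- random_token_ids(9)
  h <- model_forward(m$weights, m$config, m$vocab, ids, bk)
  logits <- lm_logits(m$weights$head, h)
  expect_identical(dim(logits), c(9L, 50L))
  expect_true(all(is.finite(logits)))
  # zero head -> flat zero logits
  expect_true(all(lm_logits(list(W = matrix(0, 32, 50), b = rep(0, 50)),
                            h) == 0))
  # crafted head favouring one PTM token dominates everywhere
  ps <- token_id(m$vocab, "<Phosphoserine>")
  head <- list(W = matrix(0, 32, 50), b = rep(0, 50))
  head$b[ps + 1L] <- 10
  crafted <- lm_logits(head, h)
  expect_true(all(max.col(crafted) - 1L == ps))
})
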