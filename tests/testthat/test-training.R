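test_that("masking sampler hits the configured branch and per-position rates", {
  v <- tiny_vocab
  cfg <- training_config(seed = 1)
  set.seed(202)
  ids <- random_token_ids(120, ptm_frac = 0.15)
  n <- 2000L
  branches <- character(n)
  std_masked <- 0L; std_total <- 0L
  for (i in seq_len(n)) {
    plan <- sample_masking_plan(cfg, ids, v)
    branches[i] <- plan$branch
    if (plan$branch == "standard") {
      std_masked <- std_masked + length(plan$masked_positions)
      std_total <- std_total + length(ids)
    }
  }
  p_hat <- mean(branches == "standard")
  expect_lt(abs(p_hat - 0.8), 3 * sqrt(0.8 * 0.2 / n))
  r_hat <- std_masked / std_total
  expect_lt(abs(r_hat - 0.15), 3 * sqrt(0.15 * 0.85 / std_total))
})

test_that("the PTM-biased branch always masks every PTM position", {
  v <- tiny_vocab
  cfg <- training_config(p_standard = 0)   # force the biased branch
  set.seed(203)
  for (i in 1:200) {
    ids <- random_token_ids(60, ptm_frac = 0.2)
    plan <- sample_masking_plan(cfg, ids, v)
    expect_identical(plan$branch, "ptm_biased")
    ptm_pos <- which(unclass(ids) %in% v$ptm_ids)
    expect_true(all(ptm_pos %in% plan$masked_positions))
    # masked inputs are mask tokens; targets keep the originals
    expect_true(all(unclass(plan$input_ids)[plan$masked_positions] ==
                      token_id(v, "<mask>")))
    expect_identical(plan$targets,
                     as.integer(unclass(ids)[plan$masked_positions]))
  }
})

test_that("biased branch without PTM tokens degrades to wild-type masking", {
  v <- tiny_vocab
  cfg <- training_config(p_standard = 0)
  set.seed(204)
  ids <- random_token_ids(400, ptm_frac = 0)
  masked <- 0L
  for (i in 1:100) {
    plan <- sample_masking_plan(cfg, ids, v)
    expect_true(all(unclass(ids)[plan$masked_positions] %in% v$wt_ids))
    masked <- masked + length(plan$masked_positions)
  }
  r_hat <- masked / (100 * 400)
  expect_lt(abs(r_hat - 0.15), 3 * sqrt(0.15 * 0.85 / (100 * 400)))
})

test_that("special tokens are never masked and plans are never empty", {
  v <- tiny_vocab
  cfg <- training_config(mask_rate = 0.01)
  set.seed(205)
  specials <- token_id(v, c("<cls>", "<pad>", "<eos>"))
  for (i in 1:200) {
    core <- random_token_ids(3)
    ids <- structure(c(specials[1], unclass(core), specials[2:3]),
                     class = "token_seq")
    plan <- sample_masking_plan(cfg, ids, v)
    expect_gte(length(plan$masked_positions), 1L)   # forced fallback
    expect_true(all(plan$masked_positions %in% 2:4))
  }
  expect_error(sample_masking_plan(cfg, integer(0), v), "empty")
})

test_that("masked-LM loss matches its closed forms", {
  plan1 <- list(masked_positions = 1L, targets = 0L)
  uniform <- matrix(0, 1, 50)
  expect_equal(mlm_loss(uniform, plan1)$mean, log(50), tolerance = 1e-12)
  # saturated logits: near-zero loss
  sat <- matrix(0, 1, 50); sat[1, 1] <- 1000
  expect_lt(mlm_loss(sat, plan1)$sum, 1e-10)
  # 3-class hand-computed softmax NLL
  l3 <- matrix(c(2, 0, -1), 1, 3)
  want <- -log(exp(2) / (exp(2) + 1 + exp(-1)))
  expect_equal(mlm_loss(l3, plan1)$sum, want, tolerance = 1e-12)
  # summed vs averaged accounting
  plan2 <- list(masked_positions = c(1L, 2L), targets = c(0L, 1L))
  two <- matrix(0, 2, 50)
  expect_equal(mlm_loss(two, plan2)$sum, 2 * log(50), tolerance = 1e-12)
  expect_equal(mlm_loss(two, plan2)$n, 2L)
  expect_error(mlm_loss(uniform, list(masked_positions = integer(0),
                                      targets = integer(0))),
               "at least one")
})

test_that("loss is invariant to the order sequences enter a batch", {
  set.seed(206)
  logits_a <- matrix(stats::rnorm(5 * 50), 5, 50)
  logits_b <- matrix(stats::rnorm(7 * 50), 7, 50)
  plan_a <- list(masked_positions = c(1L, 4L), targets = c(3L, 9L))
  plan_b <- list(masked_positions = c(2L, 5L, 6L), targets = c(1L, 8L, 30L))
  ab <- mlm_loss(logits_a, plan_a)$sum + mlm_loss(logits_b, plan_b)$sum
  ba <- mlm_loss(logits_b, plan_b)$sum + mlm_loss(logits_a, plan_a)$sum
  expect_identical(ab, ba)
})

test_that("crop_or_pad always returns the target length", {
  v <- tiny_vocab
  pad <- token_id(v, "<pad>")
  set.seed(207)
  short <- random_token_ids(10)
  out <- crop_or_pad(v, short, 1024L)
  expect_length(out, 1024L)
  expect_identical(unclass(out)[1:10], unclass(short))
  expect_true(all(unclass(out)[11:1024] == pad))
  exact <- random_token_ids(1024)
  expect_identical(unclass(crop_or_pad(v, exact, 1024L)), unclass(exact))
  # oversized input: output is a contiguous window of the original
  long <- random_token_ids(5000)
  for (i in 1:20) {
    win <- unclass(crop_or_pad(v, long, 1024L))
    expect_length(win, 1024L)
    hits <- which(unclass(long) == win[1L])
    ok <- any(vapply(hits, function(s)
      s + 1023L <= 5000L && identical(unclass(long)[s:(s + 1023L)], win),
      logical(1)))
    expect_true(ok)
  }
})

test_that("length-bucketed batching is shortest-first and a partition", {
  set.seed(208)
  b <- length_bucketed_batches(c(5, 6, 900, 901), batch_size = 2,
                               n_buckets = 2)
  expect_identical(sort(b[[1L]]), c(1L, 2L))
  # partition property over random datasets
  for (i in 1:50) {
    lens <- sample(5:500, sample(3:40, 1), replace = TRUE)
    bs <- length_bucketed_batches(lens, batch_size = 4, n_buckets = 3)
    expect_identical(sort(unlist(bs)), seq_along(lens))
    # every batch draws from one bucket, and buckets are fed shortest-first
    breaks <- unique(stats::quantile(lens, probs = seq(0, 1, length.out = 4)))
    bin_of <- vapply(bs, function(ix) {
      bins <- cut(lens[ix], breaks = breaks, include.lowest = TRUE,
                  labels = FALSE)
      expect_identical(length(unique(bins)), 1L)
      bins[1L]
    }, integer(1))
    expect_true(all(diff(bin_of) >= 0))
  }
  # single bucket degenerates to plain batching
  one <- length_bucketed_batches(rep(7, 10), batch_size = 3, n_buckets = 1)
  expect_length(one, 4L)
  # token budget shrinks batches for long sequences
  tb <- length_bucketed_batches(rep(100, 8), batch_size = 8,
                                n_buckets = 1, token_budget = 250)
  expect_true(all(vapply(tb, length, integer(1)) <= 2L))
  expect_error(length_bucketed_batches(integer(0), 2), "empty")
})

test_that("analytic gradients match finite differences through the whole model", {
  v <- tiny_vocab
  cfg <- lm_config(n_layers = 2L, model_dim = 8L, state_dim = 4L,
                   vocab_size = vocab_size(v))
  m <- ptm_lm(cfg, v, seed = 3)
  bk <- mock_backend(v, dim = 8L, seed = 5)
  tc <- training_config(max_length = 10L, seed = 2)
  set.seed(210)
  ids <- crop_or_pad(v, random_token_ids(8), 10L)
  plan <- sample_masking_plan(tc, ids, v)
  sg <- ptmlm:::.sequence_loss_grads(m$weights, m$config, v, bk, plan)
  flatw <- ptmlm:::.flatten_weights(m$weights)
  flatg <- ptmlm:::.flatten_weights(sg$grads)
  expect_identical(names(flatw), names(flatg))
  vecw <- unlist(flatw); vecg <- unlist(flatg)
  loss_at <- function(vec) {
    W <- m$weights; off <- 0L
    for (nm in names(flatw)) {
      n <- length(flatw[[nm]])
      val <- vec[off + seq_len(n)]; off <- off + n
      tmpl <- flatw[[nm]]
      if (!is.null(dim(tmpl))) val <- array(val, dim = dim(tmpl))
      W <- ptmlm:::.assign_path(W, nm, val)
    }
    f <- ptmlm:::.model_forward(W, m$config, v, plan$input_ids, bk)$hidden
    mlm_loss(lm_logits(W$head, f), plan)$sum
  }
  eps <- 1e-5
  # gate parameters in full, plus a random spread over everything else
  nm_of <- rep(names(flatw), vapply(flatw, length, integer(1)))
  gate_ix <- sample(which(startsWith(nm_of, "gate.")), 10L)
  other_ix <- sample(seq_along(vecw), 30L)
  for (i in c(gate_ix, other_ix)) {
    wp <- vecw; wp[i] <- wp[i] + eps
    wm <- vecw; wm[i] <- wm[i] - eps
    num <- (loss_at(wp) - loss_at(wm)) / (2 * eps)
    expect_lt(abs(num - vecg[i]) / max(1e-4, abs(num) + abs(vecg[i])),
              1e-4)
  }
})

test_that("training is seed-deterministic and the loss trends down", {
  v <- tiny_vocab
  dataset <- memorization_dataset()
  bk <- tiny_backend()
  tc <- training_config(max_length = 16L, batch_size = 20L, n_steps = 50L,
                        lr = 2e-3, seed = 7, log_every = 1L)
  m <- tiny_model(seed = 1)
  fit1 <- train_lm(m, dataset, bk, tc)
  fit2 <- train_lm(m, dataset, bk, tc)
  expect_identical(fit1$log, fit2$log)
  expect_identical(fit1$model$weights, fit2$model$weights)
  l <- fit1$log$loss
  ma <- stats::filter(l, rep(1 / 10, 10), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_lt(ma[length(ma)], ma[1L])                  # net decrease
  expect_lt(stats::lm(l ~ seq_along(l))$coefficients[2L], 0)  # negative trend
})
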