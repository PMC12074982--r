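test_that("metrics match hand-computed confusion-table oracles", {
  # perfect classifier
  perfect <- compute_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.1, 0.2))
  expect_true(all(unlist(perfect) == 1))
  # TP=2 FP=1 FN=1 TN=6 by construction
  y <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  s <- c(0.9, 0.8, 0.1, 0.7, 0.2, 0.2, 0.1, 0.1, 0.05, 0.0)
  m <- compute_metrics(y, s)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 2 / 3)
  mcc_brute <- (2 * 6 - 1 * 1) /
    sqrt((2 + 1) * (2 + 1) * (6 + 1) * (6 + 1))
  expect_equal(m$mcc, mcc_brute, tolerance = 1e-12)
})

test_that("AUROC equals the normalized pairwise-comparison statistic", {
  set.seed(50)
  y <- c(1, 0, 1, 0, 1, 0, 0, 1, 0, 0)
  s <- round(stats::runif(10), 2)
  m <- compute_metrics(y, s)
  pos <- s[y == 1]; neg <- s[y == 0]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(m$auroc, mean(pairs), tolerance = 1e-12)
  # cross-check against an independent implementation
  expect_equal(m$auroc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("AUPRC is the step-integrated average precision", {
  y <- c(1, 0, 1, 0)
  s <- c(0.9, 0.8, 0.7, 0.1)
  # descending: y = 1,0,1,0 -> precision at recall steps: 1/1, 2/3
  want <- 0.5 * 1 + 0.5 * (2 / 3)
  expect_equal(compute_metrics(y, s)$auprc, want, tolerance = 1e-12)
})

test_that("single-class labels flag the ranking metrics instead of zeroing them", {
  expect_warning(m <- compute_metrics(c(1, 1), c(0.2, 0.9)), "single-class")
  expect_true(is.na(m$auroc))
  expect_true(is.na(m$auprc))
})

test_that("random scores concentrate at chance level", {
  set.seed(51)
  n <- 300L
  aurocs <- replicate(200, {
    y <- stats::rbinom(n, 1, 0.3)
    s <- stats::runif(n)
    compute_metrics(y, s)$auroc
  })
  expect_lt(abs(mean(aurocs) - 0.5), 3 * stats::sd(aurocs) / sqrt(200))
})

test_that("the replicate protocol returns five seeded, reproducible rows", {
  set.seed(52)
  x <- matrix(stats::rnorm(200 * 6), 200, 6)
  ylin <- as.integer(x[, 1] + 0.5 * x[, 2] > 0)   # linearly separable
  tr <- 1:140; te <- 141:200
  rep1 <- fit_head(x[tr, ], ylin[tr], x[te, ], ylin[te], n_replicates = 5L)
  expect_identical(nrow(rep1$replicates), 5L)
  expect_length(rep1$mean, 7L)
  rep2 <- fit_head(x[tr, ], ylin[tr], x[te, ], ylin[te], n_replicates = 5L)
  expect_identical(rep1$replicates, rep2$replicates)
  # separable signal is learned
  expect_gte(rep1$mean[["accuracy"]], 0.95)
  expect_error(fit_head(x[tr, ], rep(1L, 140), x[te, ], ylin[te]),
               "single class")
})

test_that("label shuffling drives the head to chance AUROC", {
  set.seed(53)
  x <- matrix(stats::rnorm(200 * 6), 200, 6)
  y <- sample(rep(0:1, each = 100))
  tr <- 1:140; te <- 141:200
  rep <- fit_head(x[tr, ], y[tr], x[te, ], y[te], n_replicates = 3L)
  n1 <- sum(y[te] == 1); n0 <- sum(y[te] == 0)
  sigma <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(rep$mean[["auroc"]] - 0.5), 3 * sigma)
})

test_that("sequence embeddings pool over non-pad positions only", {
  m <- tiny_model(seed = 11)
  bk <- tiny_backend()
  set.seed(54)
  ids <- random_token_ids(10)
  res <- extract_embeddings(m, list(ids), backend = bk, level = "residue")
  expect_identical(dim(res[[1L]]), c(10L, 32L))
  pooled <- extract_embeddings(m, list(ids), backend = bk,
                               level = "sequence")
  expect_equal(drop(pooled), colMeans(res[[1L]]), tolerance = 1e-12)
  padded <- crop_or_pad(m$vocab, ids, 16L)
  pooled_pad <- extract_embeddings(m, list(padded), backend = bk,
                                   level = "sequence")
  expect_lt(max(abs(pooled - pooled_pad)), 1e-6)
})

test_that("zero-shot discovery ranks PTM logits at the masked position", {
  m <- tiny_model(seed = 12)
  bk <- tiny_backend()
  v <- m$vocab
  # crafted head: phosphoserine always wins
  ps <- token_id(v, "<Phosphoserine>")
  m$weights$head$W[] <- 0
  m$weights$head$b[] <- 0
  m$weights$head$b[ps + 1L] <- 5
  out <- zero_shot_ptm_discovery(m, "MSKS", 2L, backend = bk)
  expect_identical(out$token[1L], "<Phosphoserine>")
  # residue restriction: serine-compatible tokens only
  expect_setequal(out$token,
                  names(v$ptm_tokens)[v$ptm_tokens == "S"])
  # unrestricted ranking covers every PTM token exactly once
  full <- zero_shot_ptm_discovery(m, "MSKS", 2L, backend = bk,
                                  restrict_to_residue = FALSE)
  expect_setequal(full$token, names(v$ptm_tokens))
  expect_identical(anyDuplicated(full$token), 0L)
  expect_true(all(diff(full$logit) <= 0))
  # restriction identity versus the raw head logits
  ids <- encode_tokens(v, c("M", "<mask>", "K", "S"))
  h <- model_forward(m$weights, m$config, v, ids, bk)
  raw <- lm_logits(m$weights$head, h)[2L, ]
  expect_equal(out$logit[out$token == "<Phosphoserine>"],
               raw[ps + 1L], tolerance = 1e-12)
  expect_error(zero_shot_ptm_discovery(m, "MSKS", 9L, backend = bk),
               "outside sequence")
})

test_that("pair features concatenate pooled embeddings, modified first", {
  m <- tiny_model(seed = 13)
  bk <- tiny_backend()
  f_ab <- pair_task_features(m, "MSKV", "ACDY", backend = bk)
  expect_length(f_ab, 64L)
  f_aa <- pair_task_features(m, "MSKV", "MSKV", backend = bk)
  expect_identical(f_aa[1:32], f_aa[33:64])
  f_ba <- pair_task_features(m, "ACDY", "MSKV", backend = bk)
  expect_identical(f_ab, c(f_ba[33:64], f_ba[1:32]))
})
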