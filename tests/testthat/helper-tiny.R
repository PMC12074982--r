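# Shared tiny fixtures: default vocabulary, a desk-scale model, and a
# seeded mock backend. Built once per test run; everything is generated in
# code, nothing is read from disk.

tiny_vocab <- build_default_vocab()

tiny_model <- function(seed = 1L, model_dim = 32L, n_layers = 2L,
                       state_dim = 8L) {
  ptm_lm(lm_config(n_layers = n_layers, model_dim = model_dim,
                   state_dim = state_dim, preset = "tiny"),
         tiny_vocab, seed = seed)
}

tiny_backend <- function(dim = 32L, seed = 42L) {
  mock_backend(tiny_vocab, dim = dim, seed = seed)
}

# random mixed wild-type/PTM token id sequence (never pads/specials)
random_token_ids <- function(n, ptm_frac = 0.2, vocab = tiny_vocab) {
  pool_wt <- vocab$wt_ids
  pool_ptm <- vocab$ptm_ids
  ids <- ifelse(stats::runif(n) < ptm_frac,
                sample(pool_ptm, n, replace = TRUE),
                sample(pool_wt, n, replace = TRUE))
  structure(as.integer(ids), class = "token_seq")
}

# 20-sequence memorization corpus used by the learning-sanity checks
memorization_dataset <- function(vocab = tiny_vocab) {
  spec <- fixture_spec(n_sequences = 20, min_length = 16, max_length = 16,
                       ptm_rate = 0.1, seed = 3)
  seqs <- gen_sequences(spec)
  recs <- gen_ptm_records(spec, seqs, vocab)
  cur <- curate_dataset(seqs, recs, vocab, quiet = TRUE)
  toks <- lapply(names(seqs), function(a)
    if (!is.null(cur$sequences[[a]])) cur$sequences[[a]]
    else split_residues(seqs[[a]]))
  lapply(toks, function(t) encode_tokens(vocab, t))
}
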