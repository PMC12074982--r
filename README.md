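# ptmlm — PTM-aware protein language modeling in R

Post-translational modifications (PTMs) — phosphorylation, acetylation,
glycosylation and dozens more — reshape protein structure, function and
interactions, yet standard protein language models only see the 20 unmodified
amino acids. `ptmlm` is for computational biologists who want to model
*proteoforms*: it treats each annotated modification as a first-class token
(`<Phosphoserine>`, `<N6-acetyllysine>`, ...) alongside the wild-type
residues, and learns representations of mixed wild-type/PTM sequences with a
bidirectional selective state-space (Mamba-style) masked language model.

## The model

**Tokenization.** The vocabulary is 5 special tokens, the 20 amino acids
(D, N, E, K, V, Y, A, Q, M, I, T, L, R, F, G, C, S, P, H, W) and 25 named PTM
tokens taken from UniProt annotation names, each tied to the residue it
modifies (e.g. `<Phosphoserine>` → S). Curation maps tab-separated annotation
records `(accession, position, ptm_name, residue)` onto FASTA sequences by
substitution — never insertion — with residue-compatibility checks.

**Sequence layer.** Each direction runs a selective state-space recurrence
with input-dependent step size Δ, input map B and readout C (zero-order-hold
discretization of the transition, Euler form for the input):

    h_t = exp(Δ_t ⊙ A) h_{t−1} + (Δ_t B_t) x_t
    y_t = C_t · h_t + D_skip ⊙ x_t

wrapped in the usual block (RMSNorm pre-norm, expansion, causal depthwise
convolution, SiLU, multiplicative gate, output projection). A single
direction is causal; the bidirectional layer runs a forward block and a
backward block on the flipped sequence, concatenates the two hidden streams
and fuses them with a 2D→D linear map, while the residual streams are
averaged: `residual = 0.5 (residual_f + flip(residual_b))`.

**Gated fusion with a wild-type backend.** Wild-type tokens can additionally
be embedded by an external protein LM backend (PTM tokens are converted to
`<mask>` for the backend); the backend embedding `e` and the model's own
token embedding `p` are merged by a sigmoid gate

    g = σ(W [p; e] + b),   fused = p ⊙ g + e ⊙ (1 − g),

an elementwise convex combination. The backend is pluggable; the package
ships a deterministic mock backend so everything runs self-contained.

**Training.** Biased masked language modeling: with probability 0.8 a
standard pass masks 15% of positions; with probability 0.2 *all* PTM tokens
are masked plus 15% of wild-type tokens. The loss is the negative log
likelihood of the original tokens at masked positions, `L = −Σ_i log P(x_i |
x_masked)`, optimized with Adam (no weight decay) at a constant learning
rate, with sequences randomly cropped/padded to a fixed length and batched
shortest-first by length cluster.

**Downstream use.** Frozen embeddings (per-residue or mean-pooled) feed
classification heads with an n = 5 replicate protocol reporting accuracy,
precision, recall, F1, MCC, AUROC and AUPRC; zero-shot PTM discovery masks a
position and ranks the PTM-token logits there.

## Worked example

```r
library(ptmlm)
v <- build_default_vocab()
v
#> PTM-aware token vocabulary
#>   size: 50 tokens ( 5 special, 20 wild-type, 25 PTM )

recs <- ptm_records(c("P62993", "P62993"), c(2, 7),
                    c("<Phosphoserine>", "<N6-acetyllysine>"), c("S", "K"))
cur <- curate_dataset(c(P62993 = "MSEAIAKYDFKA"), recs, v)
#> curated 2/2 records onto 1/1 sequences (0 rejected)
cur$sequences$P62993
#>  [1] "M" "<Phosphoserine>" "E" "A" "I" "A" "<N6-acetyllysine>" "Y" "D" "F" "K" "A"

m  <- ptm_lm(lm_config(preset = "tiny"), v, seed = 1)
m
#> PTM-aware bidirectional state-space language model
#>   2 bidirectional layers, dim 32, state 8, vocab 50 (43,186 parameters)

bk  <- mock_backend(v, dim = 32)
emb <- predict(m, cur$sequences$P62993, backend = bk)   # 12 x 32 hidden states

head(zero_shot_ptm_discovery(m, "MSEAIAKYDFKA", 2, backend = bk), 3)
#>                                 token       logit
#>                       <Phosphoserine> -0.09369069
#>                      <N-acetylserine> -0.11952179
#>  <O-(pantetheine 4-phosphoryl)serine> -0.18292981
```

The discovery table ranks the serine-compatible PTM tokens by their logit at
the masked position; with a trained checkpoint the ranking reflects learned
context (this untrained example only illustrates the interface). Train with
`train_lm()`, save/load text checkpoints with `save_checkpoint()` /
`load_checkpoint()`, or drive everything from the shell via `exec/ptmlm`
(subcommands `fixtures`, `curate`, `train`, `embed`, `benchmark`,
`discover`).

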