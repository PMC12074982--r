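---
title: "PTM-aware language modeling: model, training procedure and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PTM-aware language modeling: model, training procedure and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmlm)
```

This vignette documents the science behind `ptmlm`: the model and its
assumptions, the parameters that matter, what the synthetic generators do
and do not emulate, and the numerical and design choices made where the
design was genuinely open. It states no empirical result beyond what the
test suite and `scripts/acceptance.R` themselves compute.

## The modeling problem

Proteins acquire post-translational modifications — phosphorylation,
acetylation, glycosylation, lipidation and many others — that change their
chemistry at specific residues. A language model over the 20 amino acids
cannot distinguish a phosphorylated serine from an unmodified one. `ptmlm`
extends the token alphabet with named PTM tokens (UniProt annotation names,
each bound to the wild-type residue it replaces) and models *proteoforms*:
sequences in which some positions carry a PTM token instead of an amino
acid.

Two ideas carry the architecture:

1. **Bidirectional selective state-space layers.** Each layer is a pair of
   Mamba-style blocks, one reading left-to-right, one reading the flipped
   sequence. Their hidden streams are concatenated and fused by a
   fully connected 2D→D map; their residual streams are averaged,
   `residual = 0.5 (residual_f + flip(residual_b))`. A single block is
   provably causal (the test suite probes this by finite differences), so
   the flip-and-fuse wrapper is what gives every position both contexts.

2. **Gated fusion with a wild-type backend.** A pre-trained wild-type
   protein LM can embed the unmodified part of the sequence (PTM tokens are
   converted to `<mask>` before the backend sees them). The backend
   embedding and the model's own token embedding are merged once, at the
   input layer, by an elementwise sigmoid gate — a convex combination whose
   mixing weight is itself a learned function of both embeddings.

## Sequence layer and its numerics

Within a block, token features are expanded (factor `expand`, default 2),
passed through a causal depthwise convolution (width 4) and SiLU, and then
through the selective scan

$$h_t = \exp(\Delta_t \odot A)\,h_{t-1} + (\Delta_t B_t)\,x_t,
\qquad y_t = C_t \cdot h_t + D_{\text{skip}} \odot x_t,$$

with per-token, input-dependent $\Delta_t$ (softplus-positive), $B_t$ and
$C_t$. Numerical choices:

* **Discretization.** Zero-order hold for the transition
  ($\bar A = \exp(\Delta A)$) and the simplified Euler form for the input
  ($\bar B = \Delta B$). The independent recurrence oracle in the tests is
  written against exactly this contract.
* **Stability.** $A$ is parameterized as $-\exp(A_{\log})$, so
  $|\exp(\Delta A)| \le 1$ elementwise for any positive step; the scan
  cannot diverge. $A_{\log}$ is initialized to $\log(1\ldots N)$ per
  channel, and $\Delta$'s bias so the initial step sizes are log-uniform in
  $[10^{-3}, 0.1]$ — the standard initialization for this layer family.
* **Normalization.** Pre-norm RMSNorm (ε = 1e-5) with the
  (hidden, residual) two-stream contract; the final layer's output is
  `rmsnorm(hidden + residual)`.
* **Gradients.** All backward passes are written by hand and verified
  against central finite differences through the entire model (embedding,
  gate, both scan directions, convolution, loss) at relative tolerance
  1e-4 in the test suite.

The reference scan is sequential by design: this package favors a
transparent, testable recurrence over fused or parallel-prefix kernels,
which are out of scope.

## Training procedure

Masked language modeling with a PTM bias. Per sequence:

* with probability `p_standard = 0.8`: mask each non-special position
  independently at rate `mask_rate = 0.15`;
* otherwise: mask **all** PTM positions, plus wild-type positions at 15%.
  PTM positions are removed from the wild-type pool first, so the 15% draw
  applies to wild-type tokens only, matching the stated procedure.

Masked positions are replaced by `<mask>` (no keep/random substitution
branch: the procedure says token masking, and the backend interface already
speaks `<mask>`). If a draw masks nothing, one uniformly chosen non-special
position is forced so the loss — the summed negative log likelihood at
masked positions, reported per-token-averaged as well — is always defined.
Special tokens are never maskable.

Sequences are randomly cropped (uniform window start) or end-padded to
`max_length` (1,024 at full scale), grouped into length clusters, and fed
shortest-first; an optional per-batch token budget implements dynamic
batching. The optimizer is Adam with no weight decay at a constant learning
rate (2e-4 at full scale). Pad positions carry zero fused embeddings and are
excluded from the loss; the scans still traverse them — a documented
limitation of the flip-based bidirectional design.

**Desk-scale defaults.** The shipped presets are `tiny` (2 bidirectional
layers, width 32, state 8 — used throughout the tests) and full-width
presets at 24 or 12 bidirectional layers × width 768: "24 layers" of a
bidirectional stack can be counted per bidirectional layer or per direction,
so both readings are available (`full-24x768`, `full-12x768`). Desk-scale
training runs in the tests use `max_length` 16, full-batch updates over a
20-sequence memorization corpus, 500 steps, and a constant learning rate of
2e-3 — the constant-rate regime scaled up for a model four orders of
magnitude smaller than the full configuration. The memorization check
(masked-token accuracy > 0.95) and the 50-step loss-trend check are
optimization sanity oracles, not statements about real-data performance.

## Gated fusion and the backend contract

The gate is vector-valued (one sigmoid per embedding dimension):
`g = σ(W [p; e] + b)`, `fused = p ⊙ g + e ⊙ (1 − g)`. Limits behave as
expected (saturated gate reproduces one branch exactly; zero weights give
the exact midpoint), and the output is always elementwise between the two
inputs. Fusion happens once at the input embedding — the published
`gated_fuse` consumes input ids, not per-layer states.

A backend is anything with `embed(ids) → [length × backend_dim]` and a
`dim`. When `backend_dim ≠ model_dim` a learned affine adapter bridges the
two (how the published full-scale system bridged 1280→768 is not stated;
a learned projection is the neutral choice). The package's `mock_backend()`
assigns each token a fixed unit-norm Gaussian vector from a seed: identical
tokens embed identically, embeddings are position-independent, and the whole
test suite runs against this mock. It emulates the *interface* of a
pre-trained protein LM, not its contextual knowledge — conclusions about
real wild-type embeddings require plugging in a real backend behind the same
contract.

## Synthetic data: what it does and does not emulate

The generators are pure functions of `(spec, seed)`:

* `gen_sequences()` — uniform random sequences over the 20 amino acids.
  Real proteins are not uniform (composition bias, domains, low-complexity
  regions); uniformity is chosen so that letter-frequency and masking-rate
  checks have exact binomial nulls.
* `gen_ptm_records()` — each residue compatible with at least one PTM token
  receives a record with probability `ptm_rate` (default 0.05, roughly the
  per-residue density implied by large annotation databases); the PTM type
  is drawn among residue-compatible tokens with skewed weights so that the
  two types that dominate real annotation sets (N-linked glycosylation of
  asparagine and phosphoserine) are up-weighted 8:1. Records are
  residue-compatible by construction, so strict curation accepts 100% —
  real annotation tables contain positional and isoform errors that the
  `skip` policy is designed to absorb.
* `gen_task()` — binary labels through a logistic link on the standardized
  PTM-token count (all types by default; optionally one chosen type), with
  `effect_size` the log-odds per standard deviation. Effect 0 severs the
  label–input link, giving exact chance-level nulls; the planted count is
  deliberately a *global* sequence property so that mean-pooled embeddings
  can recover it. Passing benchmarks on these tasks shows the harness is
  sound — heads learn real signal, stay at chance under nulls, and track
  effect size monotonically — not that the embeddings rival trained
  full-scale models on curated disease or druggability data.

The benchmark corpus used in the tests is 500 sequences of length 20–30 at
`ptm_rate` 0.3: short sequences keep the planted count from being diluted
by mean pooling, and the elevated rate gives the count a usable variance at
this corpus size.

## Open design points, resolved

* **Conflicting records** at one position: first in file order wins; the
  loser is reported as a conflict. Duplicates apply once.
* **Unknown residues** (B, Z, X, U, O) map to `<unk>` by default; a strict
  policy raises instead.
* **LM head** is untied from the input embedding table.
* **Threshold** for thresholded metrics is 0.5; ranking metrics are
  computed from raw scores. Single-class test labels make AUROC/AUPRC
  undefined: they are returned as `NA` with a warning, never silently 0.
* **Zero-shot discovery** restricts candidates to PTM tokens compatible
  with the wild-type residue at the queried position (PTMs are residue
  specific); the full-vocabulary ranking is a toggle.
* **Checkpoints** are JSON text with every array serialized as `%.17g`
  strings — plain text that round-trips IEEE doubles bit-exactly, which
  rounded decimal JSON numbers do not guarantee.
* **Default head** for benchmarks is a single-hidden-layer perceptron
  (`nnet`), width 16, 200 iterations, no weight decay — a deliberately
  plain stand-in for per-task tuned heads, behind a config object so any
  head can be swapped in.

## Known limitations

* The sequential scan is O(L) per layer in R loop steps; the package is a
  reference implementation for desk-scale experiments, not a training
  system for 650M-parameter models.
* The mock backend carries no evolutionary information; absolute benchmark
  numbers under the mock are not comparable to published full-scale
  results.
* Bidirectional flipping means pads are traversed (masked from the loss but
  visible to the scan); with heavily padded batches this wastes compute and
  can leak pad positions into hidden states. Keeping length clusters tight
  minimizes padding.
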