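#' @keywords internal
"_PACKAGE"

# Canonical special tokens, ESM-2 naming convention. <mask> is required for the
# wild-type backend interface; the remaining four follow the same convention.
.specials <- c("<cls>", "<pad>", "<eos>", "<unk>", "<mask>")

# The 20 wild-type amino-acid tokens, in the canonical published order.
.wt_tokens <- c("D", "N", "E", "K", "V", "Y", "A", "Q", "M", "I",
                "T", "L", "R", "F", "G", "C", "S", "P", "H", "W")

# Default PTM token set with the expected wild-type residue each one modifies.
# Token spellings keep the UniProt annotation names verbatim (including the
# horizontal ellipsis U+2026); the residue map is explicit data, never parsed
# from the token string at runtime.
.default_ptm_tokens <- c(
  "<N-linked (GlcNAc\u2026) asparagine>"      = "N",
  "<Pyrrolidone carboxylic acid>"             = "Q",
  "<Phosphoserine>"                           = "S",
  "<Phosphothreonine>"                        = "T",
  "<N-acetylalanine>"                         = "A",
  "<N-acetylmethionine>"                      = "M",
  "<N6-acetyllysine>"                         = "K",
  "<Phosphotyrosine>"                         = "Y",
  "<S-diacylglycerol cysteine>"               = "C",
  "<N6-(pyridoxal phosphate)lysine>"          = "K",
  "<N-acetylserine>"                          = "S",
  "<N6-carboxylysine>"                        = "K",
  "<N6-succinyllysine>"                       = "K",
  "<S-palmitoyl cysteine>"                    = "C",
  "<O-(pantetheine 4-phosphoryl)serine>"      = "S",
  "<Sulfotyrosine>"                           = "Y",
  "<O-linked (GalNAc\u2026) threonine>"       = "T",
  "<Omega-N-methylarginine>"                  = "R",
  "<N-myristoyl glycine>"                     = "G",
  "<4-hydroxyproline>"                        = "P",
  "<Asymmetric dimethylarginine>"             = "R",
  "<N5-methylglutamine>"                      = "Q",
  "<4-aspartylphosphate>"                     = "D",
  "<S-geranylgeranyl cysteine>"               = "C",
  "<4-carboxyglutamate>"                      = "E"
)

#' Build the mixed wild-type + PTM token vocabulary
#'
#' Constructs the default vocabulary: five special tokens (`<cls>`, `<pad>`,
#' `<eos>`, `<unk>`, `<mask>`), the 20 wild-type amino-acid tokens, and 25
#' named PTM tokens, each PTM token carrying the wild-type residue it is
#' compatible with (e.g. `<Phosphoserine>` modifies `S`). Token ids are
#' 0-based and assigned in this fixed order, so the default vocabulary always
#' has 50 tokens.
#'
#' @param extra_ptm_tokens optional named character vector or list of
#'   `name = expected_residue` pairs appended after the default PTM tokens.
#'   Names must be new; residues must be one of the 20 amino acids.
#' @return An object of class `ptm_vocab`: a list with `tokens` (ordered
#'   character vector; position `i` holds the token with id `i - 1`),
#'   `specials`, `wt_tokens`, `ptm_tokens` (named by token, value = expected
#'   residue), and the ids of each group.
#' @examples
#' v <- build_default_vocab()
#' vocab_size(v)            # 50
#' v$ptm_tokens[["<Phosphoserine>"]]  # "S"
#' @export
build_default_vocab <- function(extra_ptm_tokens = NULL) {
  ptm <- .default_ptm_tokens
  if (!is.null(extra_ptm_tokens)) {
    extra <- unlist(extra_ptm_tokens)
    if (is.null(names(extra)) || any(!nzchar(names(extra))))
      stop("extra_ptm_tokens must be named: name = expected residue")
    bad <- setdiff(extra, .wt_tokens)
    if (length(bad))
      stop("expected residue must be a wild-type amino acid, got: ",
           paste(bad, collapse = ", "))
    ptm <- c(ptm, extra)
  }
  tokens <- c(.specials, .wt_tokens, names(ptm))
  if (anyDuplicated(tokens))
    stop("duplicate token name: ",
         paste(unique(tokens[duplicated(tokens)]), collapse = ", "))
  v <- list(
    tokens     = tokens,
    specials   = .specials,
    wt_tokens  = .wt_tokens,
    ptm_tokens = ptm,
    special_ids = match(.specials, tokens) - 1L,
    wt_ids      = match(.wt_tokens, tokens) - 1L,
    ptm_ids     = match(names(ptm), tokens) - 1L
  )
  class(v) <- "ptm_vocab"
  v
}

#' @export
print.ptm_vocab <- function(x, ...) {
  cat("PTM-aware token vocabulary\n")
  cat("  size:", length(x$tokens), "tokens (",
      length(x$specials), "special,", length(x$wt_tokens), "wild-type,",
      length(x$ptm_tokens), "PTM )\n")
  invisible(x)
}

#' Vocabulary size
#' @param vocab a `ptm_vocab`
#' @return integer number of tokens
#' @export
vocab_size <- function(vocab) length(vocab$tokens)

#' Look up token ids
#' @param vocab a `ptm_vocab`
#' @param tokens character vector of token strings
#' @return 0-based integer ids (NA for unknown tokens)
#' @export
token_id <- function(vocab, tokens) match(tokens, vocab$tokens) - 1L

.mask_id <- function(vocab) token_id(vocab, "<mask>")
.pad_id  <- function(vocab) token_id(vocab, "<pad>")
.unk_id  <- function(vocab) token_id(vocab, "<unk>")

#' Encode token strings into a token sequence
#'
#' Matching is case-insensitive for PTM token names (canonical casing is
#' restored on decode); single-letter amino acids are matched as given.
#' Under the default `"lenient"` policy, unknown tokens (including the
#' ambiguous residue codes B, Z, X, U, O) are mapped to `<unk>`; `"strict"`
#' raises an error naming the first offending token.
#'
#' @param vocab a `ptm_vocab`
#' @param tokens character vector of token strings (possibly empty)
#' @param policy `"lenient"` or `"strict"`
#' @return an integer vector of 0-based ids of class `token_seq`
#' @examples
#' v <- build_default_vocab()
#' encode_tokens(v, c("M", "<Phosphoserine>", "K"))
#' @export
encode_tokens <- function(vocab, tokens, policy = c("lenient", "strict")) {
  policy <- match.arg(policy)
  if (length(tokens) == 0L)
    return(structure(integer(0), class = "token_seq"))
  ids <- match(tokens, vocab$tokens)
  miss <- is.na(ids)
  if (any(miss)) {
    # case-insensitive retry for multi-character (PTM / special) names
    ids[miss] <- match(tolower(tokens[miss]), tolower(vocab$tokens))
    miss <- is.na(ids)
  }
  if (any(miss)) {
    if (policy == "strict")
      stop("unknown token: '", tokens[which(miss)[1L]], "'")
    ids[miss] <- .unk_id(vocab) + 1L
  }
  structure(as.integer(ids - 1L), class = "token_seq")
}

#' Decode token ids back to token strings
#' @param vocab a `ptm_vocab`
#' @param ids integer vector of 0-based ids
#' @return character vector of canonical token strings
#' @export
decode_tokens <- function(vocab, ids) {
  ids <- as.integer(unclass(ids))
  if (any(ids < 0L | ids >= length(vocab$tokens)))
    stop("token id out of range for this vocabulary")
  vocab$tokens[ids + 1L]
}

#' Split a plain amino-acid string into single-letter tokens
#' @param sequence character scalar, e.g. `"MSKV"`
#' @return character vector of one-letter tokens
#' @export
split_residues <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) return(character(0))
  strsplit(sequence, "", fixed = TRUE)[[1L]]
}

#' Convert a token sequence to backend (wild-type LM) input tokens
#'
#' The wild-type embedding backend understands only wild-type and special
#' tokens, so every PTM token id is replaced by the `<mask>` id. All other
#' ids (wild-type, specials, existing masks, pads) pass through unchanged and
#' the length is preserved. The operation is idempotent.
#'
#' @param vocab a `ptm_vocab`
#' @param ids integer vector of 0-based token ids
#' @return integer vector of the same length with PTM ids masked
#' @export
to_backend_tokens <- function(vocab, ids) {
  out <- as.integer(unclass(ids))
  out[out %in% vocab$ptm_ids] <- .mask_id(vocab)
  structure(out, class = "token_seq")
}

#' Number of non-pad positions in a token sequence
#' @param vocab a `ptm_vocab`
#' @param ids token ids
#' @return integer count
#' @export
seq_length_nonpad <- function(vocab, ids) {
  sum(as.integer(unclass(ids)) != .pad_id(vocab))
}

#' Write a vocabulary to its on-disk form
#'
#' One token per line, UTF-8, no byte-order mark; the token on line `i` has
#' id `i - 1`. PTM tokens additionally get a sidecar line in
#' `<path>.residues` (`token<TAB>residue`) so the compatibility map survives
#' the round trip.
#'
#' @param vocab a `ptm_vocab`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_vocab <- function(vocab, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(vocab$tokens), con, useBytes = TRUE)
  rescon <- file(paste0(path, ".residues"), open = "wb")
  on.exit(close(rescon), add = TRUE)
  writeLines(enc2utf8(paste(names(vocab$ptm_tokens), vocab$ptm_tokens,
                            sep = "\t")), rescon, useBytes = TRUE)
  invisible(path)
}

#' Read a vocabulary from its on-disk form
#' @param path file written by [write_vocab()]
#' @return a `ptm_vocab`
#' @export
read_vocab <- function(path) {
  tokens <- readLines(path, encoding = "UTF-8")
  respath <- paste0(path, ".residues")
  if (!file.exists(respath))
    stop("missing residue sidecar file: ", respath)
  res <- utils::read.delim(respath, header = FALSE, sep = "\t",
                           quote = "", stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  ptm <- stats::setNames(res[[2L]], res[[1L]])
  specials <- intersect(.specials, tokens)
  wt <- intersect(.wt_tokens, tokens)
  v <- list(
    tokens = tokens, specials = specials, wt_tokens = wt,
    ptm_tokens = ptm,
    special_ids = match(specials, tokens) - 1L,
    wt_ids = match(wt, tokens) - 1L,
    ptm_ids = match(names(ptm), tokens) - 1L
  )
  class(v) <- "ptm_vocab"
  v
}

#' Read wild-type protein sequences from FASTA
#' @param path FASTA file (plain multi-line FASTA)
#' @return named character vector, names = accessions (first word of header)
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA: ", path)
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L)
  seqs
}

#' Write protein sequences to FASTA
#' @param seqs named character vector of sequences
#' @param path output path
#' @return `path`, invisibly
#' @export
write_protein_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}
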