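# Mapping experimentally-annotated PTM records onto wild-type sequences.
# Positions are 1-based in all user-facing tables (UniProt convention);
# any 0-based arithmetic stays internal.

#' Construct a table of PTM annotation records
#'
#' @param accession character vector of protein accessions
#' @param position 1-based integer positions
#' @param ptm_name PTM token names (must resolve in the vocabulary used later)
#' @param residue expected one-letter wild-type residue at the position
#' @return a `data.frame` with columns `accession`, `position`, `ptm_name`,
#'   `residue`
#' @export
ptm_records <- function(accession, position, ptm_name, residue) {
  if (any(position < 1L)) stop("positions are 1-based and must be >= 1")
  data.frame(accession = as.character(accession),
             position = as.integer(position),
             ptm_name = as.character(ptm_name),
             residue = as.character(residue),
             stringsAsFactors = FALSE)
}

#' Read PTM records from a tab-separated file
#'
#' Expects a header line `accession  position  ptm_name  residue`.
#' @param path TSV path
#' @return a records `data.frame` as from [ptm_records()]
#' @export
read_ptm_records <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("accession", "position", "ptm_name", "residue")
  if (!all(need %in% names(df)))
    stop("records table must have columns: ", paste(need, collapse = ", "))
  ptm_records(df$accession, df$position, df$ptm_name, df$residue)
}

#' Write PTM records to a tab-separated file
#' @param records records table
#' @param path output path
#' @return `path`, invisibly
#' @export
write_ptm_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Apply PTM records to one wild-type sequence
#'
#' Substitutes the PTM token for the wild-type residue at each record's
#' position. A record is accepted only if its position lies inside the
#' sequence and the sequence residue there equals both the record's stated
#' residue and the PTM token's expected residue; substitution never changes
#' the sequence length. Duplicated records (same position and PTM) are
#' applied once; a second, different PTM at an already-modified position is
#' rejected as a conflict (first record in file order wins).
#'
#' @param sequence wild-type amino-acid string
#' @param records records table (all rows for one accession)
#' @param vocab a `ptm_vocab`
#' @param policy `"skip"` (default): rejected records are reported but the
#'   sequence is still produced; `"strict"`: any rejection is an error.
#' @return list with `tokens` (character vector, mixed wild-type/PTM),
#'   `n_ptm` (accepted record count), and `rejections` (data.frame of
#'   rejected rows with a `reason` column)
#' @examples
#' v <- build_default_vocab()
#' r <- ptm_records("P1", 2, "<Phosphoserine>", "S")
#' apply_records("MSK", r, v)$tokens  # "M" "<Phosphoserine>" "K"
#' @export
apply_records <- function(sequence, records, vocab,
                          policy = c("skip", "strict")) {
  policy <- match.arg(policy)
  tokens <- split_residues(sequence)
  n <- length(tokens)
  if (length(unique(records$accession)) > 1L)
    stop("apply_records expects records for a single accession")
  reasons <- character(nrow(records))
  seen <- character(0)      # "position|ptm" keys already applied
  modified <- integer(0)    # positions already carrying a PTM token
  for (i in seq_len(nrow(records))) {
    pos <- records$position[i]
    ptm <- records$ptm_name[i]
    expected <- vocab$ptm_tokens[ptm]
    key <- paste0(pos, "|", ptm)
    if (is.na(expected)) {
      reasons[i] <- paste0("unknown PTM token '", ptm, "'")
    } else if (pos < 1L || pos > n) {
      reasons[i] <- paste0("position ", pos, " outside sequence of length ", n)
    } else if (key %in% seen) {
      reasons[i] <- "duplicate record"
    } else if (pos %in% modified) {
      reasons[i] <- paste0("conflicting PTM at already-modified position ", pos)
    } else if (tokens[pos] != expected) {
      reasons[i] <- paste0("residue mismatch at position ", pos,
                           ": expected ", expected, ", found ", tokens[pos])
    } else if (!is.na(records$residue[i]) && nzchar(records$residue[i]) &&
               records$residue[i] != tokens[pos]) {
      reasons[i] <- paste0("record residue ", records$residue[i],
                           " disagrees with sequence residue ", tokens[pos])
    } else {
      tokens[pos] <- ptm
      seen <- c(seen, key)
      modified <- c(modified, pos)
    }
  }
  rej <- records[nzchar(reasons), , drop = FALSE]
  if (nrow(rej)) rej$reason <- reasons[nzchar(reasons)]
  else rej$reason <- character(0)
  if (policy == "strict" && nrow(rej))
    stop("record rejected (", rej$reason[1L], ") for accession ",
         rej$accession[1L], " position ", rej$position[1L])
  list(tokens = tokens, n_ptm = length(modified), rejections = rej)
}

#' Curate a PTM sequence dataset from FASTA + annotation records
#'
#' Maps every record onto its sequence with [apply_records()] and emits one
#' modified token sequence per accession that received at least one accepted
#' record; accessions with no accepted record are dropped, and records whose
#' accession is absent from the FASTA are reported as unresolved. Output
#' order is deterministic (sorted by accession).
#'
#' @param sequences named character vector (accession -> wild-type sequence),
#'   e.g. from [read_protein_fasta()]
#' @param records records table across accessions
#' @param vocab a `ptm_vocab`
#' @param policy passed to [apply_records()]
#' @param quiet suppress the curation summary message
#' @return list of class `ptm_curation`: `sequences` (named list of token
#'   vectors), `n_ptm` (named integer), `summary` (counts), `rejections`
#'   (combined table incl. unresolved accessions)
#' @export
curate_dataset <- function(sequences, records, vocab,
                           policy = c("skip", "strict"), quiet = FALSE) {
  policy <- match.arg(policy)
  if (length(sequences) == 0L) stop("no input sequences")
  unresolved <- records[!records$accession %in% names(sequences), , drop = FALSE]
  if (nrow(unresolved)) unresolved$reason <- "accession not in FASTA"
  else unresolved$reason <- character(0)
  usable <- records[records$accession %in% names(sequences), , drop = FALSE]
  accs <- sort(unique(usable$accession))
  out <- list(); nptm <- integer(0); rejs <- list(unresolved)
  for (acc in accs) {
    res <- apply_records(sequences[[acc]],
                         usable[usable$accession == acc, , drop = FALSE],
                         vocab, policy)
    rejs[[length(rejs) + 1L]] <- res$rejections
    if (res$n_ptm > 0L) {
      out[[acc]] <- res$tokens
      nptm[acc] <- res$n_ptm
    }
  }
  rejections <- do.call(rbind, rejs)
  summary <- list(records_read = nrow(records),
                  records_accepted = sum(nptm),
                  records_rejected = nrow(rejections),
                  sequences_in = length(sequences),
                  sequences_emitted = length(out))
  if (!quiet)
    message(sprintf(
      "curated %d/%d records onto %d/%d sequences (%d rejected)",
      summary$records_accepted, summary$records_read,
      summary$sequences_emitted, summary$sequences_in,
      summary$records_rejected))
  structure(list(sequences = out, n_ptm = nptm, summary = summary,
                 rejections = rejections),
            class = "ptm_curation")
}

#' @export
print.ptm_curation <- function(x, ...) {
  s <- x$summary
  cat("PTM curation:", s$sequences_emitted, "modified sequences from",
      s$sequences_in, "inputs;", s$records_accepted, "of", s$records_read,
      "records accepted\n")
  invisible(x)
}

#' Write a curated token-sequence set to TSV
#'
#' Two columns: `accession` and the space-separated token strings.
#' @param curation a `ptm_curation`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_curated_tsv <- function(curation, path) {
  df <- data.frame(
    accession = names(curation$sequences),
    tokens = vapply(curation$sequences, paste, character(1), collapse = " "),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a curated token-sequence set from TSV
#' @param path file written by [write_curated_tsv()]
#' @return named list of token vectors
#' @export
read_curated_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  stats::setNames(strsplit(df$tokens, " ", fixed = TRUE), df$accession)
}

#' Project a mixed token sequence back to its wild-type sequence
#'
#' Replaces every PTM token by its expected wild-type residue; wild-type
#' tokens pass through. Applying the original records to this projection
#' reproduces the modified sequence (curation is idempotent in that sense).
#'
#' @param tokens character vector of mixed wild-type/PTM tokens
#' @param vocab a `ptm_vocab`
#' @return wild-type amino-acid string
#' @export
wildtype_projection <- function(tokens, vocab) {
  is_ptm <- tokens %in% names(vocab$ptm_tokens)
  tokens[is_ptm] <- vocab$ptm_tokens[tokens[is_ptm]]
  paste(tokens, collapse = "")
}
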