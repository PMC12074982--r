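# Checkpoints, run configuration, and the command-line dispatcher.
#
# Checkpoints are a versioned JSON container: a manifest (array name ->
# dims) plus the flattened values encoded as %.17g strings, which
# round-trips IEEE doubles bit-exactly through plain text.

.ckpt_version <- "1"

.flatten_weights <- function(w, prefix = "") {
  out <- list()
  keys <- names(w)
  if (is.null(keys)) keys <- as.character(seq_along(w))  # unnamed lists
  for (i in seq_along(w)) {
    v <- w[[i]]
    key <- if (nzchar(prefix)) paste0(prefix, ".", keys[i]) else keys[i]
    if (is.null(v)) next
    if (is.list(v)) out <- c(out, .flatten_weights(v, key))
    else out[[key]] <- v
  }
  out
}

.assign_path <- function(w, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1L]]
  assign_rec <- function(node, parts, value) {
    key <- parts[1L]
    if (grepl("^[0-9]+$", key)) key <- as.integer(key)  # unnamed list index
    if (length(parts) == 1L) { node[[key]] <- value; return(node) }
    node[[key]] <- assign_rec(node[[key]], parts[-1L], value)
    node
  }
  assign_rec(w, parts, value)
}

#' Save model weights (and config) to a text checkpoint
#'
#' @param model a `ptm_lm` (or a fit's `$model`)
#' @param path output file (JSON)
#' @return `path`, invisibly
#' @export
save_checkpoint <- function(model, path) {
  flat <- .flatten_weights(model$weights)
  manifest <- lapply(flat, function(v)
    if (is.matrix(v) || is.array(v)) dim(v) else length(v))
  values <- lapply(flat, function(v) sprintf("%.17g", as.numeric(v)))
  obj <- list(version = .ckpt_version,
              config = unclass(model$config[c("n_layers", "model_dim",
                                              "vocab_size", "backend_dim")]),
              ssm = unclass(model$config$ssm),
              manifest = manifest,
              values = values)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), path)
  invisible(path)
}

#' Load model weights from a text checkpoint
#'
#' Restores weights bit-exactly into a model with a matching configuration;
#' a mismatching manifest or configuration is a descriptive error.
#'
#' @param model a `ptm_lm` whose configuration the checkpoint must match
#' @param path file written by [save_checkpoint()]
#' @return the model with restored weights
#' @export
load_checkpoint <- function(model, path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("unreadable checkpoint ", path, ": ",
                         conditionMessage(e)))
  if (!identical(obj$version, .ckpt_version))
    stop("checkpoint version ", obj$version, " != supported ", .ckpt_version)
  for (f in c("n_layers", "model_dim", "vocab_size")) {
    if (!identical(as.integer(obj$config[[f]]),
                   as.integer(model$config[[f]])))
      stop("checkpoint/config mismatch on ", f, ": checkpoint has ",
           obj$config[[f]], ", model has ", model$config[[f]])
  }
  flat <- .flatten_weights(model$weights)
  missing <- setdiff(names(flat), names(obj$manifest))
  extra <- setdiff(names(obj$manifest), names(flat))
  if (length(missing) || length(extra))
    stop("checkpoint manifest mismatch; missing: [",
         paste(missing, collapse = ", "), "] unexpected: [",
         paste(extra, collapse = ", "), "]")
  w <- model$weights
  for (nm in names(flat)) {
    dims <- unlist(obj$manifest[[nm]])
    vals <- as.numeric(unlist(obj$values[[nm]]))
    tmpl <- flat[[nm]]
    if (length(vals) != length(tmpl))
      stop("checkpoint array ", nm, " has ", length(vals),
           " values, expected ", length(tmpl))
    v <- if (is.matrix(tmpl) || is.array(tmpl)) array(vals, dim = dims)
         else vals
    w <- .assign_path(w, nm, v)
  }
  model$weights <- w
  model
}

#' Read a run configuration (YAML key/value, with presets)
#'
#' Recognized keys mirror [lm_config()] and [training_config()]; a
#' `preset` key selects a named model preset.
#'
#' @param path YAML file
#' @return named list
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' Write a run configuration
#' @param config named list
#' @param path output YAML path
#' @return `path`, invisibly
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# --- CLI --------------------------------------------------------------------

.cli_usage <- "usage: ptmlm <fixtures|curate|train|embed|benchmark|discover> [options]
  fixtures  --out DIR [--n N] [--seed S]
  curate    --fasta F --records R --out FILE
  train     --data CURATED_TSV --out DIR [--steps N] [--seed S] [--max-len L]
  embed     --data CURATED_TSV --checkpoint CKPT --out FILE
  benchmark --data CURATED_TSV [--effect E] [--seed S] [--out FILE]
  discover  --seq AASTRING --pos P [--checkpoint CKPT]
  (all subcommands accept --help; --version prints the package version)"

.cli_args <- function(argv) {
  # parse --key value pairs into a named list
  out <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a)
    key <- substring(a, 3L)
    if (key %in% c("help", "version")) { out[[key]] <- TRUE; i <- i + 1L }
    else {
      if (i == length(argv)) stop("missing value for --", key)
      out[[key]] <- argv[i + 1L]; i <- i + 2L
    }
  }
  out
}

.cli_require <- function(opts, keys) {
  miss <- setdiff(keys, names(opts))
  if (length(miss))
    stop("missing required flag(s): ", paste0("--", miss, collapse = " "))
}

#' Command-line entry point
#'
#' Dispatches the subcommands `fixtures`, `curate`, `train`, `embed`,
#' `benchmark` and `discover`. Returns an exit status instead of calling
#' `quit()`, so it is directly testable; the installed `exec/ptmlm` script
#' forwards `commandArgs()` here.
#'
#' @param argv character vector of command-line arguments
#' @return integer exit status (0 ok, 1 runtime error, 2 usage error)
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0L || argv[1L] %in% c("--help", "help")) {
    cat(.cli_usage, "\n"); return(if (length(argv)) 0L else 2L)
  }
  if (argv[1L] == "--version") {
    cat(as.character(utils::packageVersion("ptmlm")), "\n"); return(0L)
  }
  cmd <- argv[1L]
  known <- c("fixtures", "curate", "train", "embed", "benchmark", "discover")
  if (!cmd %in% known) {
    message("unknown subcommand: ", cmd, "\n", .cli_usage); return(2L)
  }
  opts <- tryCatch(.cli_args(argv[-1L]), error = function(e) e)
  if (inherits(opts, "error")) {
    message(conditionMessage(opts), "\n", .cli_usage); return(2L)
  }
  if (isTRUE(opts$help)) { cat(.cli_usage, "\n"); return(0L) }
  status <- tryCatch({ .cli_dispatch(cmd, opts); 0L },
    usage_error = function(e) { message(conditionMessage(e)); 2L },
    error = function(e) { message("error: ", conditionMessage(e)); 1L })
  status
}

.usage_stop <- function(...) stop(structure(
  class = c("usage_error", "error", "condition"),
  list(message = paste0(...), call = NULL)))

.cli_dispatch <- function(cmd, opts) {
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  vocab <- build_default_vocab()
  switch(cmd,
    fixtures = {
      if (is.null(opts$out)) .usage_stop("fixtures requires --out")
      spec <- fixture_spec(n_sequences = num(opts$n, 50),
                           seed = num(opts$seed, 1))
      write_fixture_bundle(spec, opts$out, vocab)
      message("fixture bundle written to ", opts$out)
    },
    curate = {
      if (!all(c("fasta", "records", "out") %in% names(opts)))
        .usage_stop("curate requires --fasta --records --out")
      seqs <- read_protein_fasta(opts$fasta)
      recs <- read_ptm_records(opts$records)
      cur <- curate_dataset(seqs, recs, vocab, quiet = FALSE)
      write_curated_tsv(cur, opts$out)
    },
    train = {
      if (!all(c("data", "out") %in% names(opts)))
        .usage_stop("train requires --data --out")
      toks <- read_curated_tsv(opts$data)
      dataset <- lapply(toks, function(t) encode_tokens(vocab, t))
      maxlen <- as.integer(num(opts[["max-len"]], 64))
      tcfg <- training_config(n_steps = as.integer(num(opts$steps, 50)),
                              max_length = maxlen, batch_size = 8L,
                              seed = as.integer(num(opts$seed, 1)))
      model <- ptm_lm(lm_config(preset = "tiny"), vocab,
                      seed = tcfg$seed)
      backend <- mock_backend(vocab, dim = model$config$backend_dim)
      fit <- train_lm(model, dataset, backend, tcfg, quiet = FALSE)
      dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
      save_checkpoint(fit$model, file.path(opts$out, "checkpoint.json"))
      utils::write.csv(fit$log, file.path(opts$out, "metrics.csv"),
                       row.names = FALSE)
      write_run_config(unclass(tcfg), file.path(opts$out, "config.yaml"))
      message("checkpoint + metrics written to ", opts$out)
    },
    embed = {
      if (!all(c("data", "checkpoint", "out") %in% names(opts)))
        .usage_stop("embed requires --data --checkpoint --out")
      toks <- read_curated_tsv(opts$data)
      model <- load_checkpoint(ptm_lm(lm_config(preset = "tiny"), vocab),
                               opts$checkpoint)
      emb <- extract_embeddings(model, unname(toks), level = "sequence")
      utils::write.table(cbind(accession = names(toks), as.data.frame(emb)),
                         opts$out, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      message("embeddings written to ", opts$out)
    },
    benchmark = {
      if (is.null(opts$data)) .usage_stop("benchmark requires --data")
      toks <- read_curated_tsv(opts$data)
      spec <- fixture_spec(effect_size = num(opts$effect, 1),
                           seed = num(opts$seed, 1))
      task <- gen_task(spec, toks)
      model <- ptm_lm(lm_config(preset = "tiny"), vocab, seed = spec$seed)
      emb <- extract_embeddings(model, unname(task$tokens),
                                level = "sequence")
      tr <- task$split == "train"; te <- task$split == "test"
      rep <- fit_head(emb[tr, ], task$labels[tr], emb[te, ],
                      task$labels[te])
      print(rep)
      if (!is.null(opts$out)) {
        con <- file(opts$out, "w"); on.exit(close(con))
        for (i in seq_len(nrow(rep$replicates)))
          writeLines(jsonlite::toJSON(as.list(rep$replicates[i, ]),
                                      auto_unbox = TRUE, digits = NA), con)
      }
    },
    discover = {
      if (!all(c("seq", "pos") %in% names(opts)))
        .usage_stop("discover requires --seq --pos")
      model <- ptm_lm(lm_config(preset = "tiny"), vocab,
                      seed = as.integer(num(opts$seed, 1)))
      if (!is.null(opts$checkpoint))
        model <- load_checkpoint(model, opts$checkpoint)
      df <- zero_shot_ptm_discovery(model, opts$seq,
                                    as.integer(opts$pos))
      utils::write.table(format(df, digits = 6), row.names = FALSE,
                         quote = FALSE, sep = "\t")
    })
  invisible(NULL)
}
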