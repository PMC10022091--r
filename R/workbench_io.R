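# Delimited-text I/O for the two input tables, plus the command-line
# workbench that chains simulate -> featurize -> finetune-encoder -> split
# -> train -> evaluate. Comma vs tab is autodetected from the file
# extension; every run logs its seed and settings next to its outputs.

delim_for <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a drug-combination table
#'
#' Expects a delimited text file with header columns `drug_a_smiles`,
#' `drug_b_smiles`, `cell_line`, `label`. Every row is validated: labels
#' must be 0/1 and every SMILES must parse. A file with any invalid row is
#' rejected outright (no silent row dropping).
#'
#' @param path File path (`.csv` comma, `.tsv`/`.txt` tab).
#' @return data.frame of records, row order preserved.
#' @export
readSynergyTable <- function(path) {
  # comment.char must be off: '#' is a SMILES bond symbol (triple bond)
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          stringsAsFactors = FALSE, fill = FALSE,
                          comment.char = "", quote = "")
  req <- c("drug_a_smiles", "drug_b_smiles", "cell_line", "label")
  miss <- setdiff(req, colnames(df))
  if (length(miss) > 0L) {
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!(df$label %in% c(0L, 1L)))
  if (length(bad) > 0L) {
    stop("row ", bad[1L], ": label '", df$label[bad[1L]],
         "' is not 0/1", call. = FALSE)
  }
  for (col in c("drug_a_smiles", "drug_b_smiles")) {
    for (s in unique(df[[col]])) {
      ok <- tryCatch({canonicalSmiles(s); TRUE}, error = function(e) FALSE)
      if (!ok) {
        stop("row ", which(df[[col]] == s)[1L], ": invalid SMILES '", s,
             "' in column ", col, call. = FALSE)
      }
    }
  }
  df$label <- as.integer(df$label)
  df
}

#' Write a drug-combination table
#'
#' @param records data.frame (or [SynergyExperiment-class]) of records.
#' @param path Output path; delimiter from the extension.
#' @return `path`, invisibly.
#' @export
writeSynergyTable <- function(records, path) {
  df <- record_frame(records)
  utils::write.table(df, path, sep = delim_for(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a cell-line expression matrix
#'
#' First column: cell-line identifier; remaining columns: genes. Duplicate
#' identifiers and ragged rows are rejected.
#'
#' @param path File path.
#' @return Numeric matrix with cell-line rownames.
#' @export
readExpression <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          stringsAsFactors = FALSE, fill = FALSE,
                          comment.char = "", quote = "")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids) > 0L) {
    stop("duplicate cell-line identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values", call. = FALSE)
  rownames(m) <- ids
  m
}

#' Write a cell-line expression matrix
#'
#' @param expr Matrix with cell-line rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(expr, path) {
  df <- data.frame(cell_line = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = delim_for(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# ---- CLI -------------------------------------------------------------------

cli_usage <- paste(
  "usage: dualsyn <subcommand> [--key value ...]",
  "subcommands:",
  "  simulate          --out DIR [--seed N --n-records N --ratio R",
  "                    --label-noise E --n-drugs N --n-cell-lines N --n-genes N]",
  "  featurize         --dataset F --out F [--n-bits N]",
  "  finetune-encoder  --corpus F --out F [--epochs N --seed N --dim N]",
  "  split             --dataset F --scheme S --out F [--k N --seed N]",
  "  train             --dataset F --expression F --out DIR [--seed N",
  "                    --epochs N --d N --alpha A --dropout P --encoder F",
  "                    --plan F --fold N --no-attention --no-highway",
  "                    --no-smiles --no-fingerprint --no-rdrop]",
  "  evaluate          --model F --dataset F --expression F --out F",
  "                    [--plan F --fold N]",
  sep = "\n")

cli_flags <- c("--no-attention", "--no-highway", "--no-smiles",
               "--no-fingerprint", "--no-rdrop")

parse_cli_args <- function(args) {
  out <- list(flags = character(0))
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (a %in% cli_flags) {
      out$flags <- c(out$flags, a)
      i <- i + 1L
    } else if (startsWith(a, "--")) {
      if (i == length(args)) stop("flag ", a, " needs a value", call. = FALSE)
      out[[sub("^--", "", a)]] <- args[[i + 1L]]
      i <- i + 2L
    } else {
      stop("unknown argument '", a, "'", call. = FALSE)
    }
  }
  out
}

opt_num <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
}

opt_int <- function(opts, key, default) as.integer(opt_num(opts, key, default))

opt_chr <- function(opts, key, default = NULL) {
  v <- opts[[key]]
  if (is.null(v)) default else v
}

need_opt <- function(opts, key) {
  v <- opts[[key]]
  if (is.null(v)) stop("missing required option --", key, call. = FALSE)
  v
}

write_run_log <- function(dir, subcommand, seed, settings) {
  jsonlite::write_json(
    list(subcommand = subcommand, seed = seed, settings = settings,
         package_version = as.character(utils::packageVersion("dualsyn")),
         r_version = R.version.string),
    file.path(dir, paste0(subcommand, "_log.json")),
    auto_unbox = TRUE, digits = NA)
}

#' Command-line workbench
#'
#' Dispatches one subcommand (`simulate`, `featurize`, `finetune-encoder`,
#' `split`, `train`, `evaluate`) on a character vector of arguments, exactly
#' as the `inst/cli/dualsyn.R` wrapper does from a shell. Every run writes a
#' JSON log (seed, settings, versions) next to its outputs.
#'
cli_allowed <- list(
  "simulate" = c("out", "seed", "n-records", "ratio", "label-noise",
                 "n-drugs", "n-cell-lines", "n-genes"),
  "featurize" = c("dataset", "out", "n-bits"),
  "finetune-encoder" = c("corpus", "out", "epochs", "seed", "dim"),
  "split" = c("dataset", "scheme", "out", "k", "seed"),
  "train" = c("dataset", "expression", "out", "seed", "epochs", "d",
              "heads", "alpha", "dropout", "lr", "batch-size", "encoder",
              "plan", "fold"),
  "evaluate" = c("model", "dataset", "expression", "out", "plan", "fold"))

#' @param args Character vector: subcommand followed by `--key value` pairs.
#' @return Integer exit status, 0 on success; validation failures print a
#'   message and return 1.
#' @export
runCli <- function(args) {
  status <- tryCatch({
    if (length(args) < 1L) stop(cli_usage, call. = FALSE)
    sub <- args[[1L]]
    opts <- parse_cli_args(args[-1L])
    if (!is.null(cli_allowed[[sub]])) {
      unknown <- setdiff(names(opts), c("flags", cli_allowed[[sub]]))
      if (length(unknown) > 0L) {
        stop("unknown option(s) for ", sub, ": --",
             paste(unknown, collapse = " --"), call. = FALSE)
      }
      if (sub != "train" && length(opts$flags) > 0L) {
        stop("flag(s) ", paste(opts$flags, collapse = " "),
             " only apply to train", call. = FALSE)
      }
    }
    switch(sub,
           "simulate" = cli_simulate(opts),
           "featurize" = cli_featurize(opts),
           "finetune-encoder" = cli_finetune(opts),
           "split" = cli_split(opts),
           "train" = cli_train(opts),
           "evaluate" = cli_evaluate(opts),
           stop("unknown subcommand '", sub, "'\n", cli_usage, call. = FALSE))
    0L
  }, error = function(e) {
    message("dualsyn error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

cli_simulate <- function(opts) {
  out <- need_opt(opts, "out")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- opt_int(opts, "seed", 1L)
  exp <- generateSynergyDataset(
    nDrugs = opt_int(opts, "n-drugs", 25L),
    nCellLines = opt_int(opts, "n-cell-lines", 10L),
    nGenes = opt_int(opts, "n-genes", 100L),
    nRecords = opt_int(opts, "n-records", 2000L),
    ratio = opt_num(opts, "ratio", 0.4),
    labelNoise = opt_num(opts, "label-noise", 0.05),
    seed = seed)
  writeSynergyTable(exp, file.path(out, "dataset.csv"))
  writeExpression(exprMatrix(exp), file.path(out, "expression.csv"))
  tr <- groundTruth(exp)
  jsonlite::write_json(tr[c("wFingerprint", "wExpression", "threshold",
                            "realizedRatio", "labelNoise")],
                       file.path(out, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write_run_log(out, "simulate", seed, opts[names(opts) != "flags"])
}

cli_featurize <- function(opts) {
  df <- readSynergyTable(need_opt(opts, "dataset"))
  n_bits <- opt_int(opts, "n-bits", 2048L)
  drugs <- unique(c(df$drug_a_smiles, df$drug_b_smiles))
  fp <- fingerprintMatrix(drugs, nBits = n_bits)
  out <- need_opt(opts, "out")
  utils::write.table(data.frame(molecule = drugs, fp, check.names = FALSE),
                     out, sep = delim_for(out), row.names = FALSE,
                     quote = FALSE)
  write_run_log(dirname(out), "featurize", NA, list(n_bits = n_bits))
}

cli_finetune <- function(opts) {
  corpus_path <- need_opt(opts, "corpus")
  corpus <- if (grepl("\\.(csv|tsv)$", corpus_path)) {
    df <- readSynergyTable(corpus_path)
    unique(c(df$drug_a_smiles, df$drug_b_smiles))
  } else {
    readLines(corpus_path)
  }
  seed <- opt_int(opts, "seed", 1L)
  enc <- smilesEncoder(encoderConfig(dim = opt_int(opts, "dim", 64L),
                                     seed = seed))
  ft <- finetuneEncoder(enc, corpus, epochs = opt_int(opts, "epochs", 3L),
                        batchSize = min(16L, length(corpus)), seed = seed)
  out <- need_opt(opts, "out")
  saveRDS(ft$encoder, out)
  jsonlite::write_json(ft$encoder$config, paste0(out, ".config.json"),
                       auto_unbox = TRUE, digits = NA)
  write_run_log(dirname(out), "finetune-encoder", seed,
                list(epochs = opt_int(opts, "epochs", 3L),
                     final_loss = utils::tail(ft$trace, 1L)))
}

cli_split <- function(opts) {
  df <- readSynergyTable(need_opt(opts, "dataset"))
  scheme <- need_opt(opts, "scheme")
  k <- opt_int(opts, "k", 5L)
  seed <- opt_int(opts, "seed", 1L)
  plan <- switch(scheme,
                 stratified = stratifiedKfold(df, k, seed),
                 drug_pair = leaveDrugPairOut(df, k, seed),
                 drug = leaveDrugOut(df, k, seed),
                 cell_line = leaveCellLineOut(df, k, seed),
                 stop("unknown scheme '", scheme, "'", call. = FALSE))
  out <- need_opt(opts, "out")
  jsonlite::write_json(list(scheme = scheme, k = k, seed = seed,
                            folds = folds(plan)),
                       out, auto_unbox = TRUE, digits = NA)
  write_run_log(dirname(out), "split", seed, list(scheme = scheme, k = k))
}

read_plan_fold <- function(opts) {
  plan <- jsonlite::read_json(need_opt(opts, "plan"), simplifyVector = TRUE)
  fold <- opt_int(opts, "fold", 1L)
  if (fold < 1L || fold > length(plan$folds$train)) {
    stop("fold ", fold, " out of range", call. = FALSE)
  }
  list(train = plan$folds$train[[fold]], test = plan$folds$test[[fold]])
}

cli_train <- function(opts) {
  df <- readSynergyTable(need_opt(opts, "dataset"))
  expr <- readExpression(need_opt(opts, "expression"))
  exp <- SynergyExperiment(df, expr)
  seed <- opt_int(opts, "seed", 1L)
  cfg <- trainConfig(
    d = opt_int(opts, "d", 32L),
    heads = opt_int(opts, "heads", 2L),
    dropout = opt_num(opts, "dropout", 0.1),
    alpha = opt_num(opts, "alpha", 1),
    lr = opt_num(opts, "lr", 1e-3),
    batchSize = opt_int(opts, "batch-size", 32L),
    epochs = opt_int(opts, "epochs", 10L),
    seed = seed,
    useAttention = !("--no-attention" %in% opts$flags),
    useHighway = !("--no-highway" %in% opts$flags),
    useSmiles = !("--no-smiles" %in% opts$flags),
    useFingerprint = !("--no-fingerprint" %in% opts$flags),
    useRdrop = !("--no-rdrop" %in% opts$flags))
  encoder <- if (!is.null(opts$encoder)) readRDS(opts$encoder) else NULL
  train_idx <- if (!is.null(opts$plan)) read_plan_fold(opts)$train else NULL
  out <- need_opt(opts, "out")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  model <- trainSynergyModel(exp, encoder, cfg, trainIdx = train_idx)
  saveRDS(model, file.path(out, "model.rds"))
  jsonlite::write_json(model$trace, file.path(out, "trace.json"),
                       digits = NA)
  write_run_log(out, "train", seed, cfg)
}

cli_evaluate <- function(opts) {
  model <- readRDS(need_opt(opts, "model"))
  df <- readSynergyTable(need_opt(opts, "dataset"))
  expr <- readExpression(need_opt(opts, "expression"))
  exp <- SynergyExperiment(df, expr)
  idx <- if (!is.null(opts$plan)) read_plan_fold(opts)$test else NULL
  report <- evaluateModel(model, exp, idx = idx)
  out <- need_opt(opts, "out")
  writeMetricReport(report, out)
  write_run_log(dirname(out), "evaluate", NA,
                list(n = sum(confusion(report))))
}
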