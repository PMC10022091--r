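test_that("dataset tables round-trip field-for-field", {
  exp <- small_experiment()
  f <- withr::local_tempfile(fileext = ".csv")
  writeSynergyTable(exp, f)
  back <- readSynergyTable(f)
  expect_identical(back, records(exp))
  # tab-delimited variant
  ft <- withr::local_tempfile(fileext = ".tsv")
  writeSynergyTable(records(exp), ft)
  expect_identical(readSynergyTable(ft), records(exp))
})

test_that("dataset validation names the missing column and the bad row", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- records(small_experiment())[1:5, ]
  writeSynergyTable(df, f)
  ok <- readSynergyTable(f)
  expect_identical(nrow(ok), 5L)

  writeLines("drug_a_smiles,drug_b_smiles,cell_line\nCCO,CCN,c1", f)
  expect_error(readSynergyTable(f), "label")

  writeLines(c("drug_a_smiles,drug_b_smiles,cell_line,label",
               "CCO,CCN,c1,1", "CCO,CCN,c1,2"), f)
  expect_error(readSynergyTable(f), "row 2")

  writeLines(c("drug_a_smiles,drug_b_smiles,cell_line,label",
               "CCO,CCN,c1,1", "C$X,CCN,c1,0"), f)
  expect_error(readSynergyTable(f), "invalid SMILES")
})

test_that("expression matrices round-trip and reject duplicates", {
  expr <- generateExpression(3, 5, seed = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  writeExpression(expr, f)
  back <- readExpression(f)
  expect_equal(back, expr)
  expect_identical(dim(readExpression(f)), c(3L, 5L))

  dup <- rbind(expr, expr[1, , drop = FALSE])
  writeExpression(dup, f)
  expect_error(readExpression(f), "duplicate")
})

test_that("the CLI chains simulate, split, train and evaluate", {
  dir <- withr::local_tempdir()
  data_dir <- file.path(dir, "data")
  expect_identical(runCli(c("simulate", "--out", data_dir, "--seed", "3",
                            "--n-records", "120", "--n-drugs", "10",
                            "--n-cell-lines", "5", "--n-genes", "20")), 0L)
  expect_true(file.exists(file.path(data_dir, "dataset.csv")))
  expect_true(file.exists(file.path(data_dir, "expression.csv")))

  plan_file <- file.path(dir, "plan.json")
  expect_identical(runCli(c("split", "--dataset",
                            file.path(data_dir, "dataset.csv"),
                            "--scheme", "stratified", "--k", "4",
                            "--seed", "3", "--out", plan_file)), 0L)
  expect_true(file.exists(plan_file))

  run_dir <- file.path(dir, "run")
  expect_identical(runCli(c("train", "--dataset",
                            file.path(data_dir, "dataset.csv"),
                            "--expression",
                            file.path(data_dir, "expression.csv"),
                            "--out", run_dir, "--seed", "3",
                            "--epochs", "1", "--d", "8",
                            "--plan", plan_file, "--fold", "1")), 0L)
  expect_true(file.exists(file.path(run_dir, "model.rds")))

  metrics_file <- file.path(dir, "metrics.json")
  expect_identical(runCli(c("evaluate", "--model",
                            file.path(run_dir, "model.rds"),
                            "--dataset", file.path(data_dir, "dataset.csv"),
                            "--expression",
                            file.path(data_dir, "expression.csv"),
                            "--plan", plan_file, "--fold", "1",
                            "--out", metrics_file)), 0L)
  got <- jsonlite::read_json(metrics_file, simplifyVector = TRUE)
  expect_true(all(c("metrics", "counts") %in% names(got)))
})

test_that("the CLI fails cleanly on bad input", {
  expect_identical(suppressMessages(runCli(c("nonsense"))), 1L)
  expect_identical(suppressMessages(runCli(c("simulate", "--bogus"))), 1L)
  # unknown keys are rejected, not silently ignored
  expect_identical(suppressMessages(runCli(c("simulate", "--bogus", "5",
                                             "--out", tempfile()))), 1L)
  expect_identical(suppressMessages(runCli(c("simulate", "--no-rdrop",
                                             "--out", tempfile()))), 1L)
  expect_identical(
    suppressWarnings(suppressMessages(runCli(c("train", "--dataset",
                                               "missing.csv")))), 1L)
})

test_that("evaluating against mismatched expression dimensions fails clearly", {
  dir <- withr::local_tempdir()
  exp <- small_experiment()
  m <- trainSynergyModel(exp, tiny_encoder(),
                         trainConfig(d = 8L, epochs = 1L, seed = 2L))
  model_file <- file.path(dir, "model.rds")
  saveRDS(m, model_file)
  data_file <- file.path(dir, "dataset.csv")
  writeSynergyTable(exp, data_file)
  other_expr <- generateExpression(5, 7, seed = 99)
  rownames(other_expr) <- rownames(exprMatrix(exp))
  expr_file <- file.path(dir, "expr.csv")
  writeExpression(other_expr, expr_file)
  status <- suppressMessages(runCli(c("evaluate", "--model", model_file,
                                      "--dataset", data_file,
                                      "--expression", expr_file,
                                      "--out", file.path(dir, "m.json"))))
  expect_identical(status, 1L)
})

test_that("fingerprint and encoder subcommands write their artifacts", {
  dir <- withr::local_tempdir()
  data_file <- file.path(dir, "dataset.csv")
  writeSynergyTable(small_experiment(), data_file)
  fp_file <- file.path(dir, "fp.csv")
  expect_identical(runCli(c("featurize", "--dataset", data_file,
                            "--out", fp_file, "--n-bits", "128")), 0L)
  fp <- utils::read.csv(fp_file, check.names = FALSE)
  expect_identical(ncol(fp), 129L)   # molecule key + bits

  enc_file <- file.path(dir, "encoder.rds")
  expect_identical(runCli(c("finetune-encoder", "--corpus", data_file,
                            "--out", enc_file, "--epochs", "1",
                            "--dim", "16", "--seed", "2")), 0L)
  expect_true(file.exists(enc_file))
  expect_true(file.exists(paste0(enc_file, ".config.json")))
})
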