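toy_records <- function(pairs, lines = NULL) {
  data.frame(drug_a_smiles = vapply(pairs, `[`, "", 1L),
             drug_b_smiles = vapply(pairs, `[`, "", 2L),
             cell_line = if (is.null(lines)) "c1" else lines,
             label = rep_len(c(1L, 0L), length(pairs)),
             stringsAsFactors = FALSE)
}

test_that("stratified k-fold balances classes and partitions the index set", {
  df <- data.frame(drug_a_smiles = "CCO", drug_b_smiles = "CCN",
                   cell_line = "c1",
                   label = c(rep(1L, 5), rep(0L, 10)))
  plan <- stratifiedKfold(df, k = 5L, seed = 3L)
  sizes <- vapply(folds(plan), function(f) length(f$test), integer(1))
  expect_equal(sizes, rep(3L, 5))
  pos <- vapply(folds(plan), function(f) sum(df$label[f$test]), integer(1))
  expect_lte(diff(range(pos)), 1L)
  tests <- sort(unlist(lapply(folds(plan), `[[`, "test")))
  expect_identical(tests, 1:15)
  expect_identical(folds(stratifiedKfold(df, 5L, 3L)), folds(plan))
  # a class with fewer than k members cannot be stratified over k folds
  expect_error(stratifiedKfold(df[c(1:4, 6:15), ], k = 5L), "fewer than k")
})

test_that("per-fold positive fraction tracks the global fraction", {
  exp <- small_experiment()
  df <- records(exp)
  global <- mean(df$label)
  plan <- stratifiedKfold(df, k = 5L, seed = 9L)
  for (f in folds(plan)) {
    frac <- mean(df$label[f$test])
    expect_lte(abs(frac - global), 1 / length(f$test))
  }
})

test_that("leave-drug-pair-out co-assigns unordered and respelled pairs", {
  # (A,B) and (B,A) spelled differently must share a fold
  df <- toy_records(list(c("CCO", "CCN"), c("NCC", "OCC"), c("CCO", "CCC"),
                         c("CCC", "CCN"), c("CCO", "CCCC"), c("CCN", "CCCC")),
                    lines = "c1")
  plan <- leaveDrugPairOut(df, k = 3L, seed = 2L)
  for (f in folds(plan)) {
    in_test_1 <- 1L %in% f$test
    in_test_2 <- 2L %in% f$test
    expect_identical(in_test_1, in_test_2)
  }
  expect_identical(auditSplitPlan(plan, df), 0L)
})

test_that("leave-drug-out matches the enumerated toy case", {
  # drugs {A,B,C}; holding out A tests (A,B) and (A,C), trains on (B,C)
  df <- toy_records(list(c("CCO", "CCN"), c("CCO", "CCC"), c("CCN", "CCC")))
  plan <- leaveDrugOut(df, k = 3L, seed = 1L)
  held <- heldOutEntities(plan)
  canA <- canonicalSmiles("CCO")
  fold_a <- which(vapply(held, function(h) canA %in% h, logical(1)))
  f <- folds(plan)[[fold_a]]
  expect_setequal(f$test, c(1L, 2L))
  expect_identical(f$train, 3L)
  # a record with two drugs is tested in both their folds
  tested_in <- vapply(folds(plan), function(f) 3L %in% f$test, logical(1))
  expect_identical(sum(tested_in), 2L)
  # every record is in exactly one of train/test per fold
  for (f in folds(plan)) {
    expect_setequal(c(f$train, f$test), 1:3)
  }
  expect_identical(auditSplitPlan(plan, df), 0L)
})

test_that("leave-drug-out errors when a fold's training set empties", {
  df <- toy_records(list(c("CCO", "CCN"), c("CCO", "CCC")))
  expect_error(leaveDrugOut(df, k = 3L, seed = 1L), "empty training set")
})

test_that("leave-cell-line-out holds out whole lines deterministically", {
  df <- toy_records(rep(list(c("CCO", "CCN")), 6),
                    lines = rep(c("c1", "c2"), each = 3))
  plan <- leaveCellLineOut(df, k = 2L, seed = 5L)
  for (i in 1:2) {
    f <- folds(plan)[[i]]
    held <- heldOutEntities(plan)[[i]]
    expect_true(all(df$cell_line[f$test] %in% held))
    expect_true(!any(df$cell_line[f$train] %in% held))
  }
  expect_identical(auditSplitPlan(plan, df), 0L)
  # determinism across reruns, distinct seeds differ
  exp <- small_experiment()
  p1 <- leaveCellLineOut(exp, k = 4L, seed = 8L)
  p2 <- leaveCellLineOut(exp, k = 4L, seed = 8L)
  expect_identical(heldOutEntities(p1), heldOutEntities(p2))
})

test_that("all four schemes pass the leakage audit on a synthetic dataset", {
  exp <- small_experiment()
  expect_identical(auditSplitPlan(stratifiedKfold(exp, 5L, 1L), exp), 0L)
  expect_identical(auditSplitPlan(leaveDrugPairOut(exp, 5L, 1L), exp), 0L)
  expect_identical(auditSplitPlan(leaveDrugOut(exp, 4L, 1L), exp), 0L)
  expect_identical(auditSplitPlan(leaveCellLineOut(exp, 5L, 1L), exp), 0L)
})

test_that("distinct seeds give distinct grouped plans", {
  exp <- small_experiment()
  plans <- lapply(1:4, function(s) heldOutEntities(leaveDrugPairOut(exp, 5L, s)))
  expect_gt(length(unique(plans)), 1L)
})
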