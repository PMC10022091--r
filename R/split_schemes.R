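# Cross-validation protocols with machine-checkable no-leakage guarantees.
#
# Four schemes: stratified random k-fold, and grouped k-fold over drug
# pairs, single drugs, or cell lines. Grouping always uses canonical SMILES
# so that two spellings of one molecule cannot leak across folds. Grouped
# k-fold with k = number of entities gives true one-entity-at-a-time
# leave-one-out.

record_frame <- function(records) {
  if (is(records, "SynergyExperiment")) records(records) else records
}

# deterministic per-scheme RNG without touching the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

new_split_plan <- function(folds, scheme, k, seed, n, heldout = list()) {
  new("SplitPlan", folds = folds, scheme = scheme, k = as.integer(k),
      seed = as.integer(seed), n = as.integer(n), heldout = heldout)
}

#' Stratified random k-fold split
#'
#' Shuffles each class independently and deals records round-robin so the
#' per-fold synergistic:antagonistic ratio matches the global one as closely
#' as integer counts allow; positive counts across folds differ by at most 1.
#'
#' @param records A [SynergyExperiment-class] or its record data.frame.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; the same seed reproduces the plan.
#' @return A [SplitPlan-class].
#' @export
stratifiedKfold <- function(records, k = 5L, seed = 1L) {
  df <- record_frame(records)
  n <- nrow(df)
  stopifnot(k >= 2L)
  for (cl in c(0L, 1L)) {
    if (sum(df$label == cl) < k) {
      stop("class ", cl, " has fewer than k = ", k, " members", call. = FALSE)
    }
  }
  assign_fold <- integer(n)
  with_seed(seed, {
    for (cl in c(0L, 1L)) {
      idx <- sample(which(df$label == cl))
      assign_fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds <- lapply(seq_len(k), function(f) {
    list(train = which(assign_fold != f), test = which(assign_fold == f))
  })
  new_split_plan(folds, "stratified", k, seed, n)
}

canonical_pair_key <- function(df) {
  ca <- canonicalSmiles(df$drug_a_smiles)
  cb <- canonicalSmiles(df$drug_b_smiles)
  paste(pmin(ca, cb), pmax(ca, cb), sep = "||")
}

grouped_plan <- function(df, groups, k, seed, scheme) {
  ug <- sort(unique(groups))
  if (length(ug) < k) {
    stop("only ", length(ug), " distinct ", scheme,
         " entities for k = ", k, " folds", call. = FALSE)
  }
  gf <- integer(length(ug))
  with_seed(seed, gf[sample.int(length(ug))] <- rep_len(seq_len(k), length(ug)))
  names(gf) <- ug
  gf
}

#' Leave-drug-pair-out split
#'
#' Groups records by the unordered pair of canonical molecules, so (A,B) and
#' (B,A) — and any respelling — always land on the same side of a fold.
#'
#' @inheritParams stratifiedKfold
#' @return A [SplitPlan-class].
#' @export
leaveDrugPairOut <- function(records, k = 5L, seed = 1L) {
  df <- record_frame(records)
  key <- canonical_pair_key(df)
  gf <- grouped_plan(df, key, k, seed, "drug-pair")
  folds <- lapply(seq_len(k), function(f) {
    test <- which(gf[key] == f)
    list(train = setdiff(seq_len(nrow(df)), test), test = test)
  })
  new_split_plan(folds, "drug_pair", k, seed, nrow(df),
                 heldout = lapply(seq_len(k), function(f) names(gf)[gf == f]))
}

#' Leave-drug-out split
#'
#' Partitions the distinct canonical drugs into k groups; a fold's test set
#' is every record containing at least one held-out drug, its training set
#' every record containing none. Records pairing two held-out drugs stay in
#' the test set. A record can therefore be tested in up to two folds (one
#' per constituent drug); within each fold train and test still partition
#' the dataset.
#'
#' @inheritParams stratifiedKfold
#' @return A [SplitPlan-class].
#' @export
leaveDrugOut <- function(records, k = 5L, seed = 1L) {
  df <- record_frame(records)
  ca <- canonicalSmiles(df$drug_a_smiles)
  cb <- canonicalSmiles(df$drug_b_smiles)
  gf <- grouped_plan(df, c(ca, cb), k, seed, "drug")
  folds <- lapply(seq_len(k), function(f) {
    test <- which(gf[ca] == f | gf[cb] == f)
    train <- setdiff(seq_len(nrow(df)), test)
    if (length(train) == 0L) {
      stop("fold ", f, " has an empty training set: every record contains ",
           "a held-out drug; reduce k or enlarge the dataset", call. = FALSE)
    }
    list(train = train, test = test)
  })
  new_split_plan(folds, "drug", k, seed, nrow(df),
                 heldout = lapply(seq_len(k), function(f) names(gf)[gf == f]))
}

#' Leave-cell-line-out split
#'
#' Partitions cell lines into k groups; each fold tests all records of its
#' held-out lines and trains on the rest, so the model never sees the
#' expression profile of a test line during training.
#'
#' @inheritParams stratifiedKfold
#' @return A [SplitPlan-class].
#' @export
leaveCellLineOut <- function(records, k = 5L, seed = 1L) {
  df <- record_frame(records)
  gf <- grouped_plan(df, df$cell_line, k, seed, "cell-line")
  folds <- lapply(seq_len(k), function(f) {
    test <- which(gf[df$cell_line] == f)
    list(train = setdiff(seq_len(nrow(df)), test), test = test)
  })
  new_split_plan(folds, "cell_line", k, seed, nrow(df),
                 heldout = lapply(seq_len(k), function(f) names(gf)[gf == f]))
}

#' Exhaustive leakage audit of a split plan
#'
#' Scans every fold for held-out grouping entities — unordered canonical
#' drug pairs (`drug_pair`), canonical drugs (`drug`), or cell lines
#' (`cell_line`) — occurring anywhere in that fold's training records. For
#' `stratified` plans it instead checks that test folds partition the index
#' set.
#'
#' @param plan A [SplitPlan-class].
#' @param records The records the plan was built from.
#' @return Number of leaked entities found, summed over folds (0 = clean).
#' @export
auditSplitPlan <- function(plan, records) {
  df <- record_frame(records)
  stopifnot(nrow(df) == plan@n)
  if (scheme(plan) == "stratified") {
    tests <- sort(unlist(lapply(folds(plan), `[[`, "test")))
    return(as.integer(!identical(tests, seq_len(plan@n))))
  }
  key <- switch(scheme(plan),
    drug_pair = list(canonical_pair_key(df)),
    drug = {
      ca <- canonicalSmiles(df$drug_a_smiles)
      cb <- canonicalSmiles(df$drug_b_smiles)
      list(ca, cb)
    },
    cell_line = list(df$cell_line),
    stop("unknown scheme", call. = FALSE))
  fl <- folds(plan)
  held <- heldOutEntities(plan)
  leaks <- 0L
  for (i in seq_along(fl)) {
    train_ent <- unique(unlist(lapply(key, function(k) k[fl[[i]]$train])))
    leaks <- leaks + length(intersect(held[[i]], train_ent))
  }
  leaks
}
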