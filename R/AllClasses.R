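#' @import methods
NULL

#' SynergyExperiment: labeled drug-pair records plus cell-line expression
#'
#' The central data container: a table of drug-combination observations
#' (drug A SMILES, drug B SMILES, cell-line identifier, binary synergy label
#' with 1 = synergistic, 0 = antagonistic) together with the gene-expression
#' matrix of the cell lines (rows = cell lines, columns = genes). Validity
#' requires every record's cell line to be present in the expression matrix,
#' strictly binary labels and finite expression values.
#'
#' @slot records data.frame with columns `drug_a_smiles`, `drug_b_smiles`,
#'   `cell_line`, `label`.
#' @slot expression numeric matrix, rownames are cell-line identifiers.
#' @slot truth list; for synthetic data, the planted rule parameters.
#' @export
setClass("SynergyExperiment",
         representation(records = "data.frame",
                        expression = "matrix",
                        truth = "list"),
         prototype(truth = list()))

setValidity("SynergyExperiment", function(object) {
  req <- c("drug_a_smiles", "drug_b_smiles", "cell_line", "label")
  miss <- setdiff(req, colnames(object@records))
  if (length(miss) > 0L) {
    return(paste("records missing column(s):", paste(miss, collapse = ", ")))
  }
  lab <- object@records$label
  if (!all(lab %in% c(0L, 1L))) return("labels must be 0 or 1")
  if (is.null(rownames(object@expression))) {
    return("expression matrix must have cell-line rownames")
  }
  if (anyDuplicated(rownames(object@expression)) > 0L) {
    return("duplicate cell-line identifiers in expression matrix")
  }
  unknown <- setdiff(unique(object@records$cell_line),
                     rownames(object@expression))
  if (length(unknown) > 0L) {
    return(paste("cell line(s) absent from expression matrix:",
                 paste(unknown, collapse = ", ")))
  }
  if (!all(is.finite(object@expression))) {
    return("expression matrix contains non-finite values")
  }
  TRUE
})

#' Construct a SynergyExperiment
#'
#' @param records data.frame of labeled drug-pair observations.
#' @param expression cell-line-by-gene numeric matrix with rownames.
#' @param truth optional list of generator ground-truth parameters.
#' @return A [SynergyExperiment-class] object.
#' @export
SynergyExperiment <- function(records, expression, truth = list()) {
  records$label <- as.integer(records$label)
  new("SynergyExperiment", records = as.data.frame(records),
      expression = expression, truth = truth)
}

#' @describeIn SynergyExperiment-class the record table
#' @param x,object A `SynergyExperiment`.
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @export
setMethod("records", "SynergyExperiment", function(x) x@records)

#' @describeIn SynergyExperiment-class the expression matrix
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))

#' @export
setMethod("exprMatrix", "SynergyExperiment", function(x) x@expression)

#' @describeIn SynergyExperiment-class unique SMILES over both drug columns
#' @export
setGeneric("drugLibrary", function(x) standardGeneric("drugLibrary"))

#' @export
setMethod("drugLibrary", "SynergyExperiment", function(x) {
  unique(c(x@records$drug_a_smiles, x@records$drug_b_smiles))
})

#' @describeIn SynergyExperiment-class generator ground truth (may be empty)
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @export
setMethod("groundTruth", "SynergyExperiment", function(x) x@truth)

#' @export
setMethod("show", "SynergyExperiment", function(object) {
  r <- object@records
  cat("SynergyExperiment with", nrow(r), "records\n")
  cat("  drugs:", length(unique(c(r$drug_a_smiles, r$drug_b_smiles))),
      " cell lines:", length(unique(r$cell_line)),
      " genes:", ncol(object@expression), "\n")
  cat("  synergistic:antagonistic =", sum(r$label == 1L), ":",
      sum(r$label == 0L), "\n")
})

#' SplitPlan: cross-validation folds with a leakage-safe grouping scheme
#'
#' @slot folds list of `list(train =, test =)` integer index vectors.
#' @slot scheme one of `"stratified"`, `"drug_pair"`, `"drug"`, `"cell_line"`.
#' @slot k number of folds.
#' @slot seed integer seed the plan was built from.
#' @slot n number of records the plan indexes into.
#' @slot heldout per-fold character vectors of held-out grouping entities
#'   (canonical pair keys, canonical drugs, or cell lines); empty for
#'   stratified plans.
#' @export
setClass("SplitPlan",
         representation(folds = "list", scheme = "character",
                        k = "integer", seed = "integer", n = "integer",
                        heldout = "list"),
         prototype(heldout = list()))

setValidity("SplitPlan", function(object) {
  for (f in object@folds) {
    if (!all(c("train", "test") %in% names(f))) {
      return("each fold needs train and test indices")
    }
    if (length(intersect(f$train, f$test)) > 0L) {
      return("train and test overlap within a fold")
    }
    if (any(c(f$train, f$test) < 1L) || any(c(f$train, f$test) > object@n)) {
      return("fold indices out of range")
    }
  }
  TRUE
})

#' @describeIn SplitPlan-class list of per-fold train/test index pairs
#' @param x,object A `SplitPlan`.
#' @export
setGeneric("folds", function(x) standardGeneric("folds"))

#' @export
setMethod("folds", "SplitPlan", function(x) x@folds)

#' @describeIn SplitPlan-class the split scheme tag
#' @export
setGeneric("scheme", function(x) standardGeneric("scheme"))

#' @export
setMethod("scheme", "SplitPlan", function(x) x@scheme)

#' @describeIn SplitPlan-class per-fold held-out grouping entities
#' @export
setGeneric("heldOutEntities", function(x) standardGeneric("heldOutEntities"))

#' @export
setMethod("heldOutEntities", "SplitPlan", function(x) x@heldout)

#' @export
setMethod("show", "SplitPlan", function(object) {
  cat("SplitPlan (", object@scheme, "), k = ", object@k,
      ", n = ", object@n, ", seed = ", object@seed, "\n", sep = "")
  sizes <- vapply(object@folds, function(f) length(f$test), integer(1))
  cat("  test-fold sizes:", paste(sizes, collapse = ", "), "\n")
})

#' MetricReport: the nine-metric evaluation summary
#'
#' Holds ACC, BACC, Prec, Rec, F1, ROC_AUC, MCC, Kappa and AP together with
#' the confusion counts they derive from.
#'
#' @slot metrics named numeric vector of the nine metrics.
#' @slot counts named integer vector `TP`, `TN`, `FP`, `FN`.
#' @export
setClass("MetricReport",
         representation(metrics = "numeric", counts = "integer"))

.metric_order <- c("ACC", "BACC", "Prec", "Rec", "F1",
                   "ROC_AUC", "MCC", "Kappa", "AP")

setValidity("MetricReport", function(object) {
  if (!all(.metric_order %in% names(object@metrics))) {
    return("metrics must contain all nine named values")
  }
  if (!all(c("TP", "TN", "FP", "FN") %in% names(object@counts))) {
    return("counts must name TP, TN, FP, FN")
  }
  m <- object@metrics
  unit <- c("ACC", "BACC", "Prec", "Rec", "F1", "ROC_AUC", "AP")
  if (any(m[unit] < -1e-12 | m[unit] > 1 + 1e-12, na.rm = TRUE)) {
    return("unit-interval metric out of [0,1]")
  }
  if (any(abs(m[c("MCC", "Kappa")]) > 1 + 1e-12, na.rm = TRUE)) {
    return("MCC/Kappa out of [-1,1]")
  }
  TRUE
})

#' @describeIn MetricReport-class named metric vector in canonical order
#' @param x,object A `MetricReport`.
#' @export
setGeneric("metrics", function(x) standardGeneric("metrics"))

#' @export
setMethod("metrics", "MetricReport", function(x) x@metrics[.metric_order])

#' @describeIn MetricReport-class the confusion counts
#' @export
setGeneric("confusion", function(x) standardGeneric("confusion"))

#' @export
setMethod("confusion", "MetricReport", function(x) x@counts)

#' @export
setMethod("show", "MetricReport", function(object) {
  m <- object@metrics[.metric_order]
  cat("MetricReport (TP=", object@counts["TP"], " TN=", object@counts["TN"],
      " FP=", object@counts["FP"], " FN=", object@counts["FN"], ")\n",
      sep = "")
  print(round(m, 4))
})
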