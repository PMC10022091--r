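# Seeded synthetic corpora emulating the structure of public drug-combination
# screens plus cell-line expression: a SMILES library from a small template
# grammar, a dense Gaussian expression matrix, and labeled drug-pair records
# carrying a planted, learnable synergy rule
#   score(i, j, c) = w_fp * Tanimoto(fp_i, fp_j) + w_expr * <u_c, v> + noise,
# thresholded to hit a target synergistic:antagonistic ratio and then
# label-flipped at a small noise rate. Both the fingerprint term and the
# expression term carry signal, so input-ablation experiments have a planted
# direction: removing fingerprints removes the dominant term.

.mol_substituents <- c("F", "Cl", "Br", "O", "N", "OC", "C#N",
                       "C(=O)O", "C(=O)N")
.mol_rings <- c("", "c1ccccc1", "C1CCCCC1")

one_template_molecule <- function() {
  len <- sample(2:6, 1L)
  parts <- rep("C", len)
  nsub <- sample(0:2, 1L)
  if (nsub > 0L) {
    for (p in sample.int(len, nsub)) {
      parts[p] <- paste0("C(", sample(.mol_substituents, 1L), ")")
    }
  }
  ring <- sample(.mol_rings, 1L, prob = c(0.5, 0.3, 0.2))
  paste0(paste(parts, collapse = ""), ring)
}

#' Generate a library of distinct valid SMILES
#'
#' Draws molecules from a template grammar (alkyl chains of length 2-6 with
#' 0-2 halogen/hydroxyl/amine/methoxy/nitrile/carboxyl/amide substituents
#' and an optional benzene or cyclohexane ring), keeping only strings that
#' are distinct as canonical molecules. Every output parses and fingerprints
#' without error.
#'
#' @param n Number of molecules.
#' @param seed Integer seed; same seed, same library.
#' @return Character vector of `n` SMILES strings.
#' @export
generateMolecules <- function(n, seed = 1L) {
  stopifnot(n >= 1L)
  with_seed(seed, {
    out <- character(0)
    seen <- character(0)
    attempts <- 0L
    while (length(out) < n) {
      attempts <- attempts + 1L
      if (attempts > 200L * n) {
        stop("template grammar exhausted before reaching n = ", n,
             " distinct molecules", call. = FALSE)
      }
      s <- one_template_molecule()
      can <- tryCatch(canonicalSmiles(s), error = function(e) NA_character_)
      if (is.na(can) || can %in% seen) next
      seen <- c(seen, can)
      out <- c(out, s)
    }
    out
  })
}

#' Generate a cell-line gene-expression matrix
#'
#' Each cell line gets an independent Gaussian signature (per-gene means
#' drawn once per line) with additive measurement noise, giving dense,
#' finite, line-distinguishable profiles.
#'
#' @param nCellLines,nGenes Matrix dimensions.
#' @param seed Integer seed.
#' @param signatureSd,noiseSd Standard deviations of the line signature and
#'   of the additive noise.
#' @return Numeric matrix (`nCellLines` x `nGenes`) with cell-line rownames.
#' @export
generateExpression <- function(nCellLines, nGenes, seed = 1L,
                               signatureSd = 1, noiseSd = 0.25) {
  stopifnot(nCellLines >= 1L, nGenes >= 1L)
  with_seed(seed, {
    sig <- matrix(stats::rnorm(nCellLines * nGenes, sd = signatureSd),
                  nCellLines, nGenes)
    m <- sig + matrix(stats::rnorm(nCellLines * nGenes, sd = noiseSd),
                      nCellLines, nGenes)
    rownames(m) <- sprintf("CL%03d", seq_len(nCellLines))
    colnames(m) <- sprintf("g%04d", seq_len(nGenes))
    m
  })
}

#' Generate a labeled synthetic synergy dataset with a planted rule
#'
#' Samples distinct (drug pair, cell line) triples, scores each with
#' `wFingerprint * z(Tanimoto) + wExpression * z(<expression, v>) + noise`
#' (both signal components z-scored across the dataset so the weights set
#' their relative strength directly), thresholds the score at the quantile
#' that realizes the target synergistic:antagonistic ratio, and finally
#' flips each label independently with probability `labelNoise`.
#'
#' @param nDrugs,nCellLines,nGenes,nRecords Corpus dimensions.
#' @param ratio Target positive:negative ratio (e.g. 0.4 or 1.5).
#' @param labelNoise Label flip probability, in \[0, 0.5).
#' @param seed Integer seed controlling molecules, expression, sampling,
#'   noise and flips.
#' @param wFingerprint,wExpression Planted weights of the Tanimoto and
#'   expression components.
#' @param noiseSd Pre-threshold score noise.
#' @param nBits Fingerprint length used by the rule.
#' @return A [SynergyExperiment-class]; `groundTruth()` returns the rule
#'   parameters (weights, gene weight vector, threshold, realized ratio).
#' @export
generateSynergyDataset <- function(nDrugs = 25L, nCellLines = 10L,
                                   nGenes = 100L, nRecords = 2000L,
                                   ratio = 0.4, labelNoise = 0.05,
                                   seed = 1L, wFingerprint = 1.5,
                                   wExpression = 1.0, noiseSd = 0.4,
                                   nBits = 2048L) {
  stopifnot(ratio > 0, nRecords >= 1L)
  if (labelNoise < 0 || labelNoise >= 0.5) {
    stop("labelNoise must lie in [0, 0.5)", call. = FALSE)
  }
  drugs <- generateMolecules(nDrugs, seed = seed + 11L)
  expr <- generateExpression(nCellLines, nGenes, seed = seed + 23L)
  n_pairs <- nDrugs * (nDrugs - 1L) / 2L
  if (n_pairs * nCellLines < nRecords) {
    stop("cannot draw ", nRecords, " distinct (pair, cell line) triples ",
         "from ", n_pairs, " pairs x ", nCellLines, " lines", call. = FALSE)
  }
  fps <- fingerprintMatrix(drugs, nBits = nBits)
  pairs <- utils::combn(nDrugs, 2L)
  tani <- apply(pairs, 2L, function(ij) tanimoto(fps[ij[1L], ], fps[ij[2L], ]))
  with_seed(seed + 37L, {
    v <- stats::rnorm(nGenes)
    line_term <- as.numeric(expr %*% v) / sqrt(nGenes)
    triple_idx <- sample.int(n_pairs * nCellLines, nRecords)
    pair_id <- ((triple_idx - 1L) %% n_pairs) + 1L
    line_id <- ((triple_idx - 1L) %/% n_pairs) + 1L
    t_comp <- scale(tani[pair_id])[, 1L]
    c_comp <- scale(line_term[line_id])[, 1L]
    score <- wFingerprint * t_comp + wExpression * c_comp +
      stats::rnorm(nRecords, sd = noiseSd)
    pos_frac <- ratio / (1 + ratio)
    theta <- stats::quantile(score, probs = 1 - pos_frac, names = FALSE)
    label <- as.integer(score > theta)
    realized <- sum(label) / max(sum(label == 0L), 1L)
    if (abs(realized - ratio) / ratio > 0.10) {
      stop("threshold calibration failed: realized ratio ",
           round(realized, 3), " vs target ", ratio, call. = FALSE)
    }
    flip <- stats::runif(nRecords) < labelNoise
    label[flip] <- 1L - label[flip]
    swap <- stats::runif(nRecords) < 0.5
    a <- ifelse(swap, pairs[2L, pair_id], pairs[1L, pair_id])
    b <- ifelse(swap, pairs[1L, pair_id], pairs[2L, pair_id])
    rec <- data.frame(drug_a_smiles = drugs[a],
                      drug_b_smiles = drugs[b],
                      cell_line = rownames(expr)[line_id],
                      label = label,
                      stringsAsFactors = FALSE)
    SynergyExperiment(rec, expr,
                      truth = list(wFingerprint = wFingerprint,
                                   wExpression = wExpression,
                                   geneWeights = v, threshold = theta,
                                   realizedRatio = realized,
                                   labelNoise = labelNoise,
                                   tanimoto = tani[pair_id],
                                   lineTerm = line_term[line_id]))
  })
}
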