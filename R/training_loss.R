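# Prediction head and the R-drop training objective. Every sample is passed
# through the fusion network twice with independent dropout masks; the loss
# is the averaged cross-entropy of the two predictions plus alpha times the
# symmetric Bernoulli KL divergence between them. Both terms are computed in
# logit space for numerical stability.

#' Binary cross-entropy
#'
#' `-[y log(p) + (1 - y) log(1 - p)]`. Probabilities on the boundary are an
#' error: no clamping is done here (the training path works from logits,
#' where no clamping is needed).
#'
#' @param prob Predicted probability, strictly inside (0, 1).
#' @param y Observed label, 0 or 1.
#' @return Non-negative loss.
#' @examples
#' crossEntropy(0.5, 1)   # log(2)
#' @export
crossEntropy <- function(prob, y) {
  stopifnot(all(y %in% c(0, 1)), length(prob) == length(y))
  if (any(prob <= 0 | prob >= 1)) {
    stop("probability outside (0, 1)", call. = FALSE)
  }
  -(y * log(prob) + (1 - y) * log(1 - prob))
}

#' Symmetric Bernoulli KL divergence (R-drop penalty)
#'
#' Treats each probability as a two-outcome distribution (p, 1-p) and
#' returns `(KL(p1 || p2) + KL(p2 || p1)) / 2`: symmetric, non-negative, and
#' zero exactly when the two predictions agree.
#'
#' @param p1,p2 Probabilities strictly inside (0, 1).
#' @return Non-negative penalty.
#' @examples
#' rdropKl(0.9, 0.6)
#' @export
rdropKl <- function(p1, p2) {
  if (any(c(p1, p2) <= 0 | c(p1, p2) >= 1)) {
    stop("probability outside (0, 1)", call. = FALSE)
  }
  kl <- function(a, b) a * log(a / b) + (1 - a) * log((1 - a) / (1 - b))
  (kl(p1, p2) + kl(p2, p1)) / 2
}

#' Combined R-drop training objective
#'
#' `L = 1/2 (CE(p1, y) + CE(p2, y)) + alpha * KLsym(p1, p2)`.
#'
#' @param p1,p2 The two dropout-pass probabilities.
#' @param y Label, 0 or 1.
#' @param alpha Non-negative KL weight.
#' @return List with `L_cross`, `L_KL` and `L`.
#' @export
totalLoss <- function(p1, p2, y, alpha = 1) {
  if (alpha < 0) stop("alpha must be non-negative", call. = FALSE)
  l_cross <- (crossEntropy(p1, y) + crossEntropy(p2, y)) / 2
  l_kl <- rdropKl(p1, p2)
  list(L_cross = l_cross, L_KL = l_kl, L = l_cross + alpha * l_kl)
}

#' Binarize probabilities
#'
#' Threshold boundary is assigned to the positive class: `1` iff
#' `prob >= threshold`.
#'
#' @param prob Probabilities in \[0, 1\].
#' @param threshold Decision threshold, default 0.5.
#' @return Integer 0/1 vector.
#' @export
binarize <- function(prob, threshold = 0.5) {
  stopifnot(all(prob >= 0 & prob <= 1))
  as.integer(prob >= threshold)
}

#' Prediction-head parameters
#'
#' @param width Fused feature width (5d).
#' @param seed Seed for initialization.
#' @return List with LayerNorm scale/shift and the final linear layer.
#' @export
newHeadParams <- function(width, seed = 1L) {
  with_seed(seed, list(ln_g = rep(1, width), ln_b = rep(0, width),
                       w = stats::rnorm(width, sd = 0.02), b = 0))
}

#' Prediction head
#'
#' Sums the two fusion paths (`m_x = m_vec + m_bit`), applies LayerNorm and
#' a linear layer to one logit, and maps it through the sigmoid.
#'
#' @param mVec,mBit Path outputs of equal length.
#' @param params From [newHeadParams()].
#' @return List with `prob` and `logit`.
#' @export
predictHead <- function(mVec, mBit, params) {
  if (length(mVec) != length(mBit)) {
    stop("m_vec and m_bit lengths differ", call. = FALSE)
  }
  mx <- mVec + mBit
  mu <- mean(mx)
  sdv <- sqrt(mean((mx - mu)^2) + 1e-5)
  xhat <- (mx - mu) / sdv
  h <- xhat * params$ln_g + params$ln_b
  logit <- sum(h * params$w) + params$b
  list(prob = stats::plogis(logit), logit = logit)
}

#' Training configuration for the fusion model
#'
#' @param d Shared aligned dimension (divisible by `heads`).
#' @param heads Attention heads.
#' @param highwayLayers Highway depth.
#' @param dropout Dropout rate in \[0, 1); 0 disables the stochasticity (the
#'   two R-drop passes then coincide).
#' @param alpha R-drop KL weight (>= 0); `useRdrop = FALSE` sets it to 0.
#' @param lr Adam learning rate.
#' @param batchSize,epochs Training schedule.
#' @param nBits Fingerprint length.
#' @param seed Seed driving initialization, shuffling and dropout.
#' @param useAttention,useHighway Path ablation switches; at least one path
#'   must remain.
#' @param useSmiles,useFingerprint Input ablation switches (zero the
#'   corresponding aligned features).
#' @param useRdrop Convenience switch equivalent to `alpha = 0`.
#' @param swapAugment If `TRUE`, every training record is also presented
#'   with drugs A and B exchanged. The architecture is order-sensitive;
#'   this optional augmentation pushes it toward pair-order invariance.
#'   Off by default.
#' @param lossMode `"rdrop"` (default) or `"averaged_ce"`, an independent
#'   code path computing only the averaged cross-entropy of the two passes.
#' @return Named list of validated settings.
#' @export
trainConfig <- function(d = 32L, heads = 2L, highwayLayers = 2L,
                        dropout = 0.1, alpha = 1, lr = 1e-3,
                        batchSize = 32L, epochs = 10L, nBits = 2048L,
                        seed = 1L, useAttention = TRUE, useHighway = TRUE,
                        useSmiles = TRUE, useFingerprint = TRUE,
                        useRdrop = TRUE, swapAugment = FALSE,
                        lossMode = c("rdrop", "averaged_ce")) {
  lossMode <- match.arg(lossMode)
  if (d %% heads != 0L) stop("heads must divide d", call. = FALSE)
  if (alpha < 0) stop("alpha must be non-negative", call. = FALSE)
  if (dropout < 0 || dropout >= 1) {
    stop("dropout must lie in [0, 1)", call. = FALSE)
  }
  if (highwayLayers < 1L) stop("highway needs >= 1 layer", call. = FALSE)
  if (!useAttention && !useHighway) {
    stop("cannot ablate both fusion paths", call. = FALSE)
  }
  if (!useRdrop) alpha <- 0
  list(d = as.integer(d), heads = as.integer(heads),
       highwayLayers = as.integer(highwayLayers), dropout = dropout,
       alpha = alpha, lr = lr, batchSize = as.integer(batchSize),
       epochs = as.integer(epochs), nBits = as.integer(nBits),
       seed = as.integer(seed), useAttention = useAttention,
       useHighway = useHighway, useSmiles = useSmiles,
       useFingerprint = useFingerprint, swapAugment = swapAugment,
       lossMode = lossMode)
}

init_fusion_params <- function(cfg, n_genes, emb_dim) {
  d <- cfg$d; w5 <- 5L * d
  with_seed(cfg$seed, {
    p <- list(w_fp = ad_param(init_mat(cfg$nBits, d)),
              b_fp = ad_param(matrix(0, 1L, d)),
              w_ex = ad_param(init_mat(n_genes, d)),
              b_ex = ad_param(matrix(0, 1L, d)),
              w_sm = ad_param(init_mat(emb_dim, d)),
              b_sm = ad_param(matrix(0, 1L, d)),
              att_wq = ad_param(init_mat(d, d)),
              att_wk = ad_param(init_mat(d, d)),
              att_wv = ad_param(init_mat(d, d)),
              att_wr = ad_param(init_mat(d, d)),
              head_ln_g = ad_param(matrix(1, 1L, w5)),
              head_ln_b = ad_param(matrix(0, 1L, w5)),
              head_w = ad_param(init_mat(w5, 1L)),
              head_b = ad_param(matrix(0, 1L, 1L)))
    for (l in seq_len(cfg$highwayLayers)) {
      pre <- paste0("hw", l, "_")
      p[[paste0(pre, "wt")]] <- ad_param(init_mat(w5, w5))
      p[[paste0(pre, "bt")]] <- ad_param(matrix(0, 1L, w5))
      p[[paste0(pre, "wq")]] <- ad_param(init_mat(w5, w5))
      p[[paste0(pre, "bq")]] <- ad_param(matrix(0, 1L, w5))
    }
    p
  })
}

# Featurize records: fingerprint, expression and embedding matrices aligned
# row-wise with the record table. Fingerprints and embeddings are computed
# once per unique canonical drug.
prepare_features <- function(experiment, encoder, n_bits) {
  df <- records(experiment)
  expr <- exprMatrix(experiment)
  drugs <- unique(c(df$drug_a_smiles, df$drug_b_smiles))
  fp <- fingerprintMatrix(drugs, nBits = n_bits)
  emb <- encodeSmiles(encoder, drugs, mode = "eval")
  list(Fa = fp[df$drug_a_smiles, , drop = FALSE],
       Fb = fp[df$drug_b_smiles, , drop = FALSE],
       Z = expr[df$cell_line, , drop = FALSE],
       Xa = emb[df$drug_a_smiles, , drop = FALSE],
       Xb = emb[df$drug_b_smiles, , drop = FALSE],
       y = df$label)
}

# Batched forward pass through alignment, dual fusion and the head.
# Returns the (B x 1) logit node.
fusion_forward <- function(params, cfg, feats, idx, train) {
  p <- cfg$dropout
  zero_if <- function(m, keep) if (keep) m else m * 0
  align <- function(x, w, b) {
    ad_dropout(ad_add(ad_matmul(ad_const(x), w), b), p, train)
  }
  fa <- align(zero_if(feats$Fa[idx, , drop = FALSE], cfg$useFingerprint),
              params$w_fp, params$b_fp)
  fb <- align(zero_if(feats$Fb[idx, , drop = FALSE], cfg$useFingerprint),
              params$w_fp, params$b_fp)
  z <- align(feats$Z[idx, , drop = FALSE], params$w_ex, params$b_ex)
  xa <- align(zero_if(feats$Xa[idx, , drop = FALSE], cfg$useSmiles),
              params$w_sm, params$b_sm)
  xb <- align(zero_if(feats$Xb[idx, , drop = FALSE], cfg$useSmiles),
              params$w_sm, params$b_sm)
  l5 <- ad_stack5(list(fa, fb, z, xa, xb))
  nb <- length(idx)
  parts <- list()
  if (cfg$useAttention) {
    rows5 <- split(seq_len(5L * nb), rep(seq_len(nb), each = 5L))
    q <- ad_matmul(l5, params$att_wq)
    k <- ad_matmul(l5, params$att_wk)
    v <- ad_matmul(l5, params$att_wv)
    att <- ad_mha_core(q, k, v, cfg$heads, rows5)
    m_tok <- ad_relu(ad_add(att, ad_matmul(l5, params$att_wr)))
    parts$m_vec <- ad_unstack5(m_tok)
  }
  if (cfg$useHighway) {
    x <- ad_unstack5(l5)
    for (l in seq_len(cfg$highwayLayers)) {
      pre <- paste0("hw", l, "_")
      g <- ad_sigmoid(x)
      tx <- ad_relu(ad_add(ad_matmul(x, params[[paste0(pre, "wt")]]),
                           params[[paste0(pre, "bt")]]))
      qx <- ad_add(ad_matmul(x, params[[paste0(pre, "wq")]]),
                   params[[paste0(pre, "bq")]])
      one_minus_g <- ad_addconst(ad_scale(g, -1), 1)
      x <- ad_add(ad_mul(g, tx), ad_mul(one_minus_g, qx))
    }
    parts$m_bit <- x
  }
  mx <- if (length(parts) == 2L) ad_add(parts$m_vec, parts$m_bit) else parts[[1L]]
  h <- ad_layernorm(mx, params$head_ln_g, params$head_ln_b)
  h <- ad_dropout(h, p, train)
  ad_add(ad_matmul(h, params$head_w), params$head_b)
}

# Averaged cross-entropy of the two passes, KL-free code path (used to
# check that alpha = 0 training is step-for-step identical).
ad_avg_ce_loss <- function(z1, z2, y) {
  n <- length(y)
  ce <- (softplus(z1$val) - y * z1$val + softplus(z2$val) - y * z2$val) / 2
  node <- ad_node(matrix(mean(ce), 1L, 1L), list(z1, z2), function(g) {
    list(g[1L] * (stats::plogis(z1$val) - y) / (2 * n),
         g[1L] * (stats::plogis(z2$val) - y) / (2 * n))
  })
  attr(node, "parts") <- c(cross = mean(ce), kl = 0, total = mean(ce))
  node
}

#' Train the dual-fusion synergy model
#'
#' Featurizes the records (hashed atom-pair fingerprints, cell-line
#' expression, SMILES embeddings from `encoder` in eval mode), then trains
#' the alignment + dual-fusion + head network with Adam under the R-drop
#' objective: every batch is passed through the network twice with
#' independent dropout masks. All randomness flows from `config$seed`; two
#' runs with identical arguments produce identical traces and weights.
#'
#' @param experiment A [SynergyExperiment-class].
#' @param encoder A `SmilesEncoder` (fine-tuned or not); built fresh with
#'   defaults when `NULL`.
#' @param config From [trainConfig()].
#' @param trainIdx Optional record indices to train on (default all).
#' @return Object of class `SynergyModel`: parameters, config, encoder,
#'   gene order, and the per-epoch `trace` (total / cross-entropy / KL).
#' @export
trainSynergyModel <- function(experiment, encoder = NULL,
                              config = trainConfig(), trainIdx = NULL) {
  stopifnot(is(experiment, "SynergyExperiment"))
  validObject(experiment)
  if (is.null(encoder)) {
    encoder <- smilesEncoder(encoderConfig(dim = 64L, seed = config$seed))
  }
  feats <- prepare_features(experiment, encoder, config$nBits)
  if (is.null(trainIdx)) trainIdx <- seq_along(feats$y)
  if (isTRUE(config$swapAugment)) {
    # append order-swapped copies of the training records
    n0 <- length(feats$y)
    feats <- list(Fa = rbind(feats$Fa, feats$Fb),
                  Fb = rbind(feats$Fb, feats$Fa),
                  Z = rbind(feats$Z, feats$Z),
                  Xa = rbind(feats$Xa, feats$Xb),
                  Xb = rbind(feats$Xb, feats$Xa),
                  y = c(feats$y, feats$y))
    trainIdx <- c(trainIdx, trainIdx + n0)
  }
  params <- init_fusion_params(config, ncol(feats$Z),
                               ncol(feats$Xa))
  opt <- adam_new(params, lr = config$lr)
  trace <- data.frame(epoch = integer(0), loss = numeric(0),
                      cross = numeric(0), kl = numeric(0))
  with_seed(config$seed + 101L, {
    for (ep in seq_len(config$epochs)) {
      idx <- sample(trainIdx)
      nb <- max(1L, floor(length(idx) / config$batchSize))
      ep_parts <- c(0, 0, 0)
      for (b in seq_len(nb)) {
        lo <- (b - 1L) * config$batchSize + 1L
        hi <- if (b == nb) length(idx) else b * config$batchSize
        take <- idx[lo:hi]
        y <- feats$y[take]
        z1 <- fusion_forward(params, config, feats, take, train = TRUE)
        z2 <- fusion_forward(params, config, feats, take, train = TRUE)
        loss <- if (config$lossMode == "averaged_ce") {
          ad_avg_ce_loss(z1, z2, y)
        } else {
          ad_rdrop_loss(z1, z2, y, config$alpha)
        }
        if (!is.finite(ad_value(loss)[1L])) {
          stop("non-finite training loss at epoch ", ep, call. = FALSE)
        }
        ep_parts <- ep_parts + attr(loss, "parts")[c("total", "cross", "kl")]
        ad_backward(loss)
        opt <- adam_step(opt, params)
      }
      trace <- rbind(trace, data.frame(epoch = ep,
                                       loss = ep_parts[1L] / nb,
                                       cross = ep_parts[2L] / nb,
                                       kl = ep_parts[3L] / nb))
    }
  })
  structure(list(params = params, config = config, encoder = encoder,
                 genes = colnames(exprMatrix(experiment)),
                 trace = trace),
            class = "SynergyModel")
}

#' @export
print.SynergyModel <- function(x, ...) {
  cfg <- x$config
  cat("SynergyModel: d =", cfg$d, "| heads =", cfg$heads,
      "| highway layers =", cfg$highwayLayers, "| alpha =", cfg$alpha, "\n")
  paths <- c(if (cfg$useAttention) "attention", if (cfg$useHighway) "highway")
  inputs <- c(if (cfg$useFingerprint) "fingerprint", "expression",
              if (cfg$useSmiles) "smiles")
  cat("  paths:", paste(paths, collapse = " + "),
      "| inputs:", paste(inputs, collapse = " + "), "\n")
  if (nrow(x$trace) > 0L) {
    cat("  final epoch loss:", signif(utils::tail(x$trace$loss, 1L), 4), "\n")
  }
  invisible(x)
}

#' Predict synergy probabilities
#'
#' Deterministic eval-mode forward pass (dropout disabled): two calls on the
#' same records return identical probabilities.
#'
#' @param model A `SynergyModel`.
#' @param experiment A [SynergyExperiment-class] whose expression matrix has
#'   the same genes (same order) as the training data.
#' @param idx Optional record indices (default all).
#' @return Numeric vector of synergy probabilities.
#' @export
predictSynergy <- function(model, experiment, idx = NULL) {
  stopifnot(is(experiment, "SynergyExperiment"))
  if (!identical(colnames(exprMatrix(experiment)), model$genes)) {
    stop("expression genes do not match the model's training genes",
         call. = FALSE)
  }
  feats <- prepare_features(experiment, model$encoder, model$config$nBits)
  if (is.null(idx)) idx <- seq_along(feats$y)
  logits <- ad_value(fusion_forward(model$params, model$config, feats, idx,
                                    train = FALSE))
  stats::plogis(logits[, 1L])
}

#' Evaluate a model on (a subset of) an experiment
#'
#' @param model A `SynergyModel`.
#' @param experiment A [SynergyExperiment-class].
#' @param idx Optional record indices (default all).
#' @param threshold Binarization threshold (default 0.5).
#' @return A [MetricReport-class].
#' @export
evaluateModel <- function(model, experiment, idx = NULL, threshold = 0.5) {
  if (is.null(idx)) idx <- seq_len(nrow(records(experiment)))
  prob <- predictSynergy(model, experiment, idx)
  metricReport(records(experiment)$label[idx], prob, threshold)
}
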