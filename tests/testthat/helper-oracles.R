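# Independent loop oracles used by module and acceptance tests. These are
# deliberately written as explicit elementwise loops over the printed
# formulas, sharing no code with the package implementation.

# contrastive objective by explicit double loop over the batch with plain
# cosine similarity
simcse_loop_oracle <- function(h1, h2, tau) {
  n <- nrow(h1)
  total <- 0
  for (i in seq_len(n)) {
    num <- exp(cosineSim(h1[i, ], h2[i, ]) / tau)
    den <- 0
    for (j in seq_len(n)) den <- den + exp(cosineSim(h1[i, ], h2[j, ]) / tau)
    total <- total - log(num / den)
  }
  total / n
}

# attention path: per-head scaled dot-product attention over the 5 tokens,
# head outputs concatenated, projected residual added, ReLU applied
attention_loop_oracle <- function(l, params) {
  d <- ncol(l)
  h <- params$heads
  dk <- d %/% h
  att <- matrix(0, 5, d)
  for (hd in seq_len(h)) {
    cols <- ((hd - 1) * dk + 1):(hd * dk)
    q <- l %*% params$wq[, cols, drop = FALSE]
    k <- l %*% params$wk[, cols, drop = FALSE]
    v <- l %*% params$wv[, cols, drop = FALSE]
    s <- matrix(0, 5, 5)
    for (i in 1:5) for (j in 1:5) {
      s[i, j] <- sum(q[i, ] * k[j, ]) / sqrt(dk)
    }
    p <- matrix(0, 5, 5)
    for (i in 1:5) p[i, ] <- exp(s[i, ]) / sum(exp(s[i, ]))
    for (i in 1:5) for (c in seq_along(cols)) {
      att[i, cols[c]] <- sum(p[i, ] * v[, c])
    }
  }
  r <- l %*% params$wr
  m <- att + r
  m[m < 0] <- 0
  as.numeric(t(m))
}

# ROC-AUC by exhaustive enumeration of (positive, negative) pairs, ties 1/2
auc_pair_oracle <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}

# AP by sweeping every distinct threshold, computed from scratch
ap_sweep_oracle <- function(y, p) {
  th <- sort(unique(p), decreasing = TRUE)
  npos <- sum(y == 1)
  r_prev <- 0
  total <- 0
  for (t in th) {
    pred <- as.integer(p >= t)
    tp <- sum(pred == 1 & y == 1)
    prec <- tp / sum(pred == 1)
    rec <- tp / npos
    total <- total + (rec - r_prev) * prec
    r_prev <- rec
  }
  total
}

# the seven confusion-derived metrics recomputed from raw label vectors by
# formula routes unrelated to the implementation (e.g. MCC as the Pearson
# correlation of the two binary vectors)
metrics_raw_oracle <- function(y, pred) {
  acc <- mean(y == pred)
  tpr <- mean(pred[y == 1] == 1)
  tnr <- mean(pred[y == 0] == 0)
  prec <- mean(y[pred == 1] == 1)
  f1 <- 2 * prec * tpr / (prec + tpr)
  mcc <- suppressWarnings(stats::cor(y, pred))
  po <- acc
  pe <- mean(y == 1) * mean(pred == 1) + mean(y == 0) * mean(pred == 0)
  kappa <- (po - pe) / (1 - pe)
  c(ACC = acc, BACC = (tpr + tnr) / 2, Prec = prec, Rec = tpr, F1 = f1,
    MCC = mcc, Kappa = kappa)
}
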