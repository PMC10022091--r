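# Contrastive SMILES encoder: a small from-scratch transformer over SMILES
# tokens, fine-tuned with the SimCSE objective — the same string is encoded
# twice with independent dropout masks, the two views form a positive pair,
# and all other batch members are in-batch negatives. No pretrained weights
# are involved; the contrastive mechanism itself (dropout views + InfoNCE
# with temperature) is what the module provides.

#' Encoder configuration
#'
#' @param layers Transformer blocks (default 2).
#' @param heads Attention heads per block; must divide `dim`.
#' @param dim Embedding width D.
#' @param ffnMult Feed-forward expansion factor.
#' @param dropout Dropout rate in (0, 1); the only SimCSE augmentation.
#' @param tau Contrastive softmax temperature (> 0); default 0.05, the
#'   SimCSE convention.
#' @param maxLen Maximum token count per SMILES (sentinels included).
#' @param pooling `"cls"` (BOS-position vector, default) or `"mean"`.
#' @param seed Seed for weight initialization.
#' @return Named list of validated settings.
#' @export
encoderConfig <- function(layers = 2L, heads = 4L, dim = 64L, ffnMult = 2L,
                          dropout = 0.1, tau = 0.05, maxLen = 64L,
                          pooling = c("cls", "mean"), seed = 1L) {
  pooling <- match.arg(pooling)
  stopifnot(layers >= 1L, heads >= 1L, dim >= heads, ffnMult >= 1L,
            maxLen >= 3L)
  if (dim %% heads != 0L) stop("heads must divide dim", call. = FALSE)
  if (dropout <= 0 || dropout >= 1) {
    stop("dropout must lie in (0, 1)", call. = FALSE)
  }
  if (tau <= 0) stop("temperature tau must be positive", call. = FALSE)
  list(layers = as.integer(layers), heads = as.integer(heads),
       dim = as.integer(dim), ffnMult = as.integer(ffnMult),
       dropout = dropout, tau = tau, maxLen = as.integer(maxLen),
       pooling = pooling, seed = as.integer(seed))
}

init_mat <- function(nr, nc, sd = 0.02) {
  matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
}

#' Construct an initialized SMILES encoder
#'
#' @param config From [encoderConfig()].
#' @param vocab Token table, as from [smilesVocabulary()].
#' @return An object of class `SmilesEncoder` holding the configuration,
#'   vocabulary and parameter set.
#' @export
smilesEncoder <- function(config = encoderConfig(),
                          vocab = smilesVocabulary()) {
  d <- config$dim
  fd <- d * config$ffnMult
  params <- with_seed(config$seed, {
    p <- list(tok_emb = ad_param(init_mat(length(vocab), d)),
              pos_emb = ad_param(init_mat(config$maxLen, d)),
              ln_f_g = ad_param(matrix(1, 1L, d)),
              ln_f_b = ad_param(matrix(0, 1L, d)))
    for (l in seq_len(config$layers)) {
      pre <- paste0("l", l, "_")
      p[[paste0(pre, "ln1_g")]] <- ad_param(matrix(1, 1L, d))
      p[[paste0(pre, "ln1_b")]] <- ad_param(matrix(0, 1L, d))
      for (w in c("wq", "wk", "wv", "wo")) {
        p[[paste0(pre, w)]] <- ad_param(init_mat(d, d))
        p[[paste0(pre, w, "_b")]] <- ad_param(matrix(0, 1L, d))
      }
      p[[paste0(pre, "ln2_g")]] <- ad_param(matrix(1, 1L, d))
      p[[paste0(pre, "ln2_b")]] <- ad_param(matrix(0, 1L, d))
      p[[paste0(pre, "w1")]] <- ad_param(init_mat(d, fd))
      p[[paste0(pre, "w1_b")]] <- ad_param(matrix(0, 1L, fd))
      p[[paste0(pre, "w2")]] <- ad_param(init_mat(fd, d))
      p[[paste0(pre, "w2_b")]] <- ad_param(matrix(0, 1L, d))
    }
    p
  })
  structure(list(config = config, vocab = vocab, params = params),
            class = "SmilesEncoder")
}

#' @export
print.SmilesEncoder <- function(x, ...) {
  cfg <- x$config
  np <- sum(vapply(x$params, function(p) length(p$val), numeric(1)))
  cat("SmilesEncoder:", cfg$layers, "layer(s),", cfg$heads, "head(s), D =",
      cfg$dim, "| vocab", length(x$vocab), "| parameters", np, "\n")
  invisible(x)
}

# Transformer forward over a list of token-index vectors. Returns the ad
# node of pooled embeddings (one row per sequence). Pre-LN blocks; dropout
# active only when train = TRUE.
encoder_forward <- function(enc, token_list, train = FALSE) {
  cfg <- enc$config
  p <- enc$params
  lens <- lengths(token_list)
  if (any(lens > cfg$maxLen)) {
    stop("sequence exceeds encoder maxLen", call. = FALSE)
  }
  rows <- split(seq_len(sum(lens)), rep(seq_along(lens), lens))
  tok_idx <- unlist(token_list, use.names = FALSE)
  pos_idx <- unlist(lapply(lens, seq_len), use.names = FALSE)
  h <- ad_add(ad_gather_rows(p$tok_emb, tok_idx),
              ad_gather_rows(p$pos_emb, pos_idx))
  h <- ad_dropout(h, cfg$dropout, train)
  for (l in seq_len(cfg$layers)) {
    pre <- paste0("l", l, "_")
    hn <- ad_layernorm(h, p[[paste0(pre, "ln1_g")]], p[[paste0(pre, "ln1_b")]])
    q <- ad_add(ad_matmul(hn, p[[paste0(pre, "wq")]]), p[[paste0(pre, "wq_b")]])
    k <- ad_add(ad_matmul(hn, p[[paste0(pre, "wk")]]), p[[paste0(pre, "wk_b")]])
    v <- ad_add(ad_matmul(hn, p[[paste0(pre, "wv")]]), p[[paste0(pre, "wv_b")]])
    att <- ad_mha_core(q, k, v, cfg$heads, rows)
    att <- ad_add(ad_matmul(att, p[[paste0(pre, "wo")]]),
                  p[[paste0(pre, "wo_b")]])
    h <- ad_add(h, ad_dropout(att, cfg$dropout, train))
    hn2 <- ad_layernorm(h, p[[paste0(pre, "ln2_g")]], p[[paste0(pre, "ln2_b")]])
    ff <- ad_relu(ad_add(ad_matmul(hn2, p[[paste0(pre, "w1")]]),
                         p[[paste0(pre, "w1_b")]]))
    ff <- ad_add(ad_matmul(ff, p[[paste0(pre, "w2")]]),
                 p[[paste0(pre, "w2_b")]])
    h <- ad_add(h, ad_dropout(ff, cfg$dropout, train))
  }
  h <- ad_layernorm(h, p$ln_f_g, p$ln_f_b)
  ad_pool_rows(h, rows, cfg$pooling)
}

#' Encode SMILES strings to embeddings
#'
#' In `eval` mode dropout is disabled and repeated calls are bit-identical;
#' in `train` mode each call draws fresh dropout masks (seed the R RNG for
#' reproducibility).
#'
#' @param encoder A `SmilesEncoder`.
#' @param smiles Character vector of SMILES strings (non-empty batch).
#' @param mode `"eval"` or `"train"`.
#' @return Numeric matrix, one embedding row of width D per input.
#' @export
encodeSmiles <- function(encoder, smiles, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (length(smiles) == 0L) stop("empty batch", call. = FALSE)
  toks <- lapply(smiles, tokenizeSmiles, vocab = encoder$vocab,
                 maxLen = encoder$config$maxLen)
  out <- ad_value(encoder_forward(encoder, toks, train = mode == "train"))
  rownames(out) <- smiles
  out
}

#' Cosine similarity
#'
#' @param u,v Non-zero numeric vectors of equal length.
#' @return Similarity in \[-1, 1\].
#' @export
cosineSim <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero vector in cosine similarity",
                               call. = FALSE)
  sum(u * v) / (nu * nv)
}

#' SimCSE contrastive loss
#'
#' For paired embedding matrices `H1[i, ]`, `H2[i, ]` (the two dropout views
#' of input i), the mean over i of
#' `-log( exp(sim(H1_i, H2_i)/tau) / sum_j exp(sim(H1_i, H2_j)/tau) )`
#' with cosine similarity, i.e. InfoNCE with in-batch negatives.
#'
#' @param h1,h2 N x D embedding matrices, row i of each being the two views
#'   of the same input.
#' @param tau Temperature (> 0).
#' @return Non-negative scalar loss (0 when N = 1).
#' @export
simcseLoss <- function(h1, h2, tau = 0.05) {
  stopifnot(is.matrix(h1), is.matrix(h2), all(dim(h1) == dim(h2)))
  if (tau <= 0) stop("temperature tau must be positive", call. = FALSE)
  n <- nrow(h1)
  h1n <- h1 / sqrt(rowSums(h1^2))
  h2n <- h2 / sqrt(rowSums(h2^2))
  s <- (h1n %*% t(h2n)) / tau
  m <- apply(s, 1L, max)
  lse <- m + log(rowSums(exp(s - m)))
  mean(lse - diag(s)[seq_len(n)])
}

#' Fine-tune the encoder with the SimCSE objective
#'
#' Each step encodes a batch twice under independent dropout masks and
#' minimizes the InfoNCE loss over the two views, with Adam. Everything is
#' driven by `seed`: two runs with the same arguments produce identical loss
#' traces and weights.
#'
#' @param encoder A `SmilesEncoder`.
#' @param corpus Character vector of SMILES; must have at least `batchSize`
#'   entries.
#' @param epochs Passes over the corpus; `epochs = 0` returns the encoder
#'   untouched.
#' @param batchSize Mini-batch size N of positive pairs.
#' @param lr Adam learning rate.
#' @param seed Integer seed for shuffling and dropout.
#' @return List with `encoder` (fine-tuned) and `trace` (per-step loss).
#' @export
finetuneEncoder <- function(encoder, corpus, epochs = 5L, batchSize = 16L,
                            lr = 1e-3, seed = 1L) {
  stopifnot(epochs >= 0L)
  if (length(corpus) < batchSize) {
    stop("corpus smaller than batchSize", call. = FALSE)
  }
  if (epochs == 0L) return(list(encoder = encoder, trace = numeric(0)))
  toks <- lapply(corpus, tokenizeSmiles, vocab = encoder$vocab,
                 maxLen = encoder$config$maxLen)
  tau <- encoder$config$tau
  opt <- adam_new(encoder$params, lr = lr)
  trace <- numeric(0)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      idx <- sample(seq_along(toks))
      nb <- floor(length(idx) / batchSize)
      for (b in seq_len(nb)) {
        take <- idx[((b - 1L) * batchSize + 1L):(b * batchSize)]
        h1 <- encoder_forward(encoder, toks[take], train = TRUE)
        h2 <- encoder_forward(encoder, toks[take], train = TRUE)
        s <- ad_matmul(ad_l2normalize_rows(h1),
                       ad_transpose(ad_l2normalize_rows(h2)))
        loss <- ad_info_nce(ad_scale(s, 1 / tau))
        if (!is.finite(ad_value(loss)[1L])) {
          stop("non-finite SimCSE loss at epoch ", ep, ", batch ", b,
               call. = FALSE)
        }
        trace <- c(trace, ad_value(loss)[1L])
        ad_backward(loss)
        opt <- adam_step(opt, encoder$params)
      }
    }
  })
  list(encoder = encoder, trace = trace)
}

#' Mean positive-pair cosine similarity under dropout
#'
#' Diagnostic for contrastive fine-tuning: encodes the corpus twice in train
#' mode (two dropout views) and averages the per-input cosine similarity of
#' the two views.
#'
#' @param encoder A `SmilesEncoder`.
#' @param corpus SMILES strings.
#' @param seed Seed for the dropout masks.
#' @return Mean cosine similarity across the corpus.
#' @export
positivePairCosine <- function(encoder, corpus, seed = 1L) {
  with_seed(seed, {
    h1 <- encodeSmiles(encoder, corpus, mode = "train")
    h2 <- encodeSmiles(encoder, corpus, mode = "train")
  })
  mean(vapply(seq_len(nrow(h1)),
              function(i) cosineSim(h1[i, ], h2[i, ]), numeric(1)))
}
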