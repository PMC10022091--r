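# Dual-path feature fusion. The five aligned inputs (fingerprint A,
# fingerprint B, expression, SMILES embedding A, SMILES embedding B) are
# concatenated in that fixed order and consumed through two views of the
# same numbers: a 5 x d token matrix for vector-level multi-head attention
# with a projected residual and ReLU, and a flat 5d vector for the bit-level
# highway network. The exported single-sample operations below are the
# reference surface; batched training runs the identical math through the
# autodiff graph.

#' Affine projection to the shared dimension
#'
#' The dimensional-alignment map g(x) = W x + b that brings fingerprints,
#' expression vectors and SMILES embeddings to one width d.
#'
#' @param x Input vector.
#' @param W d x length(x) weight matrix.
#' @param b Length-d bias vector.
#' @return Numeric vector of length d.
#' @export
linearProject <- function(x, W, b) {
  if (ncol(W) != length(x)) {
    stop("input width ", length(x), " does not match projection width ",
         ncol(W), call. = FALSE)
  }
  if (nrow(W) != length(b)) stop("bias length mismatch", call. = FALSE)
  as.numeric(W %*% x + b)
}

#' Assemble the fusion input from five aligned vectors
#'
#' Concatenation order is fixed: fingerprint A, fingerprint B, expression,
#' SMILES embedding A, SMILES embedding B. Returns both views over the same
#' numbers.
#'
#' @param fa,fb,z,xa,xb Aligned vectors, all of one dimension d.
#' @return List with `flat` (length 5d) and `mat` (5 x d, one row per
#'   feature vector in order).
#' @export
buildFusionInput <- function(fa, fb, z, xa, xb) {
  d <- length(fa)
  if (!all(lengths(list(fb, z, xa, xb)) == d)) {
    stop("all five aligned vectors must share one dimension", call. = FALSE)
  }
  mat <- rbind(fa, fb, z, xa, xb, deparse.level = 0)
  list(flat = as.numeric(t(mat)), mat = mat)
}

#' Fresh attention-path parameters
#'
#' @param d Shared aligned dimension; must be divisible by `heads`.
#' @param heads Number of attention heads.
#' @param seed Seed for initialization.
#' @return List with `wq`, `wk`, `wv`, `wr` (each d x d) and `heads`.
#' @export
newAttentionParams <- function(d, heads = 1L, seed = 1L) {
  if (d %% heads != 0L) {
    stop("heads must divide the aligned dimension d", call. = FALSE)
  }
  with_seed(seed, list(wq = init_mat(d, d), wk = init_mat(d, d),
                       wv = init_mat(d, d), wr = init_mat(d, d),
                       heads = as.integer(heads)))
}

#' Vector-level attention path
#'
#' Treats the fusion input as a 5-token sequence. Per head i:
#' Q_i = l W_i^Q, K_i = l W_i^K, V_i = l W_i^V, attended output
#' softmax(Q K^T / sqrt(d_k)) V over the 5 tokens; heads are concatenated
#' along the feature axis, the projected residual l W^R is added, and ReLU
#' is applied. Head weight matrices live as column blocks of the d x d
#' matrices in `params`.
#'
#' @param l Fusion input: the `mat` view (5 x d) or a [buildFusionInput()]
#'   result.
#' @param params From [newAttentionParams()].
#' @return `m_vec`, the nonnegative vector of length 5d (token rows
#'   concatenated); the 5 x 5 per-head attention weight matrices are
#'   attached as `attr(, "weights")`.
#' @export
attentionPath <- function(l, params) {
  if (is.list(l) && !is.null(l$mat)) l <- l$mat
  stopifnot(is.matrix(l), nrow(l) == 5L)
  d <- ncol(l)
  h <- params$heads
  q <- ad_const(l %*% params$wq)
  k <- ad_const(l %*% params$wk)
  v <- ad_const(l %*% params$wv)
  att <- ad_mha_core(q, k, v, h, list(1:5))
  m_tok <- pmax(ad_value(att) + l %*% params$wr, 0)
  out <- as.numeric(t(m_tok))
  dk <- d %/% h
  weights <- lapply(seq_len(h), function(hd) {
    cols <- ((hd - 1L) * dk + 1L):(hd * dk)
    row_softmax((ad_value(q)[, cols, drop = FALSE] %*%
                   t(ad_value(k)[, cols, drop = FALSE])) / sqrt(dk))
  })
  attr(out, "weights") <- weights
  out
}

#' Fresh highway-path parameters
#'
#' @param width Input width (5d).
#' @param layers Number of highway layers (>= 1).
#' @param seed Seed for initialization.
#' @return List of per-layer lists `wt`, `bt`, `wq`, `bq`.
#' @export
newHighwayParams <- function(width, layers = 2L, seed = 1L) {
  if (layers < 1L) stop("highway needs at least one layer", call. = FALSE)
  with_seed(seed, lapply(seq_len(layers), function(l) {
    list(wt = init_mat(width, width), bt = stats::rnorm(width, sd = 0.02),
         wq = init_mat(width, width), bq = stats::rnorm(width, sd = 0.02))
  }))
}

#' Bit-level highway path
#'
#' Per layer, with input x: gate g = sigmoid(x) (elementwise, on the layer
#' input itself), transform t(x) = ReLU(x W_t + b_t), carry q(x) = x W_q +
#' b_q, output g * t(x) + (1 - g) * q(x). Output width equals input width.
#'
#' @param l Fusion input: the `flat` view (length 5d) or a
#'   [buildFusionInput()] result.
#' @param params From [newHighwayParams()].
#' @return `m_bit`, vector of length 5d.
#' @export
highwayPath <- function(l, params) {
  if (is.list(l) && !is.null(l$flat)) l <- l$flat
  x <- as.numeric(l)
  for (layer in params) {
    g <- stats::plogis(x)
    tx <- pmax(as.numeric(x %*% layer$wt) + layer$bt, 0)
    qx <- as.numeric(x %*% layer$wq) + layer$bq
    x <- g * tx + (1 - g) * qx
  }
  x
}
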