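# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every node is an environment holding the forward value, an accumulator for
# the gradient, its parent nodes and a backward closure mapping the incoming
# gradient to one gradient per parent. Graphs are rebuilt on every forward
# pass; parameters are persistent leaf nodes. This is deliberately small:
# just the operations the encoder and fusion network need, each with a
# hand-derived backward that is checked against finite differences in the
# test suite.

.ad_counter <- new.env(parent = emptyenv())
.ad_counter$n <- 0L

ad_node <- function(val, parents = list(), backfn = NULL) {
  # force args before touching the id counter: nested ad_* calls in `val`
  # or `parents` create their own nodes and must get earlier ids
  force(val); force(parents); force(backfn)
  .ad_counter$n <- .ad_counter$n + 1L
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$grad <- NULL
  e$parents <- parents
  e$backfn <- backfn
  e$id <- .ad_counter$n
  class(e) <- "ad_node"
  e
}

ad_const <- function(x) ad_node(as_mat(x))

ad_param <- function(x) {
  e <- ad_node(as_mat(x))
  e$is_param <- TRUE
  e
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

ad_value <- function(x) x$val

# Accumulate gradients in reverse topological order, seeding the terminal
# scalar node with 1.
ad_backward <- function(loss) {
  stopifnot(length(loss$val) == 1L)
  order <- ad_toposort(loss)
  for (node in order) node$grad <- NULL
  loss$grad <- matrix(1, 1L, 1L)
  for (node in rev(order)) {
    if (is.null(node$backfn) || is.null(node$grad)) next
    gs <- node$backfn(node$grad)
    for (k in seq_along(node$parents)) {
      p <- node$parents[[k]]
      g <- gs[[k]]
      if (is.null(g)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(loss)
}

# Iterative post-order DFS (no recursion: graphs can be a few hundred nodes).
ad_toposort <- function(root) {
  out <- vector("list", 0L)
  visited <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$stage == 1L) {
      if (!is.null(visited[[key]])) next
      visited[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (is.null(visited[[as.character(p$id)]])) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      out[[length(out) + 1L]] <- node
    }
  }
  out
}

# ---- primitive operations ---------------------------------------------------

ad_matmul <- function(a, b) {
  ad_node(a$val %*% b$val, list(a, b), function(g) {
    list(g %*% t(b$val), t(a$val) %*% g)
  })
}

# Elementwise add; `b` may be a 1 x n bias row broadcast over the rows of `a`.
ad_add <- function(a, b) {
  bcast <- nrow(b$val) == 1L && nrow(a$val) > 1L
  val <- if (bcast) sweep(a$val, 2L, b$val[1L, ], "+") else a$val + b$val
  ad_node(val, list(a, b), function(g) {
    list(g, if (bcast) matrix(colSums(g), 1L) else g)
  })
}

ad_scale <- function(a, k) {
  ad_node(a$val * k, list(a), function(g) list(g * k))
}

ad_addconst <- function(a, k) {
  ad_node(a$val + k, list(a), function(g) list(g))
}

ad_mul <- function(a, b) {
  ad_node(a$val * b$val, list(a, b), function(g) list(g * b$val, g * a$val))
}

ad_relu <- function(a) {
  ad_node(pmax(a$val, 0), list(a), function(g) list(g * (a$val > 0)))
}

ad_sigmoid <- function(a) {
  s <- stats::plogis(a$val)
  ad_node(s, list(a), function(g) list(g * s * (1 - s)))
}

# Inverted dropout: scaling by 1/(1-p) at train time keeps eval a no-op.
ad_dropout <- function(a, p, train) {
  if (!train || p <= 0) return(a)
  mask <- matrix(stats::rbinom(length(a$val), 1L, 1 - p), nrow(a$val)) / (1 - p)
  ad_node(a$val * mask, list(a), function(g) list(g * mask))
}

ad_mean <- function(a) {
  n <- length(a$val)
  ad_node(matrix(mean(a$val), 1L, 1L), list(a), function(g) {
    list(matrix(g[1L] / n, nrow(a$val), ncol(a$val)))
  })
}

# Row-wise LayerNorm with learned scale/shift (1 x d each).
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  d <- ncol(x$val)
  mu <- rowMeans(x$val)
  xc <- x$val - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  val <- sweep(sweep(xhat, 2L, gamma$val[1L, ], "*"), 2L, beta$val[1L, ], "+")
  ad_node(val, list(x, gamma, beta), function(g) {
    dxhat <- sweep(g, 2L, gamma$val[1L, ], "*")
    dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
    list(dx,
         matrix(colSums(g * xhat), 1L),
         matrix(colSums(g), 1L))
  })
}

# Row gather (embedding lookup); backward scatter-adds.
ad_gather_rows <- function(emb, idx) {
  ad_node(emb$val[idx, , drop = FALSE], list(emb), function(g) {
    de <- matrix(0, nrow(emb$val), ncol(emb$val))
    for (r in seq_along(idx)) de[idx[r], ] <- de[idx[r], ] + g[r, ]
    list(de)
  })
}

# Normalize each row to unit L2 norm.
ad_l2normalize_rows <- function(x) {
  r <- sqrt(rowSums(x$val^2))
  if (any(r == 0)) stop("cannot normalize a zero row")
  y <- x$val / r
  ad_node(y, list(x), function(g) {
    list(g / r - y * (rowSums(g * y) / r))
  })
}

ad_transpose <- function(x) {
  ad_node(t(x$val), list(x), function(g) list(t(g)))
}

# InfoNCE over a similarity matrix S (already divided by the temperature):
# mean_i [ -S_ii + log sum_j exp(S_ij) ].
ad_info_nce <- function(s) {
  n <- nrow(s$val)
  m <- apply(s$val, 1L, max)
  lse <- m + log(rowSums(exp(s$val - m)))
  val <- mean(lse - diag(s$val))
  p <- exp(s$val - lse)            # row softmax
  ad_node(matrix(val, 1L, 1L), list(s), function(g) {
    list(g[1L] * (p - diag(n)) / n)
  })
}

# Interleave five (B x d) feature blocks into a (5B x d) token matrix in which
# sample b occupies rows (b-1)*5 + 1..5, in the given block order.
ad_stack5 <- function(blocks) {
  stopifnot(length(blocks) == 5L)
  b <- nrow(blocks[[1L]]$val); d <- ncol(blocks[[1L]]$val)
  val <- matrix(0, 5L * b, d)
  for (k in 1:5) val[seq(k, 5L * b, by = 5L), ] <- blocks[[k]]$val
  ad_node(val, blocks, function(g) {
    lapply(1:5, function(k) g[seq(k, 5L * b, by = 5L), , drop = FALSE])
  })
}

# (5B x d) token matrix -> (B x 5d) flat matrix, tokens concatenated in order.
ad_unstack5 <- function(m) {
  n <- nrow(m$val); d <- ncol(m$val)
  b <- n %/% 5L
  val <- matrix(0, b, 5L * d)
  for (k in 1:5) val[, ((k - 1L) * d + 1L):(k * d)] <- m$val[seq(k, n, by = 5L), ]
  ad_node(val, list(m), function(g) {
    dm <- matrix(0, n, d)
    for (k in 1:5) dm[seq(k, n, by = 5L), ] <- g[, ((k - 1L) * d + 1L):(k * d)]
    list(dm)
  })
}

# Multi-head scaled dot-product attention core. Q, K, V stack per-sample
# token matrices row-wise; `rows` lists each sample's row indices (blocks
# may differ in length). Columns are split into `h` heads of width d/h;
# each sample attends only over its own tokens. Returns the row-stacked,
# head-concatenated output.
ad_mha_core <- function(q, k, v, h, rows) {
  d <- ncol(q$val)
  stopifnot(d %% h == 0L)
  dk <- d %/% h
  nb <- length(rows)
  sc <- 1 / sqrt(dk)
  val <- matrix(0, nrow(q$val), d)
  probs <- vector("list", nb * h)
  for (b in seq_len(nb)) {
    rw <- rows[[b]]
    for (hd in seq_len(h)) {
      cols <- ((hd - 1L) * dk + 1L):(hd * dk)
      qs <- q$val[rw, cols, drop = FALSE]
      ks <- k$val[rw, cols, drop = FALSE]
      vs <- v$val[rw, cols, drop = FALSE]
      s <- (qs %*% t(ks)) * sc
      p <- row_softmax(s)
      probs[[(b - 1L) * h + hd]] <- p
      val[rw, cols] <- p %*% vs
    }
  }
  ad_node(val, list(q, k, v), function(g) {
    dq <- matrix(0, nrow(q$val), d); dk_ <- dq; dv <- dq
    for (b in seq_len(nb)) {
      rw <- rows[[b]]
      for (hd in seq_len(h)) {
        cols <- ((hd - 1L) * dk + 1L):(hd * dk)
        p <- probs[[(b - 1L) * h + hd]]
        go <- g[rw, cols, drop = FALSE]
        vs <- v$val[rw, cols, drop = FALSE]
        dv[rw, cols] <- t(p) %*% go
        dp <- go %*% t(vs)
        ds <- p * (dp - rowSums(dp * p))   # softmax backward, row-wise
        dq[rw, cols] <- (ds %*% k$val[rw, cols, drop = FALSE]) * sc
        dk_[rw, cols] <- (t(ds) %*% q$val[rw, cols, drop = FALSE]) * sc
      }
    }
    list(dq, dk_, dv)
  })
}

# Pool one row per sample from a row-stacked token matrix: the first token
# (CLS/BOS position) or the mean over the sample's tokens.
ad_pool_rows <- function(x, rows, type = c("cls", "mean")) {
  type <- match.arg(type)
  nb <- length(rows)
  d <- ncol(x$val)
  val <- matrix(0, nb, d)
  for (b in seq_len(nb)) {
    rw <- rows[[b]]
    val[b, ] <- if (type == "cls") x$val[rw[1L], ] else colMeans(x$val[rw, , drop = FALSE])
  }
  ad_node(val, list(x), function(g) {
    dx <- matrix(0, nrow(x$val), d)
    for (b in seq_len(nb)) {
      rw <- rows[[b]]
      if (type == "cls") {
        dx[rw[1L], ] <- dx[rw[1L], ] + g[b, ]
      } else {
        dx[rw, ] <- dx[rw, ] + matrix(g[b, ] / length(rw), length(rw), d,
                                      byrow = TRUE)
      }
    }
    list(dx)
  })
}

row_softmax <- function(s) {
  m <- apply(s, 1L, max)
  e <- exp(s - m)
  e / rowSums(e)
}

softplus <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))

# Joint R-drop objective from the two logit columns z1, z2 (B x 1 each) and
# labels y: mean over the batch of
#   1/2 (CE(z1, y) + CE(z2, y)) + alpha * 1/2 (KL(p1||p2) + KL(p2||p1)),
# both computed in logit space. The KL gradients use the identity
# log(p/(1-p)) = z, which collapses d KL(p1||p2)/dz1 to p1(1-p1)(z1-z2).
ad_rdrop_loss <- function(z1, z2, y, alpha) {
  n <- length(y)
  p1 <- stats::plogis(z1$val); p2 <- stats::plogis(z2$val)
  ce1 <- softplus(z1$val) - y * z1$val
  ce2 <- softplus(z2$val) - y * z2$val
  lp1 <- -softplus(-z1$val); l1p1 <- -softplus(z1$val)
  lp2 <- -softplus(-z2$val); l1p2 <- -softplus(z2$val)
  kl12 <- p1 * (lp1 - lp2) + (1 - p1) * (l1p1 - l1p2)
  kl21 <- p2 * (lp2 - lp1) + (1 - p2) * (l1p2 - l1p1)
  l_cross <- mean((ce1 + ce2) / 2)
  l_kl <- mean((kl12 + kl21) / 2)
  total <- l_cross + alpha * l_kl
  node <- ad_node(matrix(total, 1L, 1L), list(z1, z2), function(g) {
    dz1 <- (0.5 * (p1 - y) +
              alpha * 0.5 * (p1 * (1 - p1) * (z1$val - z2$val) + (p1 - p2))) / n
    dz2 <- (0.5 * (p2 - y) +
              alpha * 0.5 * (p2 * (1 - p2) * (z2$val - z1$val) + (p2 - p1))) / n
    list(g[1L] * dz1, g[1L] * dz2)
  })
  attr(node, "parts") <- c(cross = l_cross, kl = l_kl, total = total)
  node
}

# ---- optimizer --------------------------------------------------------------

# Adam over a flat named list of ad_param nodes.
adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
             m = lapply(params, function(p) p$val * 0),
             v = lapply(params, function(p) p$val * 0))
  st
}

adam_step <- function(opt, params) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  for (k in seq_along(params)) {
    p <- params[[k]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[k]] <- b1 * opt$m[[k]] + (1 - b1) * g
    opt$v[[k]] <- b2 * opt$v[[k]] + (1 - b2) * g^2
    mhat <- opt$m[[k]] / (1 - b1^opt$t)
    vhat <- opt$v[[k]] / (1 - b2^opt$t)
    p$val <- p$val - opt$lr * mhat / (sqrt(vhat) + opt$eps)
    p$grad <- NULL
  }
  opt
}

ad_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}
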