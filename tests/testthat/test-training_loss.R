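test_that("cross-entropy matches direct substitution and rejects boundary probs", {
  expect_equal(crossEntropy(0.5, 1), log(2), tolerance = 1e-12)
  expect_equal(crossEntropy(0.5, 0), log(2), tolerance = 1e-12)
  expect_equal(crossEntropy(0.9, 1), -log(0.9), tolerance = 1e-12)
  expect_lt(crossEntropy(1 - 1e-9, 1), 1e-8)
  expect_error(crossEntropy(1, 1), "outside")
  expect_error(crossEntropy(0, 0), "outside")
})

test_that("R-drop KL is symmetric, zero iff equal, and exact on the known case", {
  expect_equal(rdropKl(0.7, 0.7), 0)
  # 1/2 (KL(0.9||0.6) + KL(0.6||0.9)) via Bernoulli KL
  expect_equal(rdropKl(0.9, 0.6), 0.26876, tolerance = 1e-4)
  set.seed(10)
  for (i in 1:20) {
    a <- runif(1, 0.01, 0.99); b <- runif(1, 0.01, 0.99)
    expect_equal(rdropKl(a, b), rdropKl(b, a), tolerance = 1e-12)
    expect_gte(rdropKl(a, b), 0)
  }
  expect_error(rdropKl(1.2, 0.5), "outside")
})

test_that("total loss composes the terms as stated", {
  # alpha = 0 reduces to averaged cross-entropy
  tl0 <- totalLoss(0.8, 0.3, 1, alpha = 0)
  expect_equal(tl0$L, tl0$L_cross)
  # equal passes: KL term vanishes
  tle <- totalLoss(0.7, 0.7, 0, alpha = 2)
  expect_equal(tle$L, tle$L_cross)
  # worked case
  tl <- totalLoss(0.9, 0.6, 1, alpha = 1)
  expect_equal(tl$L_cross, (-log(0.9) - log(0.6)) / 2, tolerance = 1e-12)
  expect_equal(tl$L, 0.57686, tolerance = 1e-4)
  expect_error(totalLoss(0.9, 0.6, 1, alpha = -1), "non-negative")
  # non-decreasing in alpha when the passes disagree
  ls <- vapply(c(0, 0.5, 1, 2), function(a) totalLoss(0.9, 0.6, 1, a)$L,
               numeric(1))
  expect_true(all(diff(ls) > 0))
})

test_that("binarize assigns the boundary to the positive class", {
  expect_identical(binarize(c(0.51, 0.5, 0.49)), c(1L, 1L, 0L))
  expect_identical(binarize(0.3, threshold = 0.2), 1L)
  expect_error(binarize(1.2), "prob")
})

test_that("prediction head normalizes then maps to a probability", {
  set.seed(12)
  width <- 10L
  params <- newHeadParams(width, seed = 3)
  mv <- rnorm(width); mb <- rnorm(width)
  out <- predictHead(mv, mb, params)
  expect_true(out$prob > 0 && out$prob < 1)
  expect_equal(out$prob, plogis(out$logit))
  expect_identical(out, predictHead(mv, mb, params))
  expect_error(predictHead(mv, mb[-1], params), "lengths")

  # read the normalized vector through one-hot output weights: it must have
  # mean 0 and variance 1 (population) before the affine rescale
  xhat <- vapply(seq_len(width), function(i) {
    p1 <- params; p1$w <- replace(rep(0, width), i, 1); p1$b <- 0
    predictHead(mv, mb, p1)$logit
  }, numeric(1))
  expect_equal(mean(xhat), 0, tolerance = 1e-5)
  expect_equal(mean(xhat^2), 1, tolerance = 1e-4)
})

test_that("training is seed-reproducible and memorizes a tiny batch", {
  exp <- small_experiment()
  enc <- tiny_encoder()
  cfg <- trainConfig(d = 8L, heads = 2L, epochs = 2L, batchSize = 25L,
                     dropout = 0.1, seed = 21L)
  m1 <- trainSynergyModel(exp, enc, cfg)
  m2 <- trainSynergyModel(exp, enc, cfg)
  expect_identical(m1$trace, m2$trace)
  expect_identical(predictSynergy(m1, exp, 1:10), predictSynergy(m2, exp, 1:10))

  # memorization sanity: 16 records, 500 steps, training CE falls below 0.1
  idx <- 1:16
  cfg2 <- trainConfig(d = 32L, heads = 2L, epochs = 500L, batchSize = 16L,
                      dropout = 0.05, alpha = 1, seed = 22L)
  m3 <- trainSynergyModel(exp, enc, cfg2, trainIdx = idx)
  expect_lt(tail(m3$trace$cross, 1L), 0.1)
})

test_that("evaluation passes are deterministic and probabilities are valid", {
  exp <- small_experiment()
  m <- trainSynergyModel(exp, tiny_encoder(),
                         trainConfig(d = 8L, epochs = 1L, seed = 5L))
  p1 <- predictSynergy(m, exp)
  p2 <- predictSynergy(m, exp)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))
  rep <- evaluateModel(m, exp)
  expect_s4_class(rep, "MetricReport")
  expect_identical(sum(confusion(rep)), nrow(records(exp)))
})

test_that("unknown cell lines are rejected with their identifiers", {
  exp <- small_experiment()
  rec <- records(exp)
  rec$cell_line[1] <- "NOT_A_LINE"
  expect_error(SynergyExperiment(rec, exprMatrix(exp)), "NOT_A_LINE")
})

test_that("both-orders augmentation trains on swapped pairs too", {
  exp <- small_experiment()
  enc <- tiny_encoder()
  cfg <- trainConfig(d = 8L, epochs = 1L, batchSize = 50L, seed = 3L,
                     swapAugment = TRUE)
  m <- trainSynergyModel(exp, enc, cfg, trainIdx = 1:50)
  expect_s3_class(m, "SynergyModel")
  expect_true(all(is.finite(m$trace$loss)))
  # prediction still runs on the unaugmented experiment
  expect_length(predictSynergy(m, exp, 1:5), 5L)
})

test_that("config validation rejects inconsistent settings", {
  expect_error(trainConfig(d = 10L, heads = 3L), "divide")
  expect_error(trainConfig(alpha = -0.5), "non-negative")
  expect_error(trainConfig(useAttention = FALSE, useHighway = FALSE),
               "both fusion paths")
  expect_equal(trainConfig(useRdrop = FALSE)$alpha, 0)
})
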