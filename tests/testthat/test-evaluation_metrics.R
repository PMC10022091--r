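test_that("confusion counts are exhaustive and validated", {
  expect_equal(confusionCounts(c(1, 0), c(1, 0)),
               c(TP = 1L, TN = 1L, FP = 0L, FN = 0L))
  expect_equal(confusionCounts(c(1, 1, 0, 0), c(1, 0, 1, 0)),
               c(TP = 1L, TN = 1L, FP = 1L, FN = 1L))
  set.seed(14)
  y <- rbinom(200, 1, 0.4); p <- rbinom(200, 1, 0.5)
  cc <- confusionCounts(y, p)
  # independent per-element tally
  tally <- c(TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  for (i in seq_along(y)) {
    k <- if (y[i] == 1 && p[i] == 1) "TP" else if (y[i] == 0 && p[i] == 0)
      "TN" else if (y[i] == 0) "FP" else "FN"
    tally[k] <- tally[k] + 1L
  }
  expect_equal(cc, tally)
  expect_equal(sum(cc), 200L)
  expect_error(confusionCounts(c(1, 0), c(1, 0, 1)), "length")
  expect_error(confusionCounts(c(1, 2), c(1, 0)), "0 or 1")
})

test_that("threshold metrics match direct substitution on the worked table", {
  m <- thresholdMetrics(c(TP = 6, TN = 3, FP = 1, FN = 2))
  expect_equal(unname(m["ACC"]), 0.75)
  expect_equal(unname(m["Prec"]), 6 / 7, tolerance = 1e-12)
  expect_equal(unname(m["Rec"]), 0.75)
  expect_equal(unname(m["F1"]), 0.8)
  expect_equal(unname(m["MCC"]), 16 / sqrt(1120), tolerance = 1e-12)
  expect_equal(unname(m["BACC"]), 0.75)
  pe <- (8 * 7 + 4 * 5) / 144
  expect_equal(unname(m["Kappa"]), (0.75 - pe) / (1 - pe), tolerance = 1e-12)

  perfect <- thresholdMetrics(c(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_equal(unname(perfect), rep(1, 7))

  # all predictions negative: precision and the MCC root are degenerate
  onesided <- thresholdMetrics(c(TP = 0, TN = 5, FP = 0, FN = 5))
  expect_equal(unname(onesided[c("Prec", "Rec", "F1", "MCC")]),
               c(0, 0, 0, 0))
})

test_that("confusion-derived metrics agree with the raw-label reference on random tables", {
  set.seed(15)
  checked <- 0L
  while (checked < 500L) {
    n <- sample(10:60, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    pred <- rbinom(n, 1, runif(1, 0.2, 0.8))
    # the reference route needs both classes on both margins and at least
    # one true positive (degenerate-denominator fallbacks differ by design)
    if (length(unique(y)) < 2L || length(unique(pred)) < 2L ||
        sum(y == 1 & pred == 1) == 0L) next
    got <- thresholdMetrics(confusionCounts(y, pred))
    want <- metrics_raw_oracle(y, pred)
    expect_equal(got[names(want)], want, tolerance = 1e-10)
    checked <- checked + 1L
  }
})

test_that("MCC flips sign under prediction complement", {
  set.seed(16)
  for (i in 1:20) {
    y <- rbinom(30, 1, 0.5); pred <- rbinom(30, 1, 0.5)
    cc <- confusionCounts(y, pred)
    if (any(cc == 0)) next
    m1 <- thresholdMetrics(cc)["MCC"]
    m2 <- thresholdMetrics(confusionCounts(y, 1 - pred))["MCC"]
    expect_equal(unname(m1), -unname(m2), tolerance = 1e-12)
  }
})

test_that("ROC-AUC equals exhaustive pair enumeration and is rank-invariant", {
  expect_equal(rocAuc(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.1)), 1)
  expect_equal(rocAuc(c(1, 0, 1, 0), c(0.9, 0.8, 0.3, 0.1)), 0.75)
  expect_equal(rocAuc(c(1, 0, 1, 0), rep(0.4, 4)), 0.5)
  expect_error(rocAuc(c(1, 1), c(0.2, 0.4)), "single class")
  set.seed(17)
  for (i in 1:30) {
    n <- sample(8:40, 1)
    y <- c(0, 1, rbinom(n, 1, 0.5))
    p <- round(runif(n + 2), 2)   # rounding forces ties
    expect_equal(rocAuc(y, p), auc_pair_oracle(y, p), tolerance = 1e-12)
    # strictly monotone transform leaves the rank statistic unchanged
    expect_equal(rocAuc(y, plogis(3 * p - 1)), rocAuc(y, p),
                 tolerance = 1e-12)
  }
})

test_that("ROC-AUC agrees with an external reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(18)
  y <- c(0, 1, rbinom(60, 1, 0.5))
  p <- runif(62)
  ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                        direction = "<")))
  expect_equal(rocAuc(y, p), ref, tolerance = 1e-10)
})

test_that("average precision equals the threshold-sweep oracle", {
  expect_equal(averagePrecision(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.1)), 1)
  expect_equal(averagePrecision(c(1, 0, 1, 0), c(0.9, 0.8, 0.3, 0.1)),
               0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-12)
  expect_error(averagePrecision(c(0, 0), c(0.2, 0.4)), "positives")
  set.seed(19)
  for (i in 1:100) {
    n <- sample(6:40, 1)
    y <- c(1, rbinom(n, 1, 0.4))
    p <- round(runif(n + 1), 2)
    expect_equal(averagePrecision(y, p), ap_sweep_oracle(y, p),
                 tolerance = 1e-12)
  }
})

test_that("metricReport assembles a valid nine-metric object", {
  set.seed(20)
  y <- rbinom(50, 1, 0.4)
  prob <- runif(50)
  rep <- metricReport(y, prob)
  expect_s4_class(rep, "MetricReport")
  m <- metrics(rep)
  expect_named(m, c("ACC", "BACC", "Prec", "Rec", "F1", "ROC_AUC", "MCC",
                    "Kappa", "AP"))
  expect_identical(sum(confusion(rep)), 50L)
  # kappa recomputed independently from the raw labels
  pred <- binarize(prob)
  expect_equal(unname(m["Kappa"]), unname(metrics_raw_oracle(y, pred)["Kappa"]),
               tolerance = 1e-12)
  # serialization round trip
  f <- withr::local_tempfile(fileext = ".json")
  writeMetricReport(rep, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$metrics$ACC, unname(m["ACC"]))
})
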