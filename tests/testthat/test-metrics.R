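test_that("confusion counts tally the four cells with positive class 1", {
  cc <- confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(c(cc@tp, cc@fn, cc@tn, cc@fp), c(1L, 1L, 1L, 1L))
  y <- rep(c(1, 0), 10)
  ccSame <- confusionCounts(y, y)
  expect_equal(ccSame@fp + ccSame@fn, 0L)
  expect_equal(cc@tp + cc@fp + cc@fn + cc@tn, 4L)
  expect_error(confusionCounts(c(1, 0), c(1)), "length")
  expect_error(confusionCounts(c(1, 2), c(1, 0)), "binary")
})

test_that("the metric bundle reproduces hand-derived values on a worked table", {
  rep <- computeMetrics(methods::new("ConfusionCounts", tp = 50L, fp = 10L,
                                     fn = 5L, tn = 35L))
  v <- round(metricValues(rep), 4)  # hand-derived values carry 4 decimals
  expect_equal(unname(v["acc"]), 0.85)
  expect_equal(unname(v["recall"]), 0.9091)
  expect_equal(unname(v["precision"]), 0.8333)
  expect_equal(unname(v["f1"]), 0.8696)
  expect_equal(unname(v["fpr"]), 0.2222)
  expect_equal(unname(v["kappa"]), 0.6939)
  expect_equal(unname(v["mcc"]), 0.6975)
})

test_that("perfect and degenerate confusion tables follow the conventions", {
  perfect <- metricValues(computeMetrics(
    methods::new("ConfusionCounts", tp = 7L, fp = 0L, fn = 0L, tn = 13L)))
  expect_equal(unname(perfect[c("acc", "f1", "kappa", "mcc")]), rep(1, 4))
  expect_equal(unname(perfect["fpr"]), 0)

  # all-one-class truth, matching prediction: Pe = 1 so kappa degenerates
  oneClass <- computeMetrics(
    methods::new("ConfusionCounts", tp = 10L, fp = 0L, fn = 0L, tn = 0L))
  expect_equal(oneClass@kappa, 0)
  expect_true(all(c("kappa", "mcc", "fpr") %in% oneClass@degenerate))

  # zero positive predictions: precision degenerates to 0
  noPos <- computeMetrics(
    methods::new("ConfusionCounts", tp = 0L, fp = 0L, fn = 4L, tn = 6L))
  expect_equal(noPos@precision, 0)
  expect_true("precision" %in% noPos@degenerate)
})

test_that("metrics agree with brute-force arithmetic on random confusion tables", {
  set.seed(21)
  for (i in 1:200) {
    cells <- as.integer(rmultinom(1, sample(4:500, 1), runif(4)))
    cc <- methods::new("ConfusionCounts", tp = cells[1], fp = cells[2],
                       fn = cells[3], tn = cells[4])
    got <- metricValues(computeMetrics(cc))
    want <- oracleMetrics(cells[1], cells[2], cells[3], cells[4])
    for (m in names(want))
      expect_equal(unname(got[m]), want[[m]], tolerance = 1e-9,
                   label = sprintf("%s on table %s", m,
                                   paste(cells, collapse = "/")))
  }
})

test_that("MCC is invariant under a simultaneous class swap and FPR = 1 - specificity", {
  set.seed(22)
  for (i in 1:50) {
    y <- rbinom(60, 1, 0.4); p <- rbinom(60, 1, 0.5)
    a <- metricValues(computeMetrics(confusionCounts(y, p)))
    b <- metricValues(computeMetrics(confusionCounts(1 - y, 1 - p)))
    expect_equal(a["mcc"], b["mcc"], tolerance = 1e-12)
    cc <- confusionCounts(y, p)
    specificity <- cc@tn / (cc@tn + cc@fp)
    expect_equal(unname(a["fpr"]), 1 - specificity, tolerance = 1e-12)
  }
})

test_that("AUC equals the pairwise rank statistic and honors tie/transform invariances", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(rocAuc(rep(0.5, 10), rep(c(1, 0), 5))$auc, 0.5)

  set.seed(23)
  y <- rbinom(200, 1, 0.5)
  y[1:2] <- c(0, 1)  # both classes guaranteed
  s <- round(runif(200), 2)  # ties present
  res <- rocAuc(s, y)
  expect_identical(res$auc, oracleAucPairwise(s, y))
  # invariant under strictly monotone transforms of the scores
  expect_equal(rocAuc(qlogis(pmin(pmax(s, 1e-3), 1 - 1e-3)), y)$auc,
               rocAuc(pmin(pmax(s, 1e-3), 1 - 1e-3), y)$auc)
  expect_equal(rocAuc(s * 100 - 3, y)$auc, res$auc)
  # curve ends at (1, 1) and is monotone
  curve <- res$curve
  expect_equal(curve$fpr[nrow(curve)], 1)
  expect_equal(curve$tpr[nrow(curve)], 1)
  expect_true(all(diff(curve$fpr) >= 0) && all(diff(curve$tpr) >= 0))

  expect_error(rocAuc(runif(5), rep(1, 5)), "both classes")
})

test_that("AUC matches an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(24)
  y <- rbinom(150, 1, 0.5); y[1:2] <- c(0, 1)
  s <- runif(150)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(rocAuc(s, y)$auc, ref, tolerance = 1e-12)
})
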