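# one featurized benchmark shared across blocks (built once; seeded)
benchDataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressMessages(featurizeDataset(
        simulateProtamineBenchmark(nPos = 50, nNeg = 50, seed = 101)))
    cache
  }
})

test_that("the 80/20 stratified split partitions the data with per-class balance", {
  ds <- benchDataset()
  parts <- splitDataset(ds, seed = 1)
  expect_equal(ncol(parts$train), 80L)
  expect_equal(ncol(parts$test), 20L)
  expect_equal(as.integer(table(classLabels(parts$train))), c(40L, 40L))
  expect_equal(as.integer(table(classLabels(parts$test))), c(10L, 10L))
  expect_length(intersect(colnames(parts$train), colnames(parts$test)), 0)
  expect_setequal(c(colnames(parts$train), colnames(parts$test)), colnames(ds))

  parts2 <- splitDataset(ds, seed = 1)
  expect_identical(colnames(parts2$train), colnames(parts$train))
  parts3 <- splitDataset(ds, seed = 2)
  expect_false(identical(colnames(parts3$train), colnames(parts$train)))
})

test_that("cross-validation folds partition the training set with sizes within one", {
  ds <- benchDataset()
  cv <- crossValidate(ds, modelSpec("lr"), folds = 10, seed = 3)
  expect_equal(nrow(cv$perFold), 10L)
  expect_true(all(c("acc", "kappa", "mcc", "auc") %in% colnames(cv$perFold)))
  # separable benchmark: an MLP cross-validates nearly perfectly
  cvMlp <- crossValidate(ds, modelSpec("mlp"), folds = 10, seed = 3)
  expect_gte(cvMlp$summary[["acc"]], 0.95)
  expect_error(crossValidate(ds[, c(1:5, 51:55)], modelSpec("lr"),
                             folds = 10), "rows per class")
})

test_that("every registry backend trains, scores in [0,1], and flags wrong widths", {
  ds <- benchDataset()
  for (alg in modelRegistry()) {
    model <- trainModel(ds, modelSpec(alg, seed = 7))
    pred <- predict(model, ds)
    expect_true(all(pred$score >= 0 & pred$score <= 1), label = alg)
    expect_true(all(pred$label %in% c("YES", "NO")), label = alg)
    # training accuracy on the separable benchmark
    expect_gte(mean((pred$label == "YES") == (classLabels(ds) == 1)), 0.99)
    expect_error(predict(model, featureMatrix(ds)[, 1:10]), "width")
  }
  expect_error(modelSpec("perceptron"), "unknown algorithm")
  expect_error(trainModel(ds[, classLabels(ds) == 1], modelSpec("lr")),
               "both classes")
})

test_that("labels flip monotonically as the decision threshold sweeps", {
  ds <- benchDataset()
  model <- trainModel(ds, modelSpec("lr"))
  scores <- predict(model, ds)$score
  nYes <- vapply(seq(0, 1, by = 0.1),
                 function(t) sum(scores >= t), integer(1))
  expect_true(all(diff(nYes) <= 0))
  # ties at the threshold go to YES
  m2 <- model; m2@threshold <- scores[1]
  expect_equal(predict(m2, featureMatrix(ds)[1, , drop = FALSE])$label, "YES")
})

test_that("deterministic backends reproduce predictions under a fixed seed", {
  ds <- benchDataset()
  for (alg in c("rf", "mlp", "xgboost", "rbf-svm")) {
    m1 <- trainModel(ds, modelSpec(alg, seed = 11))
    m2 <- trainModel(ds, modelSpec(alg, seed = 11))
    expect_equal(predict(m1, ds)$score, predict(m2, ds)$score, label = alg)
  }
})

test_that("the experiment harness reports CV and test blocks per algorithm and mode", {
  ds <- benchDataset()
  rep <- runExperiment(ds, augmentation = "none",
                       algorithms = c("lr", "knn"), folds = 5, seed = 1)
  expect_named(rep$results, c("lr", "knn"))
  for (r in rep$results) {
    expect_true(all(r$test[c("acc", "recall", "precision", "f1", "fpr", "auc")]
                    >= 0 & r$test[c("acc", "recall", "precision", "f1",
                                    "fpr", "auc")] <= 1))
    expect_true(all(abs(r$test[c("kappa", "mcc")]) <= 1))
    expect_true(all(r$cv[c("acc", "auc")] >= 0 & r$cv[c("acc", "auc")] <= 1))
  }
  expect_equal(rep$config$augmentation, "none")

  # both leakage modes run and are labeled in the config echo
  imb <- suppressMessages(featurizeDataset(
    simulateProtamineBenchmark(nPos = 30, nNeg = 60, seed = 102)))
  repPaper <- runExperiment(imb, "smote", algorithms = "lr", folds = 5,
                            leakageMode = "paper", seed = 1)
  repSafe <- runExperiment(imb, "smote", algorithms = "lr", folds = 5,
                           leakageMode = "safe", seed = 1)
  expect_equal(repPaper$config$leakageMode, "paper")
  expect_equal(repSafe$config$leakageMode, "safe")
  # paper mode trains/tests on the augmented pool (larger than the input)
  expect_gt(sum(repPaper$results$lr$counts), ncol(imb))

  f <- withr::local_tempfile(fileext = ".json")
  fcsv <- withr::local_tempfile(fileext = ".csv")
  writeExperimentReport(repPaper, f, fcsv)
  parsed <- jsonlite::read_json(f)
  expect_equal(parsed$config$leakageMode, "paper")
  expect_true(!is.null(parsed$results$lr$test$acc))
  expect_equal(nrow(read.csv(fcsv)), 2L)  # cv + test rows for one algorithm
})

test_that("augment-then-split leaks: safe-mode accuracy does not exceed paper-mode on average", {
  # overlapping classes (low arginine enrichment) so leakage has room to
  # inflate; trend asserted over seeds, not per seed
  deltas <- vapply(1:10, function(s) {
    bench <- simulateProtamineBenchmark(nPos = 25, nNeg = 75,
                                        posLengthRange = c(20L, 60L),
                                        negLengthRange = c(20L, 60L),
                                        posArgFraction = 0.12, seed = 200 + s)
    ds <- suppressMessages(featurizeDataset(bench))
    p <- runExperiment(ds, "smote", algorithms = "knn", folds = 5,
                       leakageMode = "paper", seed = s)
    q <- runExperiment(ds, "smote", algorithms = "knn", folds = 5,
                       leakageMode = "safe", seed = s)
    p$results$knn$test[["acc"]] - q$results$knn$test[["acc"]]
  }, numeric(1))
  expect_gte(mean(deltas), 0)
})
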