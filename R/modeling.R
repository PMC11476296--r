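#' @include augment.R metrics.R
NULL

# ---------------------------------------------------------------------------
# model registry: each entry knows how to fit on (x, y) and how to emit a
# probability-like score in [0, 1] for the positive class. Hyperparameters
# are backend defaults unless listed in `params`; everything is echoed into
# reports. Probability sources per backend are documented in ?modelRegistry.
# ---------------------------------------------------------------------------

.clamp01 <- function(p) pmin(pmax(p, 0), 1)

.registry <- local({
  reg <- list()

  # histogram-based gradient-boosted trees (LightGBM-style leaf-wise
  # growth, 31 leaves) via xgboost
  reg[["lightgbm"]] <- list(
    fit = function(x, y, seed, params) {
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", tree_method = "hist",
                      grow_policy = "lossguide", max_leaves = 31L,
                      nthread = 1L, seed = seed),
        data = xgboost::xgb.DMatrix(x, label = y, nthread = 1L),
        nrounds = params$nrounds %||% 100L, verbose = 0)
    },
    prob = function(fit, x)
      predict(fit, xgboost::xgb.DMatrix(x, nthread = 1L)))

  reg[["mlp"]] <- list(
    fit = function(x, y, seed, params) {
      size <- params$size %||% 32L
      withSeed(seed,
        nnet::nnet(x, y, size = size, decay = params$decay %||% 1e-4,
                   maxit = params$maxit %||% 200L, MaxNWts = 10000L,
                   entropy = TRUE, trace = FALSE))
    },
    prob = function(fit, x) .clamp01(as.numeric(predict(fit, x))))

  reg[["rf"]] <- list(
    fit = function(x, y, seed, params) {
      withSeed(seed,
        randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                   ntree = params$ntree %||% 500L))
    },
    prob = function(fit, x) predict(fit, x, type = "prob")[, "1"])

  reg[["xgboost"]] <- list(
    fit = function(x, y, seed, params) {
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", nthread = 1L,
                      seed = seed),
        data = xgboost::xgb.DMatrix(x, label = y, nthread = 1L),
        nrounds = params$nrounds %||% 100L, verbose = 0)
    },
    prob = function(fit, x)
      predict(fit, xgboost::xgb.DMatrix(x, nthread = 1L)))

  # kNN is lazy: "fit" stores the training set; score = fraction of the k
  # neighbours voting for the positive class
  reg[["knn"]] <- list(
    fit = function(x, y, seed, params) {
      list(x = x, y = y, k = params$k %||% 5L, seed = seed)
    },
    prob = function(fit, x) {
      pred <- withSeed(fit$seed,
        class::knn(fit$x, x, factor(fit$y, levels = c(0, 1)),
                   k = fit$k, prob = TRUE))
      winning <- attr(pred, "prob")
      ifelse(pred == "1", winning, 1 - winning)
    })

  reg[["lr"]] <- list(
    fit = function(x, y, seed, params) {
      df <- data.frame(x); df$.y <- y
      suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
    },
    prob = function(fit, x) {
      suppressWarnings(as.numeric(predict(fit, data.frame(x),
                                          type = "response")))
    })

  reg[["nb"]] <- list(
    fit = function(x, y, seed, params) {
      e1071::naiveBayes(x, factor(y, levels = c(0, 1)))
    },
    prob = function(fit, x) predict(fit, x, type = "raw")[, "1"])

  reg[["rbf-svm"]] <- list(
    fit = function(x, y, seed, params) {
      withSeed(seed,
        e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
                   probability = TRUE))
    },
    prob = function(fit, x) {
      attr(predict(fit, x, probability = TRUE), "probabilities")[, "1"]
    })

  reg
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The classifier registry
#'
#' Eight classifier families addressed by name (case-insensitive):
#' `lightgbm` (histogram gradient-boosted trees via xgboost's `hist`
#' method with 31 leaves, the LightGBM growth strategy), `mlp` (single
#' hidden layer of 32 units, `nnet`), `rf` (`randomForest`, 500 trees),
#' `xgboost` (100 rounds, logistic objective), `knn` (k = 5, score =
#' neighbour vote fraction), `lr` (binomial GLM), `nb` (Gaussian naive
#' Bayes, `e1071`), `rbf-svm` (radial kernel SVM with Platt-scaled
#' probabilities, `e1071`). All emit a positive-class score in \[0, 1\]:
#' native probabilities everywhere except kNN (vote fraction).
#'
#' @return Character vector of registry names.
#' @export
modelRegistry <- function() names(.registry)

#' Specify a classifier
#'
#' @param algorithm Registry name, see [modelRegistry()]; case-insensitive.
#' @param params Named list of hyperparameter overrides (backend defaults
#'   otherwise).
#' @param seed Integer seed for stochastic backends.
#' @return A validated model specification list.
#' @export
modelSpec <- function(algorithm, params = list(), seed = 1L) {
  key <- tolower(algorithm)
  stopIfNot(key %in% names(.registry),
            sprintf("unknown algorithm '%s'; registry: %s", algorithm,
                    paste(modelRegistry(), collapse = ", ")))
  list(algorithm = key, params = params, seed = as.integer(seed))
}

.featuresAndLabels <- function(data) {
  if (methods::is(data, "PseAACSet"))
    list(x = featureMatrix(data), y = classLabels(data))
  else
    list(x = as.matrix(data$x), y = data$y)
}

#' Split a dataset into train and test sets
#'
#' 80/20 by default, sizes rounding towards the training side. With
#' `stratified = TRUE` the split is performed per class, preserving class
#' ratios within one sample. Deterministic under `seed`.
#'
#' @param dataset A labeled [PseAACSet-class].
#' @param trainFraction Fraction assigned to training, in (0, 1).
#' @param stratified Split within each class.
#' @param seed Integer seed.
#' @return List with `train` and `test` [PseAACSet-class] objects.
#' @export
splitDataset <- function(dataset, trainFraction = 0.8, stratified = TRUE,
                         seed = NULL) {
  stopIfNot(trainFraction > 0 && trainFraction < 1,
            "trainFraction must lie in (0, 1)")
  lab <- classLabels(dataset)
  n <- ncol(dataset)
  stopIfNot(n >= 10L, "need at least 10 samples to split")
  idxTrain <- withSeed(seed, {
    if (stratified) {
      stopIfNot(!anyNA(lab), "stratified split requires labels")
      unlist(lapply(unique(lab), function(g) {
        ig <- which(lab == g)
        sample(ig, ceiling(trainFraction * length(ig)))
      }), use.names = FALSE)
    } else sample.int(n, ceiling(trainFraction * n))
  })
  idxTrain <- sort(idxTrain)
  train <- dataset[, idxTrain]
  test <- dataset[, setdiff(seq_len(n), idxTrain)]
  if (stratified) {
    stopIfNot(length(unique(classLabels(test))) == 2L,
              "a class is absent from the test split")
  }
  list(train = train, test = test)
}

# stratified fold assignment: within each class, shuffled round-robin
.foldAssign <- function(y, folds) {
  fold <- integer(length(y))
  for (g in unique(y)) {
    ig <- sample(which(y == g))
    fold[ig] <- rep_len(seq_len(folds), length(ig))
  }
  fold
}

#' Train a classifier
#'
#' @param train A labeled [PseAACSet-class] (or `list(x=, y=)`).
#' @param spec A [modelSpec()].
#' @param threshold Decision threshold on the score (ties go to YES).
#' @return A [ProtamineModel-class].
#' @export
trainModel <- function(train, spec, threshold = 0.5) {
  d <- .featuresAndLabels(train)
  stopIfNot(length(unique(d$y)) == 2L, "both classes must be present")
  entry <- .registry[[spec$algorithm]]
  fit <- tryCatch(entry$fit(d$x, d$y, spec$seed, spec$params),
                  error = function(e)
                    stop(sprintf("backend '%s' failed: %s", spec$algorithm,
                                 conditionMessage(e)), call. = FALSE))
  methods::new("ProtamineModel", fit = fit, algorithm = spec$algorithm,
               threshold = threshold, nFeatures = ncol(d$x),
               info = list(params = spec$params, seed = spec$seed))
}

#' Predict protamine status
#'
#' @param object A [ProtamineModel-class].
#' @param newdata Feature matrix (samples x components) or [PseAACSet-class].
#' @param ... Unused.
#' @return data.frame with `score` in \[0, 1\] and `label` (`"YES"` iff
#'   score >= threshold, else `"NO"`).
#' @export
setMethod("predict", "ProtamineModel", function(object, newdata, ...) {
  x <- if (methods::is(newdata, "PseAACSet")) featureMatrix(newdata)
       else as.matrix(newdata)
  stopIfNot(ncol(x) == object@nFeatures,
            sprintf("feature width %d does not match model width %d",
                    ncol(x), object@nFeatures))
  stopIfNot(all(is.finite(x)), "features contain non-finite values")
  score <- as.numeric(.registry[[object@algorithm]]$prob(object@fit, x))
  data.frame(score = score,
             label = ifelse(score >= object@threshold, "YES", "NO"),
             row.names = rownames(x))
})

#' Stratified k-fold cross-validation
#'
#' Folds are stratified by class and differ in size by at most one. Each
#' fold is scored with the full metric bundle on its held-out part; the
#' summary is the unweighted mean across folds.
#'
#' @param train A labeled [PseAACSet-class].
#' @param spec A [modelSpec()].
#' @param folds Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param augmentFolds Optional function applied to each within-fold
#'   training [PseAACSet-class] before fitting (leakage-safe
#'   augmentation); `NULL` = none.
#' @return List with `perFold` (data.frame of metrics per fold) and
#'   `summary` (named numeric means).
#' @export
crossValidate <- function(train, spec, folds = 10L, seed = NULL,
                          augmentFolds = NULL) {
  y <- classLabels(train)
  stopIfNot(!anyNA(y), "all rows must be labeled")
  stopIfNot(all(table(y) >= folds),
            sprintf("need >= %d rows per class for %d folds", folds, folds))
  fold <- withSeed(seed, .foldAssign(y, folds))
  rows <- lapply(seq_len(folds), function(f) {
    tr <- train[, fold != f]
    if (!is.null(augmentFolds)) tr <- augmentFolds(tr)
    te <- train[, fold == f]
    stopIfNot(length(unique(classLabels(te))) == 2L,
              sprintf("fold %d lacks a class", f))
    model <- trainModel(tr, spec)
    pred <- predict(model, te)
    rep <- evaluatePredictions(classLabels(te),
                               as.integer(pred$label == "YES"), pred$score)
    c(fold = f, metricValues(rep))
  })
  perFold <- as.data.frame(do.call(rbind, rows))
  list(perFold = perFold,
       summary = colMeans(perFold[, setdiff(colnames(perFold), "fold")]),
       algorithm = spec$algorithm)
}

#' Run the full benchmarking experiment
#'
#' For each requested algorithm: balance (optionally), split 80/20
#' stratified, 10-fold cross-validate on the training portion, fit on the
#' full training portion and score the independent test set. Two leakage
#' regimes are provided: `"paper"` augments the whole dataset before
#' splitting (synthetic neighbours of test points can enter training);
#' `"safe"` splits first and augments only training data — inside each CV
#' fold, only that fold's training part.
#'
#' @param data A labeled [PseAACSet-class], or an
#'   [Biostrings::AAStringSet] (featurized with defaults).
#' @param augmentation `"none"`, `"smote"` or `"gan"`.
#' @param algorithms Registry names (default: all eight).
#' @param leakageMode `"paper"` or `"safe"`.
#' @param folds CV folds.
#' @param trainFraction Train share of the split.
#' @param seed Global seed; propagated (with fixed offsets) to balancing,
#'   splitting, fold assignment and backends.
#' @param smoteK SMOTE neighbour count.
#' @param gan A [ganConfig()] for `augmentation = "gan"` (its seed is
#'   overridden from `seed`).
#' @return An experiment report: list with `results` (per-algorithm list
#'   of `cv`, `test`, `counts`) and `config` echo. See
#'   [writeExperimentReport()].
#' @export
runExperiment <- function(data, augmentation = c("none", "smote", "gan"),
                          algorithms = modelRegistry(),
                          leakageMode = c("paper", "safe"),
                          folds = 10L, trainFraction = 0.8, seed = 1L,
                          smoteK = 5L, gan = ganConfig()) {
  augmentation <- match.arg(augmentation)
  leakageMode <- match.arg(leakageMode)
  dataset <- if (methods::is(data, "PseAACSet")) data else featurizeDataset(data)
  gan$outDim <- nrow(dataset)
  gan$seed <- deriveSeed(seed, 11L)

  balance <- switch(augmentation,
    none = identity,
    smote = function(d) smoteOversample(d, kNeighbors = smoteK,
                                        seed = deriveSeed(seed, 12L)),
    gan = function(d) balanceWithGAN(d, gan))

  if (leakageMode == "paper") {
    full <- balance(dataset)
    parts <- splitDataset(full, trainFraction, stratified = TRUE,
                          seed = deriveSeed(seed, 13L))
    cvAugment <- NULL
  } else {
    parts <- splitDataset(dataset, trainFraction, stratified = TRUE,
                          seed = deriveSeed(seed, 13L))
    parts$train <- balance(parts$train)
    cvAugment <- if (augmentation == "none") NULL else balance
  }

  results <- lapply(algorithms, function(alg) {
    spec <- modelSpec(alg, seed = deriveSeed(seed, 14L))
    cv <- crossValidate(parts$train, spec, folds = folds,
                        seed = deriveSeed(seed, 15L),
                        augmentFolds = cvAugment)
    model <- trainModel(parts$train, spec)
    pred <- predict(model, parts$test)
    test <- evaluatePredictions(classLabels(parts$test),
                                as.integer(pred$label == "YES"), pred$score)
    list(algorithm = alg, cv = cv$summary, cvPerFold = cv$perFold,
         test = metricValues(test),
         counts = c(train = ncol(parts$train), test = ncol(parts$test)))
  })
  names(results) <- algorithms

  list(results = results,
       config = list(augmentation = augmentation, leakageMode = leakageMode,
                     algorithms = algorithms, folds = folds,
                     trainFraction = trainFraction, seed = seed,
                     smoteK = smoteK,
                     gan = gan[c("outDim", "noiseDim", "epochs", "batchSize",
                                 "lr", "beta1", "leakyAlpha", "dropout")],
                     lambda = S4Vectors::metadata(dataset)$lambda,
                     weight = S4Vectors::metadata(dataset)$weight))
}

#' Serialize an experiment report
#'
#' Writes the full report (per-algorithm CV and test metric blocks plus
#' the config echo) as JSON, and optionally a flat CSV with one row per
#' algorithm x stage.
#'
#' @param report Output of [runExperiment()].
#' @param jsonPath Path for the JSON report.
#' @param csvPath Optional path for the flat CSV.
#' @return Invisibly, `jsonPath`.
#' @export
writeExperimentReport <- function(report, jsonPath, csvPath = NULL) {
  out <- list(config = report$config,
              results = lapply(report$results, function(r) {
                list(algorithm = r$algorithm,
                     cv = as.list(r$cv), test = as.list(r$test),
                     counts = as.list(r$counts))
              }))
  jsonlite::write_json(out, jsonPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(csvPath)) {
    rows <- do.call(rbind, lapply(report$results, function(r) {
      rbind(data.frame(algorithm = r$algorithm, stage = "cv", t(r$cv)),
            data.frame(algorithm = r$algorithm, stage = "test", t(r$test)))
    }))
    write.csv(rows, csvPath, row.names = FALSE)
  }
  invisible(jsonPath)
}
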