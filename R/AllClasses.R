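#' @include AllGenerics.R
NULL

#' PseAACSet: a labeled pseudo amino acid composition dataset
#'
#' A \linkS4class{SummarizedExperiment} holding one pseudo amino acid
#' composition vector per sample (assay `"pseaac"`, components x samples),
#' the binary class label (1 = protamine, 0 = non-protamine, NA = unknown)
#' and the provenance of each row (`"real"` for vectors computed from an
#' input sequence, `"smote"` / `"gan"` for oversampled rows).
#'
#' Component metadata lives in `rowData()`: the first 20 components are the
#' residue frequencies in alphabetical one-letter order, the remaining
#' `lambda` components are sequence-order correlation factors at lags
#' 1..lambda. `metadata()` records `lambda`, `weight` and any skipped
#' input records.
#'
#' @seealso [featurizeDataset()], [smoteOversample()], [balanceWithGAN()]
#' @export
setClass("PseAACSet", contains = "SummarizedExperiment")

setValidity("PseAACSet", function(object) {
  msg <- NULL
  if (!"pseaac" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'pseaac' is required")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("label", "provenance") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'label' and 'provenance'")
  else {
    lab <- cd$label
    if (!all(is.na(lab) | lab %in% c(0L, 1L)))
      msg <- c(msg, "labels must be 0, 1 or NA")
    if (!all(cd$provenance %in% c("real", "smote", "gan")))
      msg <- c(msg, "provenance must be 'real', 'smote' or 'gan'")
  }
  lambda <- S4Vectors::metadata(object)$lambda
  if (!is.null(lambda) && nrow(object) != 20L + lambda)
    msg <- c(msg, sprintf("expected %d components for lambda = %d, found %d",
                          20L + lambda, lambda, nrow(object)))
  if (is.null(msg)) TRUE else msg
})

#' Construct a PseAACSet from a feature matrix
#'
#' @param features Numeric matrix, samples in rows, 20 + lambda components
#'   in columns.
#' @param labels Integer 0/1 labels (NA allowed), recycled NA if missing.
#' @param provenance Character provenance per row; defaults to `"real"`.
#' @param lambda Number of sequence-order correlation components.
#' @param weight Correlation weight w used when featurizing.
#' @param ids Optional sample identifiers (defaults to rownames).
#' @return A [PseAACSet-class].
#' @examples
#' m <- matrix(runif(60), nrow = 2, ncol = 30)
#' m <- m / rowSums(m)
#' PseAACSet(m, labels = c(1L, 0L))
#' @export
PseAACSet <- function(features, labels = NA_integer_, provenance = "real",
                      lambda = ncol(features) - 20L, weight = 0.05,
                      ids = rownames(features)) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (is.null(ids)) ids <- sprintf("sample%d", seq_len(n))
  labels <- suppressWarnings(as.integer(rep_len(labels, n)))
  provenance <- as.character(rep_len(provenance, n))
  assay <- t(features)
  rownames(assay) <- sprintf("x%d", seq_len(ncol(features)))
  colnames(assay) <- ids
  rowInfo <- S4Vectors::DataFrame(
    type = rep(c("composition", "correlation"), c(20L, lambda)),
    detail = c(AA20, sprintf("lag%d", seq_len(lambda))))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(pseaac = assay),
    rowData = rowInfo,
    colData = S4Vectors::DataFrame(label = labels, provenance = provenance,
                                   row.names = ids),
    metadata = list(lambda = as.integer(lambda), weight = weight))
  methods::new("PseAACSet", se)
}

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "PseAACSet", function(x) {
  t(SummarizedExperiment::assay(x, "pseaac"))
})

#' @rdname classLabels
#' @export
setMethod("classLabels", "PseAACSet", function(x) {
  SummarizedExperiment::colData(x)$label
})

#' @rdname provenance
#' @export
setMethod("provenance", "PseAACSet", function(x) {
  SummarizedExperiment::colData(x)$provenance
})

setMethod("show", "PseAACSet", function(object) {
  lab <- classLabels(object)
  cat(sprintf("PseAACSet: %d samples x %d components (lambda = %s)\n",
              ncol(object), nrow(object),
              S4Vectors::metadata(object)$lambda))
  cat(sprintf("  labels: %d positive / %d negative / %d unlabeled\n",
              sum(lab == 1L, na.rm = TRUE), sum(lab == 0L, na.rm = TRUE),
              sum(is.na(lab))))
  cat("  provenance:",
      paste(sprintf("%s=%d", names(table(provenance(object))),
                    as.integer(table(provenance(object)))), collapse = " "),
      "\n")
})

#' PositionFrequencyMatrix: per-position residue frequencies
#'
#' Holds, for a set of (possibly ragged-length) sequences, the percentage
#' of sequences carrying each of the 20 residues at each alignment-free
#' position, together with the number of sequences covering that position.
#' Columns with coverage sum to 100.
#'
#' @slot freq 20 x Lmax numeric matrix of percentages (rows = residues in
#'   alphabetical one-letter order, columns = positions 1..Lmax).
#' @slot coverage Integer vector: sequences covering each position.
#' @seealso [positionFrequencyMatrix()]
#' @export
setClass("PositionFrequencyMatrix",
         representation(freq = "matrix", coverage = "integer"))

setValidity("PositionFrequencyMatrix", function(object) {
  msg <- NULL
  if (nrow(object@freq) != 20L) msg <- c(msg, "freq must have 20 rows")
  if (ncol(object@freq) != length(object@coverage))
    msg <- c(msg, "coverage length must match freq columns")
  if (any(object@freq < -1e-9 | object@freq > 100 + 1e-9))
    msg <- c(msg, "frequencies must lie in [0, 100]")
  ok <- object@coverage > 0L
  if (any(ok) && any(abs(colSums(object@freq[, ok, drop = FALSE]) - 100) > 1e-6))
    msg <- c(msg, "covered columns must sum to 100")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "PositionFrequencyMatrix", function(object) {
  cat(sprintf("PositionFrequencyMatrix: 20 residues x %d positions (max coverage %d)\n",
              ncol(object@freq), max(object@coverage)))
})

#' ConfusionCounts: binary confusion-matrix cells
#'
#' @slot tp,fp,fn,tn Non-negative integer counts, positive class = 1.
#' @seealso [confusionCounts()], [computeMetrics()]
#' @export
setClass("ConfusionCounts",
         representation(tp = "integer", fp = "integer",
                        fn = "integer", tn = "integer"))

setValidity("ConfusionCounts", function(object) {
  counts <- c(object@tp, object@fp, object@fn, object@tn)
  if (any(counts < 0L)) return("counts must be non-negative")
  if (sum(counts) < 1L) return("at least one observation required")
  TRUE
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d FP=%d FN=%d TN=%d (n=%d)\n",
              object@tp, object@fp, object@fn, object@tn,
              object@tp + object@fp + object@fn + object@tn))
})

#' MetricReport: the classification metric bundle
#'
#' Accuracy, sensitivity (recall/TPR), precision (PPV), F1, Cohen's kappa,
#' Matthews correlation coefficient, false positive rate, and (when scores
#' were available) the ROC AUC. Ratios with a zero denominator are reported
#' as 0 and the affected metric is listed in `degenerate`.
#'
#' @slot acc,recall,precision,f1,fpr Numeric in \[0, 1\].
#' @slot kappa,mcc Numeric in \[-1, 1\].
#' @slot auc Numeric in \[0, 1\], `NA` when no scores were supplied.
#' @slot degenerate Character vector naming metrics whose denominator was 0.
#' @seealso [computeMetrics()], [evaluatePredictions()]
#' @export
setClass("MetricReport",
         representation(acc = "numeric", recall = "numeric",
                        precision = "numeric", f1 = "numeric",
                        kappa = "numeric", mcc = "numeric",
                        fpr = "numeric", auc = "numeric",
                        degenerate = "character"))

setValidity("MetricReport", function(object) {
  msg <- NULL
  unit <- c(acc = object@acc, recall = object@recall,
            precision = object@precision, f1 = object@f1, fpr = object@fpr)
  if (any(unit < -1e-12 | unit > 1 + 1e-12))
    msg <- c(msg, "acc/recall/precision/f1/fpr must lie in [0, 1]")
  if (!is.na(object@auc) && (object@auc < -1e-12 || object@auc > 1 + 1e-12))
    msg <- c(msg, "auc must lie in [0, 1]")
  corr <- c(object@kappa, object@mcc)
  if (any(corr < -1 - 1e-12 | corr > 1 + 1e-12))
    msg <- c(msg, "kappa and mcc must lie in [-1, 1]")
  if (is.null(msg)) TRUE else msg
})

#' @rdname metricValues
#' @export
setMethod("metricValues", "MetricReport", function(x) {
  c(acc = x@acc, recall = x@recall, precision = x@precision, f1 = x@f1,
    kappa = x@kappa, mcc = x@mcc, auc = x@auc, fpr = x@fpr)
})

setMethod("show", "MetricReport", function(object) {
  v <- metricValues(object)
  cat("MetricReport:\n")
  print(round(v, 4))
  if (length(object@degenerate))
    cat("  degenerate (reported as 0):",
        paste(object@degenerate, collapse = ", "), "\n")
})

#' TrainedGenerator: fitted tabular GAN generator
#'
#' The generator half of the adversarially trained network pair, ready for
#' sampling synthetic feature rows, together with the per-epoch loss traces
#' and an echo of the training configuration.
#'
#' @slot layers List of generator dense-layer weights (`W`, `b`).
#' @slot config The [ganConfig()] list used for training.
#' @slot losses Numeric matrix (epochs x 2) of mean discriminator and
#'   generator binary cross-entropy per epoch.
#' @seealso [ganTrain()], [ganSample()]
#' @export
setClass("TrainedGenerator",
         representation(layers = "list", config = "list", losses = "matrix"))

setValidity("TrainedGenerator", function(object) {
  if (!all(is.finite(object@losses))) return("loss trace contains non-finite values")
  TRUE
})

setMethod("show", "TrainedGenerator", function(object) {
  cfg <- object@config
  cat(sprintf("TrainedGenerator: noise %d -> %s -> %d features, %d epochs\n",
              cfg$noiseDim,
              paste(cfg$generatorWidths[-length(cfg$generatorWidths)],
                    collapse = "/"),
              cfg$outDim, nrow(object@losses)))
  last <- object@losses[nrow(object@losses), ]
  cat(sprintf("  final losses: D=%.4f G=%.4f\n", last[1], last[2]))
})

#' ProtamineModel: a fitted binary protamine classifier
#'
#' Wraps a backend fit from the model registry, the decision threshold and
#' the expected feature width. `predict()` returns YES/NO labels and a
#' probability-like score in \[0, 1\] (YES iff score >= threshold; ties go
#' to YES).
#'
#' @slot fit Backend-specific fitted object.
#' @slot algorithm Registry identifier (e.g. `"mlp"`, `"rbf-svm"`).
#' @slot threshold Decision threshold on the score, default 0.5.
#' @slot nFeatures Expected feature dimension.
#' @slot info Hyperparameter and seed echo for reproducibility.
#' @seealso [trainModel()], [modelRegistry()]
#' @export
setClass("ProtamineModel",
         representation(fit = "ANY", algorithm = "character",
                        threshold = "numeric", nFeatures = "integer",
                        info = "list"))

setMethod("show", "ProtamineModel", function(object) {
  cat(sprintf("ProtamineModel: %s over %d features (threshold %.2f)\n",
              object@algorithm, object@nFeatures, object@threshold))
})
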