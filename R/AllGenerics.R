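#' @include utils.R
NULL

#' Feature matrix of a PseAACSet
#'
#' Returns the descriptor matrix with samples in rows and the 20 + lambda
#' pseudo amino acid composition components in columns.
#'
#' @param x A [PseAACSet-class] object.
#' @return A numeric matrix (samples x components).
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' Class labels of a dataset
#'
#' @param x A [PseAACSet-class] object.
#' @return Integer vector of 0/1 labels (NA where unlabeled).
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' Row provenance of a dataset
#'
#' Each row of a feature table is tagged `"real"`, `"smote"` or `"gan"`
#' depending on whether it was computed from an input sequence or created
#' by an oversampler.
#'
#' @param x A [PseAACSet-class] object.
#' @return Character vector of provenance tags.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Draw synthetic feature rows from a trained generator
#'
#' @param object A [TrainedGenerator-class].
#' @param n Number of rows to draw.
#' @param seed Optional integer seed for the noise draws.
#' @return Numeric matrix (`n` x output dimension), entries clipped to
#'   \[0, 1\] and rounded to 3 decimals.
#' @export
setGeneric("ganSample", function(object, n, seed = NULL) standardGeneric("ganSample"))

#' Flat numeric view of a metric report
#'
#' @param x A [MetricReport-class].
#' @return Named numeric vector with fields
#'   `acc`, `recall`, `precision`, `f1`, `kappa`, `mcc`, `auc`, `fpr`.
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))
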