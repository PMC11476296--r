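#' @include seqio.R
NULL

# Physicochemical scales of the 20 standard residues used by the type-I
# pseudo amino acid composition: Tanford/Chou hydrophobicity, Hopp-Woods
# hydrophilicity and side-chain mass (glycine side chain = 1 Da). These are
# the classic scales of Chou's original PseAAC formulation, as also shipped
# by the common Python descriptor libraries.
.AA_HYDROPHOBICITY <- c(
  A = 0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19, G = 0.48, H = -0.40,
  I = 1.38, K = -1.50, L = 1.06, M = 0.64, N = -0.78, P = 0.12, Q = -0.85,
  R = -2.53, S = -0.18, T = -0.05, V = 1.08, W = 0.81, Y = 0.26)

.AA_HYDROPHILICITY <- c(
  A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5, G = 0.0, H = -0.5,
  I = -1.8, K = 3.0, L = -1.8, M = -1.3, N = 0.2, P = 0.0, Q = 0.2,
  R = 3.0, S = 0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3)

.AA_SIDECHAIN_MASS <- c(
  A = 15.0, C = 47.0, D = 59.0, E = 73.0, F = 91.0, G = 1.0, H = 82.0,
  I = 57.0, K = 73.0, L = 57.0, M = 75.0, N = 58.0, P = 42.0, Q = 72.0,
  R = 101.0, S = 31.0, T = 45.0, V = 43.0, W = 130.0, Y = 107.0)

#' Physicochemical property table for PseAAC
#'
#' Returns the 20 x 3 table of hydrophobicity, hydrophilicity and
#' side-chain mass used by the sequence-order correlation factors. Each
#' scale is standardized to zero mean and unit population standard
#' deviation (denominator 20) over the 20 residues, so the three
#' properties contribute on a common scale.
#'
#' @param normalized If `FALSE`, return the raw literature values.
#' @return Numeric matrix, rownames = residues (alphabetical one-letter
#'   order), columns `hydrophobicity`, `hydrophilicity`, `sidechainMass`.
#' @examples
#' colMeans(aaPropertyTable())       # ~0
#' apply(aaPropertyTable(), 2, sd)   # ~sqrt(20/19), population SD is 1
#' @export
aaPropertyTable <- function(normalized = TRUE) {
  raw <- cbind(hydrophobicity = .AA_HYDROPHOBICITY[AA20],
               hydrophilicity = .AA_HYDROPHILICITY[AA20],
               sidechainMass = .AA_SIDECHAIN_MASS[AA20])
  if (!normalized) return(raw)
  apply(raw, 2L, function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2)))
}

# 20 x 20 matrix of pairwise correlation functions
# Theta(a, b) = mean over the 3 normalized scales of (scale(a) - scale(b))^2.
.thetaPairMatrix <- function(table = aaPropertyTable()) {
  m <- matrix(0, 20L, 20L, dimnames = list(AA20, AA20))
  for (p in seq_len(ncol(table))) {
    d <- outer(table[, p], table[, p], "-")
    m <- m + d * d
  }
  m / ncol(table)
}

#' Sequence-order correlation factor
#'
#' The lag-k correlation factor averages, over all residue pairs k apart,
#' the squared differences of their normalized hydrophobicity,
#' hydrophilicity and side-chain mass. It is non-negative, zero for
#' homopolymers, and symmetric under sequence reversal.
#'
#' @param sequence Character string over the standard alphabet.
#' @param k Lag (1 <= k <= length - 1).
#' @param table Normalized property table from [aaPropertyTable()].
#' @return The scalar correlation factor theta_k.
#' @examples
#' thetaCorrelation("AAAAAAAAAAAA", 3)  # 0: identical residues
#' @export
thetaCorrelation <- function(sequence, k, table = aaPropertyTable()) {
  seq <- toupper(as.character(sequence))
  idx <- match(strsplit(seq, "", fixed = TRUE)[[1]], AA20)
  stopIfNot(!anyNA(idx), "sequence contains non-standard residues")
  L <- length(idx)
  stopIfNot(k >= 1 && k <= L - 1L,
            sprintf("lag k = %d needs sequence length >= %d", k, k + 1L))
  theta <- .thetaPairMatrix(table)
  mean(theta[cbind(idx[seq_len(L - k)], idx[seq_len(L - k) + k])])
}

#' Pseudo amino acid composition vector
#'
#' Computes the type-I PseAAC descriptor of a protein sequence: 20 residue
#' frequency components (alphabetical one-letter order) followed by
#' `lambda` sequence-order correlation components, jointly normalized so
#' that the 20 + lambda components are non-negative and sum to 1:
#' \deqn{x_u = f_u / D \ (u \le 20), \quad x_{20+k} = w\,\theta_k / D,
#'   \quad D = 1 + w \sum_{k=1}^{\lambda} \theta_k.}
#'
#' @param sequence Character string; must pass [validateSequence()].
#' @param lambda Number of correlation components (default 10, giving the
#'   30-dimensional descriptor).
#' @param w Weight of the correlation block relative to composition
#'   (default 0.05).
#' @param table Normalized property table.
#' @return Named numeric vector of length `20 + lambda` summing to 1.
#' @examples
#' v <- pseaacVector("MARYRRRSSRKCCRRVG")
#' length(v)  # 30
#' sum(v)     # 1
#' @export
pseaacVector <- function(sequence, lambda = 10L, w = 0.05,
                         table = aaPropertyTable()) {
  stopIfNot(lambda >= 1L, "lambda must be >= 1")
  stopIfNot(w > 0, "w must be > 0")
  val <- validateSequence(sequence, lambda)
  if (!val$pass)
    stop(sprintf("invalid sequence (%s: %s)", val$reason, val$detail),
         call. = FALSE)
  seq <- toupper(as.character(sequence))
  idx <- match(strsplit(seq, "", fixed = TRUE)[[1]], AA20)
  L <- length(idx)
  f <- tabulate(idx, nbins = 20L) / L
  theta <- .thetaPairMatrix(table)
  thetas <- vapply(seq_len(lambda), function(k) {
    mean(theta[cbind(idx[seq_len(L - k)], idx[seq_len(L - k) + k])])
  }, numeric(1))
  D <- 1 + w * sum(thetas)
  setNames(c(f / D, w * thetas / D),
           c(AA20, sprintf("lambda%d", seq_len(lambda))))
}

#' Featurize a sequence set into a PseAACSet
#'
#' Validates each record, computes its PseAAC vector, and assembles the
#' labeled dataset. Records failing validation are skipped with a logged
#' reason (kept in `metadata()$skipped`), never silently substituted.
#'
#' @param records [Biostrings::AAStringSet] (labels in `mcols()$label`),
#'   or named character vector.
#' @param lambda,w PseAAC parameters, see [pseaacVector()].
#' @param labels Optional label vector overriding `mcols()$label`.
#' @param verbose Log skipped records with `message()`.
#' @return A [PseAACSet-class] with one row per passing record, in input
#'   order; provenance `"real"`.
#' @examples
#' bench <- simulateProtamineBenchmark(nPos = 3, nNeg = 3, seed = 1)
#' featurizeDataset(bench)
#' @export
featurizeDataset <- function(records, lambda = 10L, w = 0.05,
                             labels = NULL, verbose = TRUE) {
  ids <- names(records)
  seqs <- toupper(as.character(records))
  if (is.null(ids)) ids <- sprintf("seq%d", seq_along(seqs))
  names(seqs) <- ids
  if (is.null(labels) && methods::is(records, "XStringSet") &&
      !is.null(S4Vectors::mcols(records)$label))
    labels <- S4Vectors::mcols(records)$label
  if (is.null(labels)) labels <- rep(NA_integer_, length(seqs))

  checks <- lapply(seqs, validateSequence, lambda = lambda)
  pass <- vapply(checks, `[[`, logical(1), "pass")
  skipped <- data.frame(
    id = ids[!pass],
    reason = vapply(checks[!pass], `[[`, character(1), "reason"),
    detail = vapply(checks[!pass], `[[`, character(1), "detail"))
  if (verbose && nrow(skipped))
    message(sprintf("skipped %d record(s): %s", nrow(skipped),
                    paste(sprintf("%s [%s]", skipped$id, skipped$reason),
                          collapse = "; ")))
  stopIfNot(any(pass), "no records passed validation")

  table <- aaPropertyTable()
  feats <- t(vapply(seqs[pass], pseaacVector, numeric(20L + lambda),
                    lambda = lambda, w = w, table = table))
  rownames(feats) <- ids[pass]
  out <- PseAACSet(feats, labels = labels[pass], provenance = "real",
                   lambda = lambda, weight = w, ids = ids[pass])
  S4Vectors::metadata(out)$skipped <- skipped
  out
}

#' Write / read a feature table as CSV
#'
#' Layout: `id,x1..x{20+lambda},label[,provenance]` with full-precision
#' floats; `label` is 0/1 (empty when unknown). `provenance` is written
#' for augmented datasets.
#'
#' @param x A [PseAACSet-class].
#' @param path CSV path.
#' @param withProvenance Include the provenance column (default: yes when
#'   any row is synthetic).
#' @return Invisibly, `path` (write) or a [PseAACSet-class] (read).
#' @export
writeFeatureCSV <- function(x, path,
                            withProvenance = any(provenance(x) != "real")) {
  m <- featureMatrix(x)
  df <- data.frame(id = colnames(x), m, check.names = FALSE)
  colnames(df) <- c("id", sprintf("x%d", seq_len(ncol(m))))
  df$label <- classLabels(x)
  if (withProvenance) df$provenance <- provenance(x)
  old <- options(digits = 17)
  on.exit(options(old))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  stopIfNot(all(c("id", "label") %in% colnames(df)),
            "feature CSV must contain 'id' and 'label' columns")
  featCols <- grep("^x[0-9]+$", colnames(df), value = TRUE)
  featCols <- featCols[order(as.integer(sub("x", "", featCols)))]
  m <- as.matrix(df[, featCols, drop = FALSE])
  rownames(m) <- df$id
  prov <- if ("provenance" %in% colnames(df)) df$provenance else "real"
  PseAACSet(m, labels = df$label, provenance = prov,
            lambda = length(featCols) - 20L, ids = df$id)
}
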