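# Independent reference implementations used as oracles. These are written
# in a deliberately different style (scalar loops, no shared code with the
# package internals) so that agreement is a genuine dual-route check.

AA_ORDER <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# the three classic PseAAC scales, declared independently of R/pseaac.R
.oracleScales <- list(
  hydrophobicity = c(A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29,
                     Q = -0.85, E = -0.74, G = 0.48, H = -0.40, I = 1.38,
                     L = 1.06, K = -1.50, M = 0.64, F = 1.19, P = 0.12,
                     S = -0.18, T = -0.05, W = 0.81, Y = 0.26, V = 1.08),
  hydrophilicity = c(A = -0.5, R = 3.0, N = 0.2, D = 3.0, C = -1.0,
                     Q = 0.2, E = 3.0, G = 0.0, H = -0.5, I = -1.8,
                     L = -1.8, K = 3.0, M = -1.3, F = -2.5, P = 0.0,
                     S = 0.3, T = -0.4, W = -3.4, Y = -2.3, V = -1.5),
  sidechainMass = c(A = 15.0, R = 101.0, N = 58.0, D = 59.0, C = 47.0,
                    Q = 72.0, E = 73.0, G = 1.0, H = 82.0, I = 57.0,
                    L = 57.0, K = 73.0, M = 75.0, F = 91.0, P = 42.0,
                    S = 31.0, T = 45.0, W = 130.0, Y = 107.0, V = 43.0))

# population-SD standardization, scalar-style
.oracleNorm <- function(scale) {
  mu <- sum(scale) / 20
  sdev <- sqrt(sum((scale - mu)^2) / 20)
  (scale - mu) / sdev
}

oracleTheta <- function(seq, k) {
  chars <- strsplit(seq, "")[[1]]
  norm <- lapply(.oracleScales, .oracleNorm)
  total <- 0
  for (i in 1:(length(chars) - k)) {
    a <- chars[i]; b <- chars[i + k]
    corr <- 0
    for (p in norm) corr <- corr + (p[[a]] - p[[b]])^2
    total <- total + corr / 3
  }
  total / (length(chars) - k)
}

oraclePseaac <- function(seq, lambda = 10, w = 0.05) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  f <- numeric(20)
  for (u in seq_along(AA_ORDER)) f[u] <- sum(chars == AA_ORDER[u]) / L
  thetas <- numeric(lambda)
  for (k in seq_len(lambda)) thetas[k] <- oracleTheta(seq, k)
  D <- 1 + w * sum(thetas)
  c(f / D, w * thetas / D)
}

# brute-force Mann-Whitney AUC over all positive-negative pairs
oracleAucPairwise <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# metric arithmetic straight from the printed formulas
oracleMetrics <- function(tp, fp, fn, tn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  fn <- as.numeric(fn); tn <- as.numeric(tn)
  n <- tp + fp + fn + tn
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  list(acc = (tp + tn) / n,
       recall = if (tp + fn > 0) tp / (tp + fn) else 0,
       precision = if (tp + fp > 0) tp / (tp + fp) else 0,
       f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0,
       fpr = if (fp + tn > 0) fp / (fp + tn) else 0,
       kappa = if (pe < 1) (po - pe) / (1 - pe) else 0,
       mcc = {
         den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
         if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0
       })
}

# independent SMOTE (used for the distributional comparison): plain loops,
# own neighbour search
oracleSmote <- function(minority, nNew, k) {
  nMin <- nrow(minority)
  out <- matrix(NA_real_, nNew, ncol(minority))
  for (s in seq_len(nNew)) {
    i <- sample.int(nMin, 1)
    dists <- numeric(nMin)
    for (j in seq_len(nMin)) dists[j] <- sqrt(sum((minority[i, ] - minority[j, ])^2))
    dists[i] <- Inf
    nn <- order(dists)[sample.int(k, 1)]
    u <- runif(1)
    out[s, ] <- minority[i, ] + u * (minority[nn, ] - minority[i, ])
  }
  out
}

# check that `row` lies on a segment between some minority row and one of
# its k nearest minority neighbours (exhaustive, exact up to `tol`)
onSmoteSegment <- function(row, minority, k, tol = 1e-8) {
  nMin <- nrow(minority)
  d <- as.matrix(dist(minority)); diag(d) <- Inf
  for (i in seq_len(nMin)) {
    for (j in order(d[i, ])[seq_len(k)]) {
      dir <- minority[j, ] - minority[i, ]
      rel <- row - minority[i, ]
      nz <- which(abs(dir) > tol)
      if (length(nz) == 0) {
        if (all(abs(rel) < tol)) return(TRUE)
        next
      }
      u <- rel[nz[1]] / dir[nz[1]]
      if (u >= -tol && u <= 1 + tol && all(abs(rel - u * dir) < tol))
        return(TRUE)
    }
  }
  FALSE
}

# random valid sequences over the standard alphabet
randomSequences <- function(n, minLen = 15, maxLen = 80) {
  lens <- minLen:maxLen
  vapply(seq_len(n), function(i) {
    paste(sample(AA_ORDER, lens[sample.int(length(lens), 1)],
                 replace = TRUE), collapse = "")
  }, character(1))
}
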