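#' @include pseaac.R
NULL

# Core SMOTE interpolation on a plain matrix of minority rows: each new row
# is x + u * (x_nn - x) for a random minority row x, one of its k Euclidean
# nearest minority neighbours x_nn, and u ~ Uniform(0, 1).
.smoteRows <- function(minority, nNew, kNeighbors) {
  nMin <- nrow(minority)
  stopIfNot(kNeighbors >= 1L && kNeighbors < nMin,
            sprintf("kNeighbors must be in [1, %d)", nMin))
  d <- as.matrix(dist(minority))
  diag(d) <- Inf
  nn <- t(apply(d, 1L, function(row) order(row)[seq_len(kNeighbors)]))
  base <- sample.int(nMin, nNew, replace = TRUE)
  pick <- nn[cbind(base, sample.int(kNeighbors, nNew, replace = TRUE))]
  u <- runif(nNew)
  minority[base, , drop = FALSE] +
    u * (minority[pick, , drop = FALSE] - minority[base, , drop = FALSE])
}

#' Balance a dataset by SMOTE oversampling
#'
#' Grows the minority class to the majority size by synthetic minority
#' over-sampling: new points are drawn uniformly on segments between a
#' minority point and one of its `kNeighbors` nearest minority neighbours
#' (Euclidean distance in feature space). Original rows are kept
#' unmodified; synthetic rows carry provenance `"smote"`. Already balanced
#' input is returned unchanged. Deterministic under `seed`.
#'
#' @param dataset A labeled [PseAACSet-class] with two classes.
#' @param kNeighbors Number of minority nearest neighbours (default 5);
#'   must be smaller than the minority count.
#' @param seed Optional integer seed.
#' @return A [PseAACSet-class] with equal class counts.
#' @examples
#' d <- featurizeDataset(simulateProtamineBenchmark(nPos = 10, nNeg = 20, seed = 1))
#' table(classLabels(smoteOversample(d, seed = 1)))
#' @export
smoteOversample <- function(dataset, kNeighbors = 5L, seed = NULL) {
  lab <- classLabels(dataset)
  stopIfNot(!anyNA(lab), "all rows must be labeled")
  tab <- table(factor(lab, levels = c(0L, 1L)))
  stopIfNot(all(tab > 0L), "both classes must be present")
  if (tab[1] == tab[2]) return(dataset)
  minLab <- as.integer(names(tab)[which.min(tab)])
  nNew <- as.integer(abs(diff(tab)))

  m <- featureMatrix(dataset)
  minority <- m[lab == minLab, , drop = FALSE]
  synth <- withSeed(seed, .smoteRows(minority, nNew, kNeighbors))
  rownames(synth) <- sprintf("smote%d", seq_len(nNew))

  out <- PseAACSet(rbind(m, synth),
                   labels = c(lab, rep(minLab, nNew)),
                   provenance = c(provenance(dataset), rep("smote", nNew)),
                   lambda = S4Vectors::metadata(dataset)$lambda,
                   weight = S4Vectors::metadata(dataset)$weight,
                   ids = c(colnames(dataset), rownames(synth)))
  S4Vectors::metadata(out)$skipped <- S4Vectors::metadata(dataset)$skipped
  out
}

#' Tabular GAN configuration
#'
#' Architecture and optimization settings of the generator/discriminator
#' pair used to synthesize minority-class feature rows: generator
#' noise -> 128 -> 128 -> `outDim` dense layers and discriminator
#' `outDim` -> 128 -> 128 -> 1 (sigmoid), LeakyReLU (alpha = 0.01) and
#' dropout 0.5 between hidden layers, both trained with Adam
#' (lr = 2e-4, beta1 = 0.5) under binary cross-entropy for 1000 epochs
#' with minibatches of 30.
#'
#' @param outDim Feature dimension the generator emits (30 for the default
#'   PseAAC descriptor).
#' @param noiseDim Dimension of the Gaussian noise input (default 100).
#' @param epochs,batchSize Training schedule.
#' @param lr,beta1 Adam learning rate and first-moment decay.
#' @param leakyAlpha LeakyReLU negative slope.
#' @param dropout Dropout rate between hidden layers (training time only).
#' @param seed Integer seed for initialization and training noise.
#' @return A validated configuration list.
#' @export
ganConfig <- function(outDim = 30L, noiseDim = 100L, epochs = 1000L,
                      batchSize = 30L, lr = 2e-4, beta1 = 0.5,
                      leakyAlpha = 0.01, dropout = 0.5, seed = NULL) {
  stopIfNot(outDim >= 1L && noiseDim >= 1L, "dimensions must be >= 1")
  stopIfNot(epochs >= 1L && batchSize >= 1L, "epochs and batchSize must be >= 1")
  rates <- c(lr = lr, beta1 = beta1, leakyAlpha = leakyAlpha, dropout = dropout)
  stopIfNot(all(rates > 0 & rates < 1), "all rates must lie in (0, 1)")
  list(outDim = as.integer(outDim), noiseDim = as.integer(noiseDim),
       epochs = as.integer(epochs), batchSize = as.integer(batchSize),
       lr = lr, beta1 = beta1, beta2 = 0.999, eps = 1e-8,
       leakyAlpha = leakyAlpha, dropout = dropout, seed = seed,
       generatorWidths = c(128L, 128L, as.integer(outDim)),
       discriminatorWidths = c(128L, 128L, 1L))
}

# --- minimal dense-network machinery (Glorot init, LeakyReLU, inverted
# --- dropout, Adam) ---

.denseInit <- function(widths, nIn) {
  layers <- vector("list", length(widths))
  for (i in seq_along(widths)) {
    fanIn <- if (i == 1L) nIn else widths[i - 1L]
    lim <- sqrt(6 / (fanIn + widths[i]))
    layers[[i]] <- list(W = matrix(runif(fanIn * widths[i], -lim, lim),
                                   fanIn, widths[i]),
                        b = rep(0, widths[i]))
  }
  layers
}

.leaky <- function(x, alpha) ifelse(x > 0, x, alpha * x)
.leakyGrad <- function(x, alpha) ifelse(x > 0, 1, alpha)
.sigmoid <- function(x) 1 / (1 + exp(-x))

# forward pass; hidden layers get LeakyReLU (+ dropout when training),
# output layer is linear (outputActivation handled by the caller).
.denseForward <- function(layers, x, alpha, dropout, train) {
  nL <- length(layers)
  cache <- list(a = vector("list", nL), z = vector("list", nL),
                mask = vector("list", nL), input = x)
  a <- x
  for (i in seq_len(nL)) {
    z <- sweep(a %*% layers[[i]]$W, 2L, layers[[i]]$b, "+")
    cache$z[[i]] <- z
    if (i < nL) {
      a <- .leaky(z, alpha)
      if (train && dropout > 0) {
        mask <- matrix(rbinom(length(a), 1L, 1 - dropout), nrow(a), ncol(a)) /
          (1 - dropout)
        cache$mask[[i]] <- mask
        a <- a * mask
      }
    } else a <- z
    cache$a[[i]] <- a
  }
  cache
}

# backprop given dL/d(output z of last layer); returns gradients and
# dL/d(input) for chaining through the frozen discriminator.
.denseBackward <- function(layers, cache, dOut, alpha) {
  nL <- length(layers)
  grads <- vector("list", nL)
  delta <- dOut
  for (i in rev(seq_len(nL))) {
    aPrev <- if (i == 1L) cache$input else cache$a[[i - 1L]]
    grads[[i]] <- list(W = crossprod(aPrev, delta), b = colSums(delta))
    if (i > 1L) {
      delta <- delta %*% t(layers[[i]]$W)
      if (!is.null(cache$mask[[i - 1L]])) delta <- delta * cache$mask[[i - 1L]]
      delta <- delta * .leakyGrad(cache$z[[i - 1L]], alpha)
    }
  }
  # delta now sits at the first layer's pre-activation; push it through W1
  # to obtain the gradient w.r.t. the network input (used to chain the
  # generator through the frozen discriminator)
  list(grads = grads, dInput = delta %*% t(layers[[1L]]$W))
}

.adamInit <- function(layers) {
  lapply(layers, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                  mb = l$b * 0, vb = l$b * 0))
}

.adamStep <- function(layers, grads, state, t, cfg) {
  for (i in seq_along(layers)) {
    for (p in c("W", "b")) {
      g <- grads[[i]][[p]]
      m <- cfg$beta1 * state[[i]][[paste0("m", p)]] + (1 - cfg$beta1) * g
      v <- cfg$beta2 * state[[i]][[paste0("v", p)]] + (1 - cfg$beta2) * g^2
      state[[i]][[paste0("m", p)]] <- m
      state[[i]][[paste0("v", p)]] <- v
      mh <- m / (1 - cfg$beta1^t)
      vh <- v / (1 - cfg$beta2^t)
      layers[[i]][[p]] <- layers[[i]][[p]] - cfg$lr * mh / (sqrt(vh) + cfg$eps)
    }
  }
  list(layers = layers, state = state)
}

.bce <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train the tabular GAN on minority-class features
#'
#' Adversarial training of the generator/discriminator pair described in
#' [ganConfig()]. Each epoch is one pass of shuffled minibatches over the
#' real rows; per minibatch the discriminator is updated once on real
#' (target 1) vs generated (target 0) rows under binary cross-entropy,
#' then the generator is updated once through the frozen discriminator
#' with target 1. The generator output layer is linear; samples are
#' clipped to \[0, 1\] at sampling time (the feature space of PseAAC).
#'
#' @param features Numeric matrix of real minority rows (n x `outDim`).
#' @param config A [ganConfig()] list; `outDim` must match `ncol(features)`.
#' @return A [TrainedGenerator-class] with per-epoch loss traces.
#' @examples
#' m <- matrix(runif(50 * 5), 50, 5)
#' g <- ganTrain(m, ganConfig(outDim = 5, epochs = 3, seed = 1))
#' @export
ganTrain <- function(features, config = ganConfig()) {
  features <- as.matrix(features)
  stopIfNot(nrow(features) >= 1L, "minority feature matrix is empty")
  stopIfNot(ncol(features) == config$outDim,
            sprintf("config outDim (%d) != feature width (%d)",
                    config$outDim, ncol(features)))
  withSeed(config$seed, {
    G <- .denseInit(config$generatorWidths, config$noiseDim)
    D <- .denseInit(config$discriminatorWidths, config$outDim)
    adamG <- .adamInit(G); adamD <- .adamInit(D)
    tG <- 0L; tD <- 0L
    n <- nrow(features)
    losses <- matrix(NA_real_, config$epochs, 2L,
                     dimnames = list(NULL, c("discriminator", "generator")))
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batchSize)
      dLoss <- gLoss <- numeric(length(starts))
      for (s in seq_along(starts)) {
        idx <- ord[starts[s]:min(starts[s] + config$batchSize - 1L, n)]
        m <- length(idx)
        real <- features[idx, , drop = FALSE]

        # discriminator step: real (1) + fake (0)
        z <- matrix(rnorm(m * config$noiseDim), m)
        fake <- .denseForward(G, z, config$leakyAlpha, config$dropout,
                              train = FALSE)$a[[length(G)]]
        xD <- rbind(real, fake)
        yD <- rep(c(1, 0), each = m)
        cD <- .denseForward(D, xD, config$leakyAlpha, config$dropout,
                            train = TRUE)
        pD <- .sigmoid(cD$a[[length(D)]])
        dLoss[s] <- .bce(pD, yD)
        dOut <- (pD - yD) / length(yD)   # BCE + sigmoid gradient
        bD <- .denseBackward(D, cD, dOut, config$leakyAlpha)
        tD <- tD + 1L
        up <- .adamStep(D, bD$grads, adamD, tD, config)
        D <- up$layers; adamD <- up$state

        # generator step through the frozen discriminator (inference mode)
        z <- matrix(rnorm(m * config$noiseDim), m)
        cG <- .denseForward(G, z, config$leakyAlpha, config$dropout,
                            train = TRUE)
        xFake <- cG$a[[length(G)]]
        cDg <- .denseForward(D, xFake, config$leakyAlpha, config$dropout,
                             train = FALSE)
        pG <- .sigmoid(cDg$a[[length(D)]])
        gLoss[s] <- .bce(pG, rep(1, m))
        dOutD <- (pG - 1) / m
        bDg <- .denseBackward(D, cDg, dOutD, config$leakyAlpha)
        bG <- .denseBackward(G, cG, bDg$dInput, config$leakyAlpha)
        tG <- tG + 1L
        up <- .adamStep(G, bG$grads, adamG, tG, config)
        G <- up$layers; adamG <- up$state
      }
      losses[epoch, ] <- c(mean(dLoss), mean(gLoss))
      if (!all(is.finite(losses[epoch, ])))
        stop(sprintf("non-finite GAN loss at epoch %d (D=%.4g, G=%.4g)",
                     epoch, losses[epoch, 1], losses[epoch, 2]), call. = FALSE)
    }
    methods::new("TrainedGenerator", layers = G, config = config,
                 losses = losses)
  })
}

#' @rdname ganSample
#' @export
setMethod("ganSample", "TrainedGenerator", function(object, n, seed = NULL) {
  stopIfNot(n >= 1L, "n must be >= 1")
  cfg <- object@config
  withSeed(seed, {
    z <- matrix(rnorm(n * cfg$noiseDim), n)
    out <- .denseForward(object@layers, z, cfg$leakyAlpha, cfg$dropout,
                         train = FALSE)$a[[length(object@layers)]]
    out <- round(pmin(pmax(out, 0), 1), 3L)  # feature-space clip, 3-decimal precision
    colnames(out) <- sprintf("x%d", seq_len(cfg$outDim))
    out
  })
})

#' Balance a dataset with GAN-synthesized minority rows
#'
#' Trains the tabular GAN on the minority-class feature rows only, samples
#' (majority - minority) synthetic rows from the fitted generator and
#' merges them with provenance `"gan"`. With `augmentBoth = TRUE` a second
#' generator is trained on the majority class and the same number of
#' synthetic majority rows is added too — useful for distributional QC of
#' both classes, not for the modeling protocol.
#'
#' @param dataset A labeled two-class [PseAACSet-class].
#' @param config A [ganConfig()]; its `outDim` must match the dataset.
#' @param augmentBoth Also synthesize rows for the majority class.
#' @return A [PseAACSet-class]; the original rows are untouched. The
#'   fitted generator(s) are kept in `metadata()$generators`.
#' @export
balanceWithGAN <- function(dataset, config = ganConfig(), augmentBoth = FALSE) {
  lab <- classLabels(dataset)
  stopIfNot(!anyNA(lab), "all rows must be labeled")
  tab <- table(factor(lab, levels = c(0L, 1L)))
  stopIfNot(all(tab > 0L), "both classes must be present")
  if (tab[1] == tab[2] && !augmentBoth) return(dataset)
  minLab <- as.integer(names(tab)[which.min(tab)])
  nNew <- as.integer(abs(diff(tab)))

  m <- featureMatrix(dataset)
  gens <- list()
  addRows <- NULL; addLab <- integer(0)
  if (nNew > 0L) {
    gen <- ganTrain(m[lab == minLab, , drop = FALSE], config)
    gens[[as.character(minLab)]] <- gen
    synth <- ganSample(gen, nNew, seed = deriveSeed(config$seed, 1L))
    rownames(synth) <- sprintf("gan%d", seq_len(nNew))
    addRows <- synth; addLab <- rep(minLab, nNew)
  }
  if (augmentBoth && nNew > 0L) {
    majLab <- 1L - minLab
    cfg2 <- config; cfg2$seed <- deriveSeed(config$seed, 2L)
    gen2 <- ganTrain(m[lab == majLab, , drop = FALSE], cfg2)
    gens[[as.character(majLab)]] <- gen2
    synth2 <- ganSample(gen2, nNew, seed = deriveSeed(config$seed, 3L))
    rownames(synth2) <- sprintf("ganmaj%d", seq_len(nNew))
    addRows <- rbind(addRows, synth2)
    addLab <- c(addLab, rep(majLab, nNew))
  }

  out <- PseAACSet(rbind(m, addRows),
                   labels = c(lab, addLab),
                   provenance = c(provenance(dataset),
                                  rep("gan", length(addLab))),
                   lambda = S4Vectors::metadata(dataset)$lambda,
                   weight = S4Vectors::metadata(dataset)$weight,
                   ids = c(colnames(dataset), rownames(addRows)))
  S4Vectors::metadata(out)$generators <- gens
  out
}

#' PCA comparison of real and synthetic feature rows
#'
#' Fits principal components on the pooled matrix (centered, unscaled) and
#' returns the 2-D projection of every row tagged by source, plus the
#' explained-variance fractions — the standard visual check that an
#' oversampler's output occupies the same region of feature space as the
#' real data.
#'
#' @param realFeatures,syntheticFeatures Matrices of equal width.
#' @return List with `coordinates` (data.frame `pc1,pc2,source`) and
#'   `explainedVariance` (all components, non-increasing).
#' @export
pcaCompare <- function(realFeatures, syntheticFeatures) {
  realFeatures <- as.matrix(realFeatures)
  syntheticFeatures <- as.matrix(syntheticFeatures)
  stopIfNot(ncol(realFeatures) == ncol(syntheticFeatures),
            "feature widths differ")
  pooled <- rbind(realFeatures, syntheticFeatures)
  stopIfNot(nrow(pooled) >= 2L, "need at least 2 rows")
  fit <- prcomp(pooled, center = TRUE, scale. = FALSE)
  coords <- data.frame(
    pc1 = fit$x[, 1L], pc2 = if (ncol(fit$x) >= 2L) fit$x[, 2L] else 0,
    source = rep(c("real", "synthetic"),
                 c(nrow(realFeatures), nrow(syntheticFeatures))))
  list(coordinates = coords,
       explainedVariance = fit$sdev^2 / sum(fit$sdev^2))
}
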