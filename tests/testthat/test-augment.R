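makeDataset <- function(nMin, nMaj, p = 30, seed = 1) {
  set.seed(seed)
  m <- matrix(runif((nMin + nMaj) * p), nMin + nMaj, p)
  m <- m / rowSums(m)
  PseAACSet(m, labels = rep(c(1L, 0L), c(nMin, nMaj)), lambda = p - 20L)
}

test_that("SMOTE balances to the majority count and keeps originals untouched", {
  ds <- makeDataset(221, 431)
  out <- smoteOversample(ds, kNeighbors = 5, seed = 1)
  expect_equal(as.integer(table(classLabels(out))), c(431L, 431L))
  expect_equal(featureMatrix(out)[1:652, ], featureMatrix(ds))
  expect_equal(provenance(out), rep(c("real", "smote"), c(652, 210)))

  # balanced input is returned unchanged
  bal <- makeDataset(50, 50)
  expect_identical(smoteOversample(bal, seed = 1), bal)

  # determinism and error contracts
  out2 <- smoteOversample(ds, kNeighbors = 5, seed = 1)
  expect_equal(featureMatrix(out2), featureMatrix(out))
  out3 <- smoteOversample(ds, kNeighbors = 5, seed = 2)
  expect_false(identical(featureMatrix(out3), featureMatrix(out)))
  tiny <- makeDataset(4, 20)
  expect_error(smoteOversample(tiny, kNeighbors = 5), "kNeighbors")
  oneClass <- PseAACSet(matrix(runif(60), 2), labels = 1L)
  expect_error(smoteOversample(oneClass), "both classes")
})

test_that("every SMOTE row lies on a minority nearest-neighbour segment and inside the minority envelope", {
  set.seed(31)
  for (case in list(c(12, 20, 4), c(30, 50, 5), c(25, 40, 3))) {
    ds <- makeDataset(case[1], case[2], p = 20 + case[3] %% 10 + 1,
                      seed = case[1])
    k <- 5
    out <- smoteOversample(ds, kNeighbors = k, seed = case[2])
    m <- featureMatrix(out)
    minority <- featureMatrix(ds)[classLabels(ds) == 1L, ]
    synth <- m[provenance(out) == "smote", , drop = FALSE]
    for (r in seq_len(nrow(synth)))
      expect_true(onSmoteSegment(synth[r, ], minority, k))
    # interpolation never extrapolates past the minority envelope
    expect_true(all(apply(synth, 2, max) <= apply(minority, 2, max) + 1e-12))
    expect_true(all(apply(synth, 2, min) >= apply(minority, 2, min) - 1e-12))
  }
})

test_that("native SMOTE matches an independent implementation in distribution", {
  minority <- withr::with_seed(32, matrix(rnorm(80 * 3), 80, 3) %*%
                                     diag(c(1, 2, 0.5)))
  # compare per-feature distributions of 1000 synthetic rows from the two
  # implementations (same algorithm, independent code paths)
  a <- withr::with_seed(33, ProtamineScan:::.smoteRows(minority, 1000, 5))
  b <- withr::with_seed(34, oracleSmote(minority, 1000, 5))
  for (j in 1:3) {
    ks <- suppressWarnings(ks.test(a[, j], b[, j]))
    expect_gt(ks$p.value, 0.001)
  }
})

test_that("GAN training keeps a finite per-epoch loss trace and samples obey the output contract", {
  ds <- makeDataset(40, 60, seed = 41)
  minority <- featureMatrix(ds)[classLabels(ds) == 1L, ]
  gen <- ganTrain(minority, ganConfig(epochs = 25, seed = 1))
  expect_s4_class(gen, "TrainedGenerator")
  expect_equal(nrow(gen@losses), 25L)
  expect_true(all(is.finite(gen@losses)))

  s <- ganSample(gen, 210, seed = 2)
  expect_equal(dim(s), c(210L, 30L))
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(s, round(s, 3))  # 3-decimal precision
  expect_identical(ganSample(gen, 210, seed = 2), s)
  expect_false(identical(ganSample(gen, 210, seed = 3), s))
  expect_error(ganSample(gen, 0), "n must be")
  expect_error(ganTrain(minority, ganConfig(outDim = 7)), "outDim")
})

test_that("the generator recovers a point-mass target, improving with training", {
  pt <- withr::with_seed(99, runif(5))
  pm <- matrix(rep(pt, each = 60), nrow = 60)
  early <- ganTrain(pm, ganConfig(outDim = 5, epochs = 60, seed = 7))
  late <- ganTrain(pm, ganConfig(outDim = 5, epochs = 300, seed = 7))
  errEarly <- mean(abs(colMeans(ganSample(early, 300, seed = 8)) - pt))
  errLate <- mean(abs(colMeans(ganSample(late, 300, seed = 8)) - pt))
  expect_lt(errLate, errEarly)
  expect_lt(errLate, 0.06)  # ~3x the calibrated run at these settings
})

test_that("GAN balancing augments only the minority class unless asked otherwise", {
  ds <- makeDataset(30, 50, seed = 51)
  cfg <- ganConfig(epochs = 15, seed = 1)
  out <- balanceWithGAN(ds, cfg)
  expect_equal(as.integer(table(classLabels(out))), c(50L, 50L))
  tab <- table(classLabels(out), provenance(out))
  expect_equal(tab["1", "gan"], 20)
  expect_equal(sum(tab["0", ]) - tab["0", "real"], 0)
  expect_equal(featureMatrix(out)[1:80, ], featureMatrix(ds))

  bal <- makeDataset(20, 20, seed = 52)
  expect_identical(balanceWithGAN(bal, cfg), bal)

  both <- balanceWithGAN(ds, cfg, augmentBoth = TRUE)
  tab2 <- table(classLabels(both), provenance(both))
  expect_equal(unname(tab2[, "gan"]), c(20L, 20L))
})

test_that("PCA comparison projects pooled rows with valid explained variance", {
  set.seed(61)
  real <- matrix(rnorm(40 * 6), 40, 6)
  res <- pcaCompare(real, real)
  co <- res$coordinates
  expect_equal(co$pc1[1:40], co$pc1[41:80])  # identical clouds coincide
  expect_true(all(res$explainedVariance >= 0 & res$explainedVariance <= 1))
  expect_true(all(diff(res$explainedVariance) <= 1e-12))
  expect_equal(sum(res$explainedVariance), 1)

  # coordinates invariant (up to per-PC sign) under row permutation
  synth <- matrix(rnorm(30 * 6), 30, 6)
  res1 <- pcaCompare(real, synth)
  perm <- withr::with_seed(62, sample(40))
  res2 <- pcaCompare(real[perm, ], synth)
  for (pc in c("pc1", "pc2")) {
    x1 <- res1$coordinates[[pc]][1:40][perm]
    x2 <- res2$coordinates[[pc]][1:40]
    expect_true(isTRUE(all.equal(x1, x2, tolerance = 1e-8)) ||
                isTRUE(all.equal(x1, -x2, tolerance = 1e-8)))
  }
  expect_error(pcaCompare(real, synth[, 1:3]), "widths")
})
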