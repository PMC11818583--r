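test_that("dummy response has the design rank and centred columns", {
  fac <- makeFactors(1)               # one row per design cell
  Y <- buildDummyResponse(fac)
  expect_equal(ncol(Y), 14L)          # 4 + 2 + 8 indicators
  expect_equal(qr(Y)$rank, 7L)
  expect_true(all(abs(colSums(Y)) < 1e-12))
  Y6 <- buildDummyResponse(makeFactors(6))
  expect_true(all(abs(colSums(Y6)) < 1e-12))
  # degenerate: a single cell centres to zero
  one <- data.frame(origin = rep("DLD1", 4), resistance = rep("naive", 4))
  expect_error(buildDummyResponse(one), "degenerate")
})

test_that("block kernels are unit-Frobenius and match an explicit Gram oracle", {
  d <- list(X = matrix(rnorm(40), 8, 5), fac = makeFactors(1))
  dec <- decomposeEffects(d$X, d$fac)
  bk <- suppressWarnings(blockKernels(dec))
  for (nm in names(bk$kernels)[1:3])
    expect_equal(sqrt(sum(bk$kernels[[nm]]^2)), 1, tolerance = 1e-12)
  for (nm in c("origin", "resistance", "interaction")) {
    Ko <- oracleGram(effectMatrices(dec)[[nm]])
    expect_equal(unname(bk$kernels[[nm]]) * sqrt(sum(Ko^2)), Ko,
                 tolerance = 1e-10)
  }
  # saturated design: residual block is zero, flagged with a warning
  expect_warning(blockKernels(dec), "residual")
  expect_true(all(bk$kernels$residual == 0))
})

noiseFreeOriginFit <- function() {
  fac <- makeFactors(3)
  set.seed(6)
  levelMeans <- matrix(rnorm(20), 4, 5,
                       dimnames = list(c("DLD1", "HCT116", "LS174T", "SW620"),
                                       NULL))
  X <- levelMeans[fac$origin, ]
  Y <- buildDummyResponse(fac, effects = "origin")
  blocks <- list(origin = X - matrix(colMeans(X), nrow(X), ncol(X),
                                     byrow = TRUE))
  suppressWarnings(fitAmopls(blocks, Y = Y, nPred = 3, nOrth = 0))
}

test_that("noise-free single-factor data gives R2Y = 1 and lambda = 1 for its block", {
  m <- noiseFreeOriginFit()
  expect_equal(m@r2y, 1, tolerance = 1e-6)
  expect_true(all(abs(blockContributions(m)[, "origin"] - 1) < 1e-9))
})

test_that("predictive subspace matches the direct eigendecomposition oracle", {
  for (seed in c(2, 9)) {
    p <- prepSim(simConfig(nFeatures = 10 + seed, replicatesPerCell = 2,
                           seed = seed, dilutionSd = 0, missingRate = 0))
    dec <- decomposeEffects(p$X, p$factors)
    m <- fitAmopls(dec, nOrth = 0)
    o <- oraclePredictive(dec, buildDummyResponse(p$factors), 7)
    expect_lt(maxPrincipalAngle(predictiveScores(m), o$vectors), 1e-6)
    expect_equal(unname(colSums(predictiveScores(m)^2)), o$values,
                 tolerance = 1e-8)
  }
})

test_that("single-block fit reduces to kernel PLS on that block", {
  set.seed(4)
  fac <- makeFactors(2)
  X <- matrix(rnorm(16 * 6), 16, 6)
  Xc <- sweep(X, 2, colMeans(X))
  Y <- buildDummyResponse(fac, effects = "origin")
  m <- fitAmopls(list(origin = Xc), Y = Y, nPred = 3, nOrth = 0)
  o <- oraclePredictive(list(origin = Xc), Y, 3)
  expect_lt(maxPrincipalAngle(predictiveScores(m), o$vectors), 1e-6)
})

test_that("model invariants: score orthogonality, lambda rows, variance budget", {
  p <- prepSim(simConfig(nFeatures = 60, replicatesPerCell = 6, seed = 3,
                         dilutionSd = 0, missingRate = 0))
  dec <- decomposeEffects(p$X, p$factors)
  m <- fitAmopls(dec, nOrth = 2)
  Tp <- predictiveScores(m); To <- orthogonalScores(m)
  cc <- cor(cbind(Tp, To))
  expect_true(all(abs(cc[upper.tri(cc)]) < 1e-8))
  # orthogonal scores are uncorrelated with every response column
  Y <- buildDummyResponse(p$factors)
  expect_true(all(abs(crossprod(To, Y)) < 1e-8))
  lam <- blockContributions(m)
  expect_true(all(lam >= 0 & lam <= 1))
  expect_equal(unname(rowSums(lam)), rep(1, nrow(lam)), tolerance = 1e-9)
  cv <- componentVariance(m)
  expect_true(all(cv >= 0))
  expect_lte(sum(cv), 1 + 1e-9)
})

test_that("fit is equivariant under feature reordering and signs follow the convention", {
  p <- prepSim(simConfig(nFeatures = 30, replicatesPerCell = 2, seed = 8,
                         dilutionSd = 0, missingRate = 0))
  dec1 <- decomposeEffects(p$X, p$factors)
  m1 <- fitAmopls(dec1, nOrth = 1)
  perm <- sample(ncol(p$X))
  dec2 <- decomposeEffects(p$X[, perm], p$factors)
  m2 <- fitAmopls(dec2, nOrth = 1)
  expect_equal(m2@loadingsPred, m1@loadingsPred[perm, ], tolerance = 1e-8)
  expect_equal(predictiveScores(m2), predictiveScores(m1), tolerance = 1e-8)
  for (c in seq_len(ncol(m1@loadingsPred)))
    expect_gt(m1@loadingsPred[which.max(abs(m1@loadingsPred[, c])), c], 0)
})

test_that("score-loading reconstruction improves with component count", {
  p <- prepSim(simConfig(nFeatures = 40, replicatesPerCell = 3, seed = 12,
                         dilutionSd = 0, missingRate = 0))
  dec <- decomposeEffects(p$X, p$factors)
  m <- fitAmopls(dec, nOrth = 1)
  L <- backProjectLoadings(m, p$X)
  Tall <- cbind(predictiveScores(m), orthogonalScores(m))
  errs <- vapply(seq_len(ncol(Tall)), function(k) {
    hat <- Tall[, 1:k, drop = FALSE] %*% t(L[, 1:k, drop = FALSE])
    sum((p$X - hat)^2)
  }, 0)
  expect_true(all(diff(errs) < 0))
  expect_equal(L[, seq_len(m@nPred)], m@loadingsPred)
})

test_that("loadings localise a planted origin effect on the carrying features", {
  p <- prepSim(simConfig(nFeatures = 80, replicatesPerCell = 3, seed = 15,
                         dilutionSd = 0, missingRate = 0,
                         effectFractions = c(origin = 0.7, resistance = 0,
                                             interaction = 0, residual = 0.3),
                         nullFeatureFrac = 0.5))
  dec <- decomposeEffects(p$X, p$factors)
  m <- fitAmopls(dec, nOrth = 0)
  origComps <- which(effectAttribution(m) == "origin")
  expect_gte(length(origComps), 1L)
  score <- rowSums(abs(m@loadingsPred[, origComps, drop = FALSE]))
  carriers <- rownames(m@loadingsPred) %in% p$truth$effectFeatures
  top <- names(sort(score, decreasing = TRUE))[seq_len(sum(carriers))]
  expect_gt(mean(top %in% p$truth$effectFeatures), 0.9)
})

test_that("invalid component counts are rejected", {
  p <- prepSim(simConfig(nFeatures = 20, replicatesPerCell = 2, seed = 1,
                         dilutionSd = 0, missingRate = 0))
  dec <- decomposeEffects(p$X, p$factors)
  expect_error(fitAmopls(dec, nPred = 8), "rank")
  expect_error(fitAmopls(dec, nPred = 0), "rank|between")
})
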