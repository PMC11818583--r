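test_that("each filter rule removes its engineered features; 12 of 20 remain", {
  x <- makeFilterFixture()
  fl <- filterFeatures(x)
  r <- fl$report
  feats <- rownames(x)
  expect_identical(r@removed$missingness, feats[1:2])
  expect_identical(r@removed$qc_intensity, feats[3:4])
  expect_identical(r@removed$qc_cv, feats[5:6])
  expect_identical(r@removed$iqr, feats[7:8])
  expect_identical(r@nRetained, 12L)
  expect_identical(rownames(fl$table), feats[9:20])
  expect_identical(unname(r@firstFailing[feats[1]]), "missingness")
  # constant feature with perfect QCs is caught by the IQR rule
  expect_identical(unname(r@firstFailing[feats[7]]), "iqr")
})

test_that("a feature detected in 2 of 10 samples above 5x blank is dropped", {
  x <- makeFilterFixture()
  m <- intensityMatrix(x)
  # feature 9: present everywhere but above 5 x blank (= 50) in only 2 samples
  m[1:8, 9] <- 40
  SummarizedExperiment::assay(x, "intensity") <- t(m)
  r <- filterFeatures(x)$report
  expect_true(rownames(x)[9] %in% r@removed$missingness)
})

test_that("filtering is monotone in its thresholds", {
  x <- makeFilterFixture()
  base <- filterFeatures(x)$report@nRetained
  expect_gte(filterFeatures(x, missingFrac = 0.9)$report@nRetained, base)
  expect_gte(filterFeatures(x, blankMult = 2)$report@nRetained, base)
  expect_gte(filterFeatures(x, qcMinMean = 1e4)$report@nRetained, base)
  expect_gte(filterFeatures(x, qcMaxCv = 0.8)$report@nRetained, base)
  tight <- filterFeatures(x, missingFrac = 0.5, qcMaxCv = 0.2)$report@nRetained
  expect_lte(tight, base)
})

test_that("filter preconditions: QC rows required, blank rule can be disabled", {
  x <- makeToySet()
  noQc <- x[, sampleRoles(x) != "qc"]
  expect_error(filterFeatures(noQc), "QC")
  noBlank <- x[, sampleRoles(x) != "blank"]
  expect_error(filterFeatures(noBlank), "blank")
  expect_s4_class(filterFeatures(noBlank, requireBlank = FALSE)$report,
                  "FilterReport")
})

test_that("PQN: identity, scale equivariance, and the corrected-row identity", {
  x <- makeToySet(nBio = 4, nQc = 3, nBlank = 1, nFeat = 12, seed = 3)
  m <- intensityMatrix(x)
  ref <- apply(m[sampleRoles(x) == "qc", ], 2, median)
  m[1, ] <- ref          # identical to reference
  m[2, ] <- 2 * ref      # doubled
  SummarizedExperiment::assay(x, "intensity") <- t(m)
  res <- pqnNormalize(x)
  expect_equal(unname(res$referenceSpectrum), unname(ref))
  expect_equal(unname(res$dilutionFactors[1]), 1)
  expect_equal(unname(res$dilutionFactors[2]), 2)
  corrected <- intensityMatrix(res$table)
  expect_equal(unname(corrected[2, ]), unname(ref))
  # corrected[i, j] * factor[i] = input[i, j] for every present cell
  expect_equal(corrected * res$dilutionFactors, m)
})

test_that("PQN is idempotent and commutes with a global rescaling", {
  x <- makeToySet(nBio = 6, nQc = 3, nBlank = 1, nFeat = 15, seed = 8)
  r1 <- pqnNormalize(x)
  r2 <- pqnNormalize(r1$table)
  expect_true(all(abs(log(r2$dilutionFactors)) < 1e-8))

  y <- x
  SummarizedExperiment::assay(y, "intensity") <-
    SummarizedExperiment::assay(x, "intensity") * 7
  ry <- pqnNormalize(y)
  b1 <- intensityMatrix(biologicalSamples(r1$table))
  by <- intensityMatrix(biologicalSamples(ry$table))
  expect_equal(by, b1 * 7)            # contrasts unchanged up to the constant
  expect_equal(by / rowSums(by), b1 / rowSums(b1))
})

test_that("PQN errors on rows with too few evaluable quotients", {
  x <- makeToySet(nBio = 3, nQc = 2, nBlank = 1, nFeat = 12)
  m <- intensityMatrix(x)
  m[2, 4:12] <- NA
  SummarizedExperiment::assay(x, "intensity") <- t(m)
  expect_error(pqnNormalize(x), "S2")
})

test_that("half-minimum imputation fills exactly the missing cells", {
  x <- makeToySet(nBio = 5, nQc = 2, nBlank = 1, nFeat = 4)
  m <- intensityMatrix(x)
  miss <- rbind(c(1, 2), c(3, 2), c(4, 3))
  m[miss] <- NA
  bioMin <- min(m[1:5, 2], na.rm = TRUE)
  SummarizedExperiment::assay(x, "intensity") <- t(m)
  y <- imputeMissing(x, "half_min")
  my <- intensityMatrix(y)
  expect_false(anyNA(my))
  expect_equal(sum(my != m, na.rm = TRUE), 0)          # present cells untouched
  expect_equal(unname(my[1, 2]), bioMin / 2)
  expect_equal(sum(is.na(m)), 3L)
  # no missing cells -> identity; method "none" is an assertion
  expect_identical(intensityMatrix(imputeMissing(y, "half_min")), my)
  expect_error(imputeMissing(x, "none"), "missing")
})

test_that("unit-variance scaling is exact and invertible", {
  set.seed(13)
  m <- matrix(rexp(60, 1e-6), 12, 5, dimnames = list(NULL, letters[1:5]))
  sc <- uvScale(m)
  expect_true(all(abs(colMeans(sc$scaled)) < 1e-12))
  expect_true(all(abs(apply(sc$scaled, 2, sd) - 1) < 1e-12))
  expect_equal(uvScale(cbind(x = c(1, 3)))$scaled[, 1],
               c(-0.7071, 0.7071), tolerance = 1e-4)
  expect_equal(uvUnscale(sc$scaled, sc$center, sc$scale), m,
               tolerance = 1e-10)
  m[, 3] <- 5
  expect_error(uvScale(m), "zero-variance.*c")
})
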