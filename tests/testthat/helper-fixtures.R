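# shared fixtures and independent oracles

# tiny hand-built feature set: nBio biological samples over the 4 x 2 design
# (recycled), plus QC and blank injections, intensities around 1e6
makeToySet <- function(nBio = 8, nQc = 2, nBlank = 1, nFeat = 5, seed = 42,
                       featureNames = sprintf("PC 3%d:%d", seq_len(nFeat), 0)) {
  set.seed(seed)
  origins <- rep(c("DLD1", "HCT116", "LS174T", "SW620"), length.out = nBio)
  resist <- rep(rep(c("naive", "resistant"), each = 4), length.out = nBio)
  n <- nBio + nQc + nBlank
  m <- matrix(exp(rnorm(n * nFeat, log(1e6), 0.2)), n, nFeat)
  m[seq(nBio + 1, nBio + nQc), ] <- matrix(
    rep(exp(log(1e6) + 0.01 * seq_len(nFeat)), each = nQc), nQc, nFeat)
  m[seq(nBio + nQc + 1, n), ] <- 1e3
  LipidFeatureSet(m,
    sampleIds = c(sprintf("S%d", seq_len(nBio)), sprintf("QC%d", seq_len(nQc)),
                  sprintf("B%d", seq_len(nBlank))),
    roles = c(rep("biological", nBio), rep("qc", nQc), rep("blank", nBlank)),
    origin = c(origins, rep(NA, nQc + nBlank)),
    resistance = c(resist, rep(NA, nQc + nBlank)),
    featureNames = featureNames)
}

# balanced 4 x 2 factor table with r replicates per cell
makeFactors <- function(r) {
  d <- expand.grid(rep = seq_len(r),
                   resistance = c("naive", "resistant"),
                   origin = c("DLD1", "HCT116", "LS174T", "SW620"),
                   stringsAsFactors = FALSE)
  data.frame(origin = d$origin, resistance = d$resistance,
             stringsAsFactors = FALSE)
}

# simulate and push through PQN + imputation + scaling
prepSim <- function(cfg) {
  sim <- simulateLipidData(cfg)
  norm <- pqnNormalize(sim$table)
  imp <- imputeMissing(norm$table)
  bio <- biologicalSamples(imp)
  list(X = uvScale(intensityMatrix(bio))$scaled,
       factors = designFactors(bio),
       truth = sim$truth, table = sim$table, normalized = norm)
}

# ---- independent oracles -------------------------------------------------

# two-way decomposition by explicit loops over groups
oracleDecompose <- function(X, factors) {
  n <- nrow(X); p <- ncol(X)
  a <- factors$origin; b <- factors$resistance
  grand <- colMeans(X)
  Xa <- Xb <- Xab <- E <- matrix(0, n, p)
  for (i in seq_len(n)) {
    ia <- which(a == a[i]); ib <- which(b == b[i])
    ic <- intersect(ia, ib)
    am <- colMeans(X[ia, , drop = FALSE])
    bm <- colMeans(X[ib, , drop = FALSE])
    cm <- colMeans(X[ic, , drop = FALSE])
    Xa[i, ] <- am - grand
    Xb[i, ] <- bm - grand
    Xab[i, ] <- cm - am - bm + grand
    E[i, ] <- X[i, ] - cm
  }
  tot <- sum(sweep(X, 2, grand)^2)
  list(origin = Xa, resistance = Xb, interaction = Xab, residual = E,
       shares = c(origin = sum(Xa^2), resistance = sum(Xb^2),
                  interaction = sum(Xab^2), residual = sum(E^2)) / tot)
}

# Gram matrix by explicit loops
oracleGram <- function(M) {
  n <- nrow(M)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- sum(M[i, ] * M[j, ])
  K
}

# predictive subspace by direct eigendecomposition of the Y-projected
# consensus kernel (the estimator itself never calls eigen())
oraclePredictive <- function(decomp, Y, nPred) {
  K <- blockKernels(decomp)$consensus
  q <- qr(Y)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  P <- tcrossprod(Q)
  e <- eigen(P %*% K %*% P, symmetric = TRUE)
  list(vectors = e$vectors[, seq_len(nPred), drop = FALSE],
       values = e$values[seq_len(nPred)])
}

maxPrincipalAngle <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  max(acos(pmin(1, svd(crossprod(qa, qb))$d)))
}

# 20-feature table in which each quality rule fails an engineered, disjoint
# pair of features: 2 high-missingness, 2 weak-in-QC, 2 noisy-in-QC,
# 2 constant; 12 clean features remain
makeFilterFixture <- function() {
  nBio <- 10; nQc <- 4; nBlank <- 2
  feats <- sprintf("PC %d:1", 30 + seq_len(20))
  m <- matrix(1e6, nBio + nQc + nBlank, 20,
              dimnames = list(NULL, feats))
  bioRows <- seq_len(nBio); qcRows <- nBio + seq_len(nQc)
  blankRows <- nBio + nQc + seq_len(nBlank)
  set.seed(1)
  m[bioRows, ] <- exp(rnorm(nBio * 20, log(1e6), 0.1))
  m[qcRows, ] <- rep(exp(rnorm(20, log(1e6), 0.02)), each = nQc) *
    exp(rnorm(nQc * 20, 0, 0.01))
  m[blankRows, ] <- 10

  m[bioRows[3:10], 1:2] <- NA                       # missingness 0.8 > 0.75
  m[qcRows, 3:4] <- 5e4                             # QC mean < 1e5
  m[qcRows, 5:6] <- rep(c(1e6, 3e6, 1e6, 3e6), 2)   # QC CV ~ 0.58 > 0.40
  m[bioRows, 7:8] <- 2e6                            # IQR = 0

  LipidFeatureSet(m,
    sampleIds = sprintf("I%02d", seq_len(nrow(m))),
    roles = rep(c("biological", "qc", "blank"), c(nBio, nQc, nBlank)),
    origin = c(rep(c("DLD1", "HCT116", "LS174T", "SW620"), length.out = nBio),
               rep(NA, nQc + nBlank)),
    resistance = c(rep(c("naive", "resistant"), length.out = nBio),
                   rep(NA, nQc + nBlank)),
    featureNames = feats)
}
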