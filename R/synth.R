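.ORIGINS <- c("DLD1", "HCT116", "LS174T", "SW620")
.RESISTANCE <- c("naive", "resistant")

.defaultPalette <- c(TG = 0.20, PC = 0.16, etherPC = 0.08, PE = 0.08,
                     SM = 0.08, HexCer = 0.05, Cer_NS = 0.05, PI = 0.04,
                     PS = 0.04, LPC = 0.04, LPE = 0.03, DG = 0.04,
                     CE = 0.04, BMP = 0.03, etherTG = 0.04)

#' Configuration for the factorial lipidomics simulator
#'
#' Defaults emulate the study regime the package targets: a balanced 4 x 2
#' design (four colorectal-cancer cell origins x naive/resistant status)
#' with 6 replicates per cell, 5 pooled-QC and 3 blank injections,
#' log-normal intensities whose centred sum of squares splits into
#' origin/resistance/interaction/residual fractions of
#' 58.4/7.8/18.1/15.7%, moderate per-sample dilution, and sparse
#' missingness.
#'
#' @param nFeatures number of lipid features.
#' @param replicatesPerCell biological replicates per design cell (>= 2).
#' @param nQc,nBlank numbers of pooled-QC and blank injections.
#' @param effectFractions named fractions of the centred sum of squares for
#'   `origin`, `resistance`, `interaction`, `residual`; must sum to 1.
#' @param dilutionSd log-scale sd of per-sample dilution factors.
#' @param missingRate fraction of biological cells deleted at random.
#' @param classPalette named numeric: lipid classes with feature counts
#'   (integers) or proportions (rescaled to `nFeatures`).
#' @param seed integer seed; same seed, same dataset.
#' @param signalSd per-feature log-scale sd of the design + noise part
#'   (0.25 by default, i.e. ~25% biological CV).
#' @param baselineLogMean,baselineLogSd log-normal baseline abundance
#'   parameters (defaults `log(1e6)` and 1).
#' @param qcNoiseSd log-scale analytical noise of QC injections.
#' @param blankLevel blank signal as a fraction of a feature's baseline.
#' @param orthFraction fraction of the total centred sum of squares carried
#'   by a single structured design-orthogonal source (taken out of the
#'   residual fraction; must not exceed it).
#' @param nullFeatureFrac fraction of features carrying no design effects
#'   (pure noise), for effect-localisation scenarios.
#' @param nBlankFail number of features whose blank signal is raised so the
#'   5x-blank missingness rule removes them (reported in the truth).
#' @param plantedLog2fc optional data.frame with columns `lipid_class`,
#'   `origin`, `log2fc`: an extra resistant-vs-naive shift for all features
#'   of that class in that origin.
#' @return validated list of class `SimConfig`.
#' @export
simConfig <- function(nFeatures = 750L, replicatesPerCell = 6L, nQc = 5L,
                      nBlank = 3L,
                      effectFractions = c(origin = 0.584, resistance = 0.078,
                                          interaction = 0.181, residual = 0.157),
                      dilutionSd = 0.2, missingRate = 0.02,
                      classPalette = .defaultPalette, seed = 1L,
                      signalSd = 0.25, baselineLogMean = log(1e6),
                      baselineLogSd = 1, qcNoiseSd = 0.05,
                      blankLevel = 1e-3, orthFraction = 0,
                      nullFeatureFrac = 0, nBlankFail = 0L,
                      plantedLog2fc = NULL) {
  cfg <- list(nFeatures = as.integer(nFeatures),
              replicatesPerCell = as.integer(replicatesPerCell),
              nQc = as.integer(nQc), nBlank = as.integer(nBlank),
              effectFractions = effectFractions, dilutionSd = dilutionSd,
              missingRate = missingRate, classPalette = classPalette,
              seed = as.integer(seed), signalSd = signalSd,
              baselineLogMean = baselineLogMean, baselineLogSd = baselineLogSd,
              qcNoiseSd = qcNoiseSd, blankLevel = blankLevel,
              orthFraction = orthFraction, nullFeatureFrac = nullFeatureFrac,
              nBlankFail = as.integer(nBlankFail),
              plantedLog2fc = plantedLog2fc)
  class(cfg) <- "SimConfig"
  validateSimConfig(cfg)
  cfg
}

#' Validate a simulator configuration
#' @param cfg list of class `SimConfig`.
#' @return `cfg`, invisibly, or an error.
#' @export
validateSimConfig <- function(cfg) {
  f <- cfg$effectFractions
  need <- c("origin", "resistance", "interaction", "residual")
  if (!all(need %in% names(f))) stop("effectFractions must name ",
                                     paste(need, collapse = ", "))
  if (abs(sum(f) - 1) > 1e-9) stop("effectFractions must sum to 1")
  if (any(f < 0)) stop("effectFractions must be non-negative")
  if (cfg$replicatesPerCell < 2L)
    stop("replicatesPerCell must be >= 2 for residual estimability")
  if (f[["residual"]] <= 0)
    stop("infeasible fractions: residual must be > 0 with replicated cells")
  if (cfg$orthFraction < 0 || cfg$orthFraction > f[["residual"]] + 1e-12)
    stop("orthFraction must lie within the residual fraction")
  if (cfg$missingRate < 0 || cfg$missingRate >= 1)
    stop("missingRate must be in [0, 1)")
  if (cfg$dilutionSd < 0) stop("dilutionSd must be >= 0")
  if (cfg$nullFeatureFrac < 0 || cfg$nullFeatureFrac >= 1)
    stop("nullFeatureFrac must be in [0, 1)")
  if (cfg$nFeatures < 2L) stop("nFeatures must be >= 2")
  invisible(cfg)
}

# sample distinct shorthand names per class; sphingolipid classes get an
# oxygen suffix, ether classes the O- prefix
.sampleFeatureNames <- function(palette, nFeatures) {
  counts <- if (abs(sum(palette) - 1) < 0.1)
    round(palette * nFeatures) else round(palette)
  while (sum(counts) != nFeatures) {
    i <- if (sum(counts) > nFeatures) which.max(counts) else which.min(counts)
    counts[i] <- counts[i] + sign(nFeatures - sum(counts))
  }
  names(counts) <- names(palette)
  out <- character(0); cls <- character(0)
  for (k in names(counts)) {
    nk <- counts[[k]]
    if (nk <= 0) next
    ether <- grepl("^ether", k)
    base <- sub("^ether", "", k)
    grid <- expand.grid(c = 30:60, d = 0:8)
    pick <- grid[sample(nrow(grid), min(nk, nrow(grid))), , drop = FALSE]
    ox <- if (.isSphingo(base)) sample(2:3, nrow(pick), replace = TRUE) else 0L
    nm <- sprintf("%s %s%d:%d%s", base, if (ether) "O-" else "",
                  pick$c, pick$d,
                  ifelse(ox > 0, sprintf(";%dO", ox), ""))
    out <- c(out, nm); cls <- c(cls, rep(k, length(nm)))
  }
  list(names = out, classes = cls)
}

# center a vector within design cells (remove cell means)
.removeCellMeans <- function(v, cellId) {
  v - ave(v, cellId)
}

#' Simulate a factorial lipidomics feature table with known truth
#'
#' Generates a balanced 4 x 2 design on the log-intensity scale: for every
#' feature, centred level offsets for origin, resistance and their
#' interaction are drawn and rescaled so the feature's centred
#' sum-of-squares shares match `effectFractions` exactly; residual noise is
#' projected into the within-cell stratum and rescaled likewise, so the
#' requested fractions are exact on the log scale (downstream recovery on
#' the exponentiated, normalized, rescaled table is approximate only
#' through the log-to-linear distortion). Intensities are exponentiated,
#' multiplied by per-sample log-normal dilution factors, and completed with
#' pooled-QC injections (noisy copies of the baseline profile), blank
#' injections (low-level noise), and random missingness.
#'
#' @param cfg A `SimConfig` from [simConfig()].
#' @return list with elements `table` (a [LipidFeatureSet-class]) and
#'   `truth` (list: `effectMatrices` — the noiseless log-scale origin /
#'   resistance / interaction matrices; `dilutionFactors`;
#'   `trueFractions` — realized log-scale shares; `orthScores` /
#'   `orthLoadings` for the planted design-orthogonal source;
#'   `effectFeatures` — features carrying design effects;
#'   `blankFailFeatures`; `classShares` — expected per-group class
#'   composition of the noiseless table).
#' @export
simulateLipidData <- function(cfg = simConfig()) {
  validateSimConfig(cfg)
  set.seed(cfg$seed)
  r <- cfg$replicatesPerCell
  design <- expand.grid(rep = seq_len(r), resistance = .RESISTANCE,
                        origin = .ORIGINS, stringsAsFactors = FALSE)
  n <- nrow(design)
  a <- design$origin; b <- design$resistance
  cellId <- paste(a, b, sep = ".")
  sampleIds <- sprintf("%s_%s_%d", a, b, design$rep)

  p <- cfg$nFeatures
  feats <- .sampleFeatureNames(cfg$classPalette, p)
  fn <- feats$names

  isNull <- rep(FALSE, p)
  if (cfg$nullFeatureFrac > 0)
    isNull[sample(p, round(cfg$nullFeatureFrac * p))] <- TRUE

  fr <- cfg$effectFractions
  frIid <- fr[["residual"]] - cfg$orthFraction

  # one design-orthogonal structured source shared by all features
  v <- .removeCellMeans(rnorm(n), cellId)
  v <- v / sqrt(sum(v^2))

  m0 <- rnorm(p, cfg$baselineLogMean, cfg$baselineLogSd)
  Ttot <- n * cfg$signalSd^2

  scaleTo <- function(x, ssTarget) {
    ss <- sum(x^2)
    if (ssTarget <= 0 || ss <= 0) x * 0 else x * sqrt(ssTarget / ss)
  }

  A <- B <- G <- E <- matrix(0, n, p)
  W <- numeric(p)
  for (j in seq_len(p)) {
    fj <- if (isNull[j]) c(origin = 0, resistance = 0, interaction = 0,
                           residual = 1) else fr
    foj <- if (isNull[j]) 0 else cfg$orthFraction
    fij <- fj[["residual"]] - foj

    al <- rnorm(4); al <- al - mean(al)
    A[, j] <- scaleTo(al[match(a, .ORIGINS)], fj[["origin"]] * Ttot)
    bl <- rnorm(2); bl <- bl - mean(bl)
    B[, j] <- scaleTo(bl[match(b, .RESISTANCE)], fj[["resistance"]] * Ttot)
    gl <- matrix(rnorm(8), 4, 2)
    gl <- gl - rowMeans(gl)
    gl <- sweep(gl, 2, colMeans(gl))
    G[, j] <- scaleTo(gl[cbind(match(a, .ORIGINS), match(b, .RESISTANCE))],
                      fj[["interaction"]] * Ttot)
    # residual noise stays i.i.d. across all design strata (as analytical
    # noise is), but is scaled so its within-cell part carries the requested
    # residual sum of squares; the small spill into the effect strata is the
    # natural finite-sample bias of the ANOVA shares
    e <- rnorm(n)
    e <- e - v * sum(v * e)                 # keep the planted source clean
    w <- .removeCellMeans(e, cellId)
    ssw <- sum(w^2)
    E[, j] <- if (fij <= 0 || ssw <= 0) e * 0 else
      e * sqrt(fij * Ttot / ssw)
    W[j] <- if (foj > 0) sample(c(-1, 1), 1) * sqrt(foj * Ttot) else 0
  }

  L <- m0[col(A)] + A + B + G + outer(v, W) + E
  if (!is.null(cfg$plantedLog2fc)) {
    ann <- annotateLipids(fn)
    for (i in seq_len(nrow(cfg$plantedLog2fc))) {
      pl <- cfg$plantedLog2fc[i, ]
      jj <- which(ann$lipid_class == pl$lipid_class |
                    feats$classes == pl$lipid_class)
      ii <- which(a == pl$origin & b == "resistant")
      L[ii, jj] <- L[ii, jj] + pl$log2fc * log(2)
    }
  }

  dil <- exp(rnorm(n, 0, cfg$dilutionSd))
  bio <- exp(L) * dil

  if (cfg$missingRate > 0)
    bio[matrix(runif(n * p) < cfg$missingRate, n, p)] <- NA_real_

  qc <- t(vapply(seq_len(cfg$nQc), function(i)
    exp(m0 + rnorm(p, 0, cfg$qcNoiseSd)), numeric(p)))
  blankBase <- exp(m0) * cfg$blankLevel
  blankFail <- character(0)
  if (cfg$nBlankFail > 0) {
    idx <- sample(which(!isNull), min(cfg$nBlankFail, sum(!isNull)))
    blankBase[idx] <- exp(m0[idx]) * 0.5
    blankFail <- fn[idx]
  }
  blank <- t(vapply(seq_len(cfg$nBlank), function(i)
    blankBase * exp(rnorm(p, 0, 0.3)), numeric(p)))

  intensities <- rbind(bio, qc, blank)
  ids <- c(sampleIds, sprintf("QC_%d", seq_len(cfg$nQc)),
           sprintf("Blank_%d", seq_len(cfg$nBlank)))
  roles <- c(rep("biological", n), rep("qc", cfg$nQc), rep("blank", cfg$nBlank))
  table <- LipidFeatureSet(intensities, sampleIds = ids, roles = roles,
                           origin = c(a, rep(NA, cfg$nQc + cfg$nBlank)),
                           resistance = c(b, rep(NA, cfg$nQc + cfg$nBlank)),
                           featureNames = fn)

  # realized log-scale shares, measured the same way the analysis will
  realized <- ssShares(decomposeEffects(L, data.frame(origin = a,
                                                      resistance = b)))
  dimnames(A) <- dimnames(B) <- dimnames(G) <- list(sampleIds, fn)

  # expected class shares of the noiseless per-group mean table
  groupMeanLog <- m0[col(A)] + A + B + G
  lin <- exp(groupMeanLog)
  grp <- paste(a, b, sep = ".")
  classShares <- do.call(rbind, lapply(unique(grp), function(g) {
    mi <- colMeans(lin[grp == g, , drop = FALSE])
    sh <- tapply(mi, feats$classes, sum) / sum(mi)
    data.frame(origin = sub("\\..*$", "", g),
               resistance = sub("^.*\\.", "", g),
               lipid_class = names(sh), share = as.numeric(sh),
               row.names = NULL)
  }))

  truth <- list(effectMatrices = list(origin = A, resistance = B,
                                      interaction = G),
                dilutionFactors = setNames(c(dil, rep(1, cfg$nQc + cfg$nBlank)),
                                           ids),
                trueFractions = realized,
                orthScores = v, orthLoadings = setNames(W, fn),
                effectFeatures = fn[!isNull],
                blankFailFeatures = blankFail,
                classShares = classShares)
  list(table = table, truth = truth)
}
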