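#' Two-way ANOVA decomposition into pure effect matrices
#'
#' Splits a (typically unit-variance-scaled) biological-sample matrix into
#' grand mean, pure effect matrices for the two fixed design factors and
#' their interaction, and within-cell residuals:
#' row i of the origin matrix is the origin-level mean minus the grand
#' mean, the resistance matrix analogously, the interaction matrix is the
#' cell mean minus both level means plus the grand mean, and the residual
#' is the observation minus its cell mean. In a balanced design the four
#' matrices are pairwise orthogonal, they reconstruct the input exactly,
#' and the sum-of-squares shares (each term's squared Frobenius norm over
#' the grand-mean-centred total) sum to 1.
#'
#' @param X numeric matrix, samples x features, no missing values.
#' @param factors data.frame with columns `origin` and `resistance`, one
#'   row per sample of `X`.
#' @param unbalanced `"error"` (default; the supported designs are
#'   balanced) or `"weighted"`, an extension that uses per-cell means with
#'   unweighted level averaging; with unbalanced data orthogonality and the
#'   unit sum of shares are no longer guaranteed.
#' @return An [EffectDecomposition-class].
#' @export
decomposeEffects <- function(X, factors, unbalanced = c("error", "weighted")) {
  unbalanced <- match.arg(unbalanced)
  X <- as.matrix(X)
  if (anyNA(X)) stop("decomposeEffects expects a complete matrix")
  if (nrow(X) != nrow(factors)) stop("factors must have one row per sample")
  a <- as.character(factors$origin)
  b <- as.character(factors$resistance)
  if (anyNA(a) || anyNA(b)) stop("factors must be complete")
  cellId <- paste(a, b, sep = "\r")
  tab <- table(a, b)
  if (any(tab == 0)) stop("empty design cell: every origin x resistance ",
                          "combination needs at least one sample")
  if (length(unique(as.vector(tab))) != 1L && unbalanced == "error")
    stop("unbalanced design; pass unbalanced = 'weighted' to use the ",
         "unweighted-means extension")

  groupMeans <- function(g) {
    gm <- rowsum(X, g) / as.vector(table(g)[sort(unique(g))])
    gm[order(rownames(gm)), , drop = FALSE]
  }
  cellMean <- groupMeans(cellId)

  if (unbalanced == "weighted" && length(unique(as.vector(tab))) != 1L) {
    # unweighted (Type-III-like) level means from cell means
    cellA <- sub("\r.*$", "", rownames(cellMean))
    cellB <- sub("^.*\r", "", rownames(cellMean))
    aMean <- rowsum(cellMean, cellA) / as.vector(table(cellA)[sort(unique(cellA))])
    bMean <- rowsum(cellMean, cellB) / as.vector(table(cellB)[sort(unique(cellB))])
    grand <- colMeans(cellMean)
  } else {
    aMean <- groupMeans(a)
    bMean <- groupMeans(b)
    grand <- colMeans(X)
  }

  Xa <- aMean[a, , drop = FALSE] - matrix(grand, nrow(X), ncol(X), byrow = TRUE)
  Xb <- bMean[b, , drop = FALSE] - matrix(grand, nrow(X), ncol(X), byrow = TRUE)
  cm <- cellMean[cellId, , drop = FALSE]
  Xab <- cm - aMean[a, , drop = FALSE] - bMean[b, , drop = FALSE] +
    matrix(grand, nrow(X), ncol(X), byrow = TRUE)
  E <- X - cm
  dimnames(Xa) <- dimnames(Xb) <- dimnames(Xab) <- dimnames(E) <- dimnames(X)

  ssTot <- sum((X - matrix(grand, nrow(X), ncol(X), byrow = TRUE))^2)
  ss <- c(origin = sum(Xa^2), resistance = sum(Xb^2),
          interaction = sum(Xab^2), residual = sum(E^2))
  shares <- if (ssTot > 0) ss / ssTot else ss * 0

  methods::new("EffectDecomposition", grandMean = grand,
               effectMatrices = list(origin = Xa, resistance = Xb,
                                     interaction = Xab),
               residuals = E, ssShares = shares,
               design = data.frame(origin = a, resistance = b,
                                   stringsAsFactors = FALSE))
}
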