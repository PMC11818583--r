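#' Build the column-centred dummy response for the design
#'
#' One indicator block per included effect: origin (4 columns), resistance
#' (2), interaction (one column per design cell, 8); each block's rows sum
#' to 1 before the final column-centring. For the full two-factor design
#' the centred matrix has rank 7 (`sum(levels - 1)` over effects).
#'
#' @param factors data.frame with columns `origin`, `resistance`.
#' @param effects character subset of
#'   `c("origin", "resistance", "interaction")`.
#' @return centred indicator matrix with a `"blocks"` attribute mapping
#'   columns to effects.
#' @export
buildDummyResponse <- function(factors,
                               effects = c("origin", "resistance", "interaction")) {
  effects <- match.arg(effects, several.ok = TRUE)
  a <- as.character(factors$origin)
  b <- as.character(factors$resistance)
  lev <- function(g, tag) {
    ls <- sort(unique(g))
    m <- outer(g, ls, "==") * 1
    colnames(m) <- paste(tag, ls, sep = ":")
    m
  }
  parts <- list()
  if ("origin" %in% effects) parts$origin <- lev(a, "origin")
  if ("resistance" %in% effects) parts$resistance <- lev(b, "resistance")
  if ("interaction" %in% effects)
    parts$interaction <- lev(paste(a, b, sep = "."), "cell")
  Y <- do.call(cbind, parts)
  blocks <- rep(names(parts), vapply(parts, ncol, 1L))
  Y <- sweep(Y, 2, colMeans(Y))
  if (all(abs(Y) < 1e-12))
    stop("degenerate design: all samples fall in a single cell")
  attr(Y, "blocks") <- blocks
  Y
}

# projection matrix onto the column space of (centred) Y
.projY <- function(Y) {
  q <- qr(Y)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

# cyclic Jacobi eigendecomposition of a small dense symmetric matrix;
# self-contained so the multiblock estimator does not route through the
# LAPACK eigensolver that serves as its independent cross-check
.jacobiEigen <- function(H, tol = 1e-13, maxSweeps = 100L) {
  n <- nrow(H)
  V <- diag(n)
  if (n == 1L) return(list(values = H[1, 1], vectors = V))
  scale <- max(sqrt(sum(diag(H)^2)), .Machine$double.eps)
  for (s in seq_len(maxSweeps)) {
    if (sqrt(2 * sum(H[upper.tri(H)]^2)) < tol * scale) break
    for (p in seq_len(n - 1L)) for (q in (p + 1L):n) {
      hpq <- H[p, q]
      if (abs(hpq) < tol * scale) next
      theta <- (H[q, q] - H[p, p]) / (2 * hpq)
      t <- if (theta == 0) 1 else sign(theta) / (abs(theta) + sqrt(theta^2 + 1))
      cs <- 1 / sqrt(t^2 + 1); sn <- t * cs
      Hp <- H[, p]; Hq <- H[, q]
      H[, p] <- cs * Hp - sn * Hq; H[, q] <- sn * Hp + cs * Hq
      Hp <- H[p, ]; Hq <- H[q, ]
      H[p, ] <- cs * Hp - sn * Hq; H[q, ] <- sn * Hp + cs * Hq
      Vp <- V[, p]; Vq <- V[, q]
      V[, p] <- cs * Vp - sn * Vq; V[, q] <- sn * Vp + cs * Vq
    }
  }
  ord <- order(diag(H), decreasing = TRUE)
  list(values = diag(H)[ord], vectors = V[, ord, drop = FALSE])
}

# top-k eigenpairs of a symmetric PSD matrix by Ritz-accelerated subspace
# iteration: deterministic initialization from the leading columns of M,
# a guard block beyond k to resolve eigenvalue clusters, residual-based
# convergence at `tol`, at most `maxIter` iterations (then an error).
.topEigen <- function(M, k, tol = 1e-10, maxIter = 1e4) {
  n <- nrow(M)
  k <- min(k, n)
  if (sqrt(sum(M^2)) < .Machine$double.eps)
    return(list(vectors = matrix(0, n, k), values = numeric(k)))
  b <- min(n, k + 8L)
  # modified Gram-Schmidt (two passes), padded with coordinate vectors so
  # the block keeps full width even when M's image is rank-deficient
  orth <- function(V) {
    basis <- matrix(0, n, 0)
    add <- function(v) {
      for (pass in 1:2) if (ncol(basis))
        v <- v - basis %*% crossprod(basis, v)
      nv <- sqrt(sum(v^2))
      if (nv > 1e-12) basis <<- cbind(basis, v / nv)
    }
    for (j in seq_len(ncol(V))) add(V[, j])
    j <- 1L
    while (ncol(basis) < b && j <= n) {
      e <- numeric(n); e[j] <- 1
      add(e); j <- j + 1L
    }
    basis
  }
  V <- orth(M[, seq_len(min(b, ncol(M))), drop = FALSE])
  scale <- max(abs(sum(diag(M))), .Machine$double.eps)
  for (i in seq_len(maxIter)) {
    V <- orth(M %*% V)
    H <- crossprod(V, M %*% V)
    H <- (H + t(H)) / 2
    ritz <- .jacobiEigen(H)
    U <- V %*% ritz$vectors[, seq_len(k), drop = FALSE]
    rho <- ritz$values[seq_len(k)]
    resid <- M %*% U - U %*% diag(rho, k)
    if (max(sqrt(colSums(resid^2))) <= tol * scale)
      return(list(vectors = U, values = pmax(rho, 0)))
    V <- V %*% ritz$vectors
  }
  stop("subspace iteration did not converge within ", maxIter,
       " iterations (tol ", tol, "); residual ",
       signif(max(sqrt(colSums(resid^2))) / scale, 3))
}

#' Normalized block kernels and their consensus
#'
#' Builds, for each block of the decomposition (the three pure effect
#' matrices and the residual), the sample-space Gram matrix
#' `K_b = X_b X_b'`, scaled to unit Frobenius norm so that no block
#' dominates by size; the consensus kernel is the unweighted mean of the
#' normalized kernels. An all-zero block keeps a zero kernel (with a
#' warning): its contribution to every component is then 0.
#'
#' @param decomp An [EffectDecomposition-class], or a named list of
#'   samples x features block matrices.
#' @return list with elements `kernels` (named list), `consensus` (matrix).
#' @export
blockKernels <- function(decomp) {
  blocks <- if (methods::is(decomp, "EffectDecomposition"))
    c(decomp@effectMatrices, list(residual = decomp@residuals))
  else decomp
  kernels <- lapply(names(blocks), function(nm) {
    K <- tcrossprod(as.matrix(blocks[[nm]]))
    f <- sqrt(sum(K^2))
    if (f < .Machine$double.eps) {
      warning("block '", nm, "' is all zero; its kernel is the zero matrix")
      K[] <- 0
      K
    } else K / f
  })
  names(kernels) <- names(blocks)
  list(kernels = kernels, consensus = Reduce(`+`, kernels) / length(kernels))
}

#' Fit the ANOVA multiblock orthogonal PLS model
#'
#' Kernel-OPLS estimation on the consensus kernel of the effect blocks.
#' Predictive components are extracted from the response-projected
#' consensus kernel `P_Y K P_Y` (power iteration with deflation); each
#' orthogonal component is the leading structure of the response-orthogonal
#' part `(I - P_Y) K (I - P_Y)`, deflated from the kernel before the
#' predictive components are re-estimated. For every component the block
#' contribution is `lambda[b, c] = t_c' K_b t_c / sum_b t_c' K_b t_c`;
#' each predictive component is attributed to the block with the largest
#' contribution. Per-component explained data variance is measured by
#' projecting the reconstructed data matrix on the score, and R2Y is the
#' fraction of response sum of squares explained by the predictive scores.
#' Component signs follow the convention that the largest-magnitude loading
#' entry is positive (ties broken by lowest feature index).
#'
#' @param decomp An [EffectDecomposition-class], or a named list of block
#'   matrices whose last element is treated as residual.
#' @param Y centred dummy response from [buildDummyResponse()]; defaults to
#'   the full-design response built from the decomposition's own factors.
#' @param nPred number of predictive components; default = rank of `Y`.
#' @param nOrth number of orthogonal components (default 1).
#' @param X optional samples x features data matrix used for loadings and
#'   explained variance; defaults to the sum of the blocks (the
#'   grand-mean-centred data).
#' @return An [AmoplsModel-class].
#' @export
fitAmopls <- function(decomp, Y = NULL, nPred = NULL, nOrth = 1L, X = NULL) {
  if (methods::is(decomp, "EffectDecomposition")) {
    if (is.null(Y)) Y <- buildDummyResponse(decomp@design)
    if (is.null(X)) X <- reconstruct(decomp) -
        matrix(decomp@grandMean, nrow(decomp@residuals),
               ncol(decomp@residuals), byrow = TRUE)
  } else if (is.null(X)) X <- Reduce(`+`, decomp)
  if (is.null(Y)) stop("Y is required when decomp is a plain block list")

  bk <- blockKernels(decomp)
  K <- bk$consensus
  n <- nrow(K)
  rankY <- qr(Y)$rank
  if (is.null(nPred)) nPred <- rankY
  nPred <- as.integer(nPred); nOrth <- as.integer(nOrth)
  if (nPred < 1L || nPred > rankY)
    stop("nPred must be between 1 and rank(Y) = ", rankY)
  P <- .projY(Y)
  Qp <- diag(n) - P

  extractPred <- function(Kcur) {
    e <- .topEigen(P %*% Kcur %*% P, nPred)
    sweep(e$vectors, 2, sqrt(pmax(e$values, 0)), "*")
  }

  Kcur <- K
  Torth <- matrix(0, n, nOrth)
  if (nOrth > 0) for (j in seq_len(nOrth)) {
    eo <- .topEigen(Qp %*% Kcur %*% Qp, 1L)
    to <- eo$vectors[, 1] * sqrt(max(eo$values[1], 0))
    Torth[, j] <- to
    ss <- sum(to^2)
    if (ss > 0) {
      D <- diag(n) - tcrossprod(to) / ss
      Kcur <- D %*% Kcur %*% D
    }
  }
  Tpred <- extractPred(Kcur)

  scoreNames <- function(tag, k) if (k) paste0(tag, seq_len(k)) else character()
  colnames(Tpred) <- scoreNames("tp", nPred)
  colnames(Torth) <- scoreNames("tpo", nOrth)
  rownames(Tpred) <- rownames(Torth) <- rownames(X)

  # feature-space loadings, with the sign convention applied to both
  loadingFor <- function(t) {
    ss <- sum(t^2)
    if (ss <= 0) rep(0, ncol(X)) else as.vector(crossprod(X, t)) / ss
  }
  fixSign <- function(t, p) {
    i <- which.max(abs(p))        # ties: which.max takes the lowest index
    if (length(i) && p[i] < 0) list(t = -t, p = -p) else list(t = t, p = p)
  }
  Ppred <- matrix(0, ncol(X), nPred)
  for (c in seq_len(nPred)) {
    s <- fixSign(Tpred[, c], loadingFor(Tpred[, c]))
    Tpred[, c] <- s$t; Ppred[, c] <- s$p
  }
  Porth <- matrix(0, ncol(X), nOrth)
  if (nOrth > 0) for (c in seq_len(nOrth)) {
    s <- fixSign(Torth[, c], loadingFor(Torth[, c]))
    Torth[, c] <- s$t; Porth[, c] <- s$p
  }
  dimnames(Ppred) <- list(colnames(X), colnames(Tpred))
  dimnames(Porth) <- list(colnames(X), colnames(Torth))

  allT <- cbind(Tpred, Torth)
  nb <- length(bk$kernels)
  lambda <- t(vapply(seq_len(ncol(allT)), function(c) {
    t <- allT[, c]
    contrib <- vapply(bk$kernels, function(Kb)
      max(as.vector(t %*% Kb %*% t), 0), 0)
    tot <- sum(contrib)
    if (tot > 0) contrib / tot else rep(1 / nb, nb)
  }, numeric(nb)))
  lambda <- matrix(lambda, ncol = nb,
                   dimnames = list(colnames(allT), names(bk$kernels)))

  ssX <- sum(X^2)
  compVar <- vapply(seq_len(ncol(allT)), function(c) {
    t <- allT[, c]; ss <- sum(t^2)
    if (ss <= 0 || ssX <= 0) 0 else {
      p <- as.vector(crossprod(X, t)) / ss
      ss * sum(p^2) / ssX
    }
  }, 0)
  names(compVar) <- colnames(allT)

  r2y <- {
    ss <- colSums(Tpred^2)
    tt <- Tpred[, ss > 1e-12 * max(ss, 0), drop = FALSE]
    if (!ncol(tt)) 0 else {
      fit <- tt %*% solve(crossprod(tt), crossprod(tt, Y))
      1 - sum((Y - fit)^2) / sum(Y^2)
    }
  }

  effBlocks <- setdiff(names(bk$kernels), character())
  attribution <- vapply(seq_len(nPred), function(c)
    names(bk$kernels)[which.max(lambda[c, ])], "")

  methods::new("AmoplsModel", scoresPred = Tpred, scoresOrth = Torth,
               loadingsPred = Ppred, loadingsOrth = Porth,
               lambda = lambda, attribution = attribution,
               compVar = compVar, r2y = r2y,
               blockNames = names(bk$kernels),
               nPred = nPred, nOrth = nOrth)
}

#' Back-project model scores to feature-space loadings
#'
#' `loading_c = X' t_c / (t_c' t_c)` for every (predictive and orthogonal)
#' component, indexed by lipid name.
#'
#' @param model An [AmoplsModel-class].
#' @param X the samples x features matrix the model was fitted on (scaled).
#' @return matrix, features x components.
#' @export
backProjectLoadings <- function(model, X) {
  X <- as.matrix(X)
  allT <- cbind(model@scoresPred, model@scoresOrth)
  if (nrow(X) != nrow(allT)) stop("X rows must match the model's samples")
  out <- apply(allT, 2, function(t) {
    ss <- sum(t^2)
    if (ss <= 0) rep(0, ncol(X)) else as.vector(crossprod(X, t)) / ss
  })
  rownames(out) <- colnames(X)
  out
}
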