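# deterministic per-effect sub-seed so adding one effect to a run does not
# perturb the null stream of another
.effectSeed <- function(seed, effect) {
  h <- sum(utf8ToInt(effect) * seq_along(utf8ToInt(effect)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

.amoplsStat <- function(model, effect) {
  pred <- seq_len(model@nPred)
  mine <- pred[model@attribution == effect]
  if (!length(mine)) return(0)
  sum(model@lambda[mine, effect] * model@compVar[mine])
}

.permuteFactors <- function(factors, effect) {
  f <- factors
  if (effect == "origin") {
    # restricted: permute origin labels within each resistance stratum
    for (lv in unique(f$resistance)) {
      i <- which(f$resistance == lv)
      f$origin[i] <- f$origin[sample(i)]
    }
  } else if (effect == "resistance") {
    for (lv in unique(f$origin)) {
      i <- which(f$origin == lv)
      f$resistance[i] <- f$resistance[sample(i)]
    }
  } else if (effect == "interaction") {
    # permute the joint cell assignment; margins are preserved because the
    # existing labels are only reordered
    i <- sample(nrow(f))
    f$origin <- f$origin[i]
    f$resistance <- f$resistance[i]
  } else stop("unknown effect: ", effect)
  f
}

.fitForFactors <- function(X, factors, nPred, nOrth) {
  dec <- decomposeEffects(X, factors)
  fitAmopls(dec, nPred = nPred, nOrth = nOrth)
}

#' Permutation significance of one design effect
#'
#' The observed statistic is the lambda-weighted explained variance summed
#' over the predictive components attributed to the tested effect. The null
#' is built by re-running the full decomposition + AMOPLS fit with the
#' tested effect's labels permuted: a main effect permutes its own factor
#' within strata of the other factor (restricted permutation), the
#' interaction permutes the joint cell assignment. The p-value is
#' `(1 + #(null >= observed)) / (1 + nPerm)`, so its floor is
#' `1 / (nPerm + 1)`.
#'
#' @param X preprocessed (scaled) samples x features matrix.
#' @param factors data.frame with columns `origin`, `resistance`.
#' @param effect `"origin"`, `"resistance"` or `"interaction"`.
#' @param nPerm number of permutations (default 1000).
#' @param seed integer; the per-effect stream is derived from it so results
#'   are reproducible and effects do not perturb each other's nulls.
#' @param nPred,nOrth model dimensions passed to [fitAmopls()].
#' @return A [PermutationResult-class].
#' @export
effectSignificance <- function(X, factors, effect, nPerm = 1000L, seed = 1L,
                               nPred = NULL, nOrth = 1L) {
  effect <- match.arg(effect, c("origin", "resistance", "interaction"))
  nPerm <- as.integer(nPerm)
  if (nPerm < 20L)
    warning("fewer than 20 permutations: p-value resolution is coarse")
  observed <- .amoplsStat(.fitForFactors(X, factors, nPred, nOrth), effect)
  nullStats <- withr::with_seed(.effectSeed(seed, effect), {
    vapply(seq_len(nPerm), function(i) {
      pf <- .permuteFactors(factors, effect)
      .amoplsStat(.fitForFactors(X, pf, nPred, nOrth), effect)
    }, 0)
  })
  p <- (1 + sum(nullStats >= observed)) / (1 + nPerm)
  methods::new("PermutationResult", effect = effect, observed = observed,
               nullStats = nullStats, pValue = p, nPerm = nPerm,
               seed = as.integer(seed))
}

#' Select the number of orthogonal components by permutation
#'
#' Orthogonal components are added one at a time; component `k` is retained
#' iff its captured data variance exceeds the 95th percentile of the same
#' quantity under full permutation of the sample labels (rows of the factor
#' table), re-running decomposition and fit each time. Stops at the first
#' non-retained component.
#'
#' @param X preprocessed samples x features matrix.
#' @param factors data.frame with columns `origin`, `resistance`.
#' @param maxOrth maximum components to consider (default 5).
#' @param nPerm permutations per component (default 1000).
#' @param seed integer.
#' @param nPred predictive components passed to [fitAmopls()].
#' @return integer count of retained orthogonal components. If `maxOrth` is
#'   reached while components are still significant, `maxOrth` is returned
#'   with a warning.
#' @export
selectNOrthogonal <- function(X, factors, maxOrth = 5L, nPerm = 1000L,
                              seed = 1L, nPred = NULL) {
  orthVar <- function(fac, k) {
    m <- .fitForFactors(X, fac, nPred, k)
    unname(m@compVar[m@nPred + k])
  }
  kept <- 0L
  withr::with_seed(.effectSeed(seed, "orthogonal"), {
    for (k in seq_len(maxOrth)) {
      obs <- orthVar(factors, k)
      nullV <- vapply(seq_len(nPerm), function(i) {
        pf <- factors[sample(nrow(factors)), , drop = FALSE]
        orthVar(pf, k)
      }, 0)
      if (obs > quantile(nullV, 0.95, names = FALSE)) kept <- k else break
    }
  })
  if (kept == maxOrth)
    warning("maxOrth reached with the last component still significant")
  kept
}
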