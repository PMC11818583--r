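#' @import methods
#' @importFrom stats median quantile sd cor var rnorm runif setNames ave
#' @importFrom utils read.delim write.csv head
#' @importFrom withr with_seed
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assayNames colData rowData
#' @importFrom S4Vectors DataFrame
NULL

.SAMPLE_ROLES <- c("biological", "qc", "blank")

#' Container for a lipidomics feature table with sample roles and design
#'
#' `LipidFeatureSet` extends
#' [SummarizedExperiment::SummarizedExperiment] with the conventions used
#' throughout this package: rows are lipid features, columns are injections,
#' the single assay `"intensity"` holds non-negative intensities with `NA`
#' for missing cells, `colData` carries `role` (one of `"biological"`,
#' `"qc"`, `"blank"`) and, for biological samples, the two design factors
#' `origin` and `resistance`. `rowData` may carry the parsed lipid
#' annotation columns produced by [parseLipidName()].
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#'
#' @seealso [readFeatureTable()], [simulateLipidData()], [filterFeatures()]
#' @export
setClass("LipidFeatureSet", contains = "SummarizedExperiment")

setValidity("LipidFeatureSet", function(object) {
  msgs <- character()
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("role", "origin", "resistance") %in% colnames(cd)))
    return("colData must contain 'role', 'origin' and 'resistance'")
  role <- as.character(cd$role)
  if (!all(role %in% .SAMPLE_ROLES))
    msgs <- c(msgs, sprintf("invalid roles: %s",
                            paste(unique(setdiff(role, .SAMPLE_ROLES)), collapse = ", ")))
  bio <- role == "biological"
  if (any(bio) &&
      (anyNA(cd$origin[bio]) || anyNA(cd$resistance[bio])))
    msgs <- c(msgs, "every biological sample needs both design factors")
  if (any(!bio) &&
      (!all(is.na(cd$origin[!bio])) || !all(is.na(cd$resistance[!bio]))))
    msgs <- c(msgs, "qc/blank samples must not carry design factors")
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'intensity' is required")
  else {
    x <- SummarizedExperiment::assay(object, "intensity")
    if (any(x < 0, na.rm = TRUE))
      msgs <- c(msgs, "intensities must be >= 0 where present")
  }
  if (anyDuplicated(rownames(object)))
    msgs <- c(msgs, "duplicate feature names")
  if (length(msgs)) msgs else TRUE
})

#' Two-way ANOVA decomposition of a designed data matrix
#'
#' Holds the grand mean, the pure effect matrices for the origin and
#' resistance main effects and their interaction, the residual matrix, and
#' the sum-of-squares share of each term relative to the grand-mean-centred
#' total. Produced by [decomposeEffects()].
#'
#' @slot grandMean numeric, per-feature grand mean.
#' @slot effectMatrices named list of matrices (`origin`, `resistance`,
#'   `interaction`), each conformal with the input (samples x features).
#' @slot residuals matrix of within-cell residuals.
#' @slot ssShares named numeric: fraction of the centred total sum of
#'   squares attributed to each effect and to the residual.
#' @slot design data.frame with columns `origin` and `resistance`, one row
#'   per sample, in input order.
#'
#' @export
setClass("EffectDecomposition",
  slots = c(grandMean = "numeric", effectMatrices = "list",
            residuals = "matrix", ssShares = "numeric", design = "data.frame"))

setValidity("EffectDecomposition", function(object) {
  msgs <- character()
  eff <- object@effectMatrices
  if (!all(c("origin", "resistance", "interaction") %in% names(eff)))
    return("effectMatrices must contain origin, resistance, interaction")
  dims <- vapply(eff, dim, integer(2))
  if (!all(dims == dim(object@residuals)))
    msgs <- c(msgs, "effect matrices and residuals must be conformal")
  if (nrow(object@design) != nrow(object@residuals))
    msgs <- c(msgs, "design rows must match sample rows")
  if (!all(c("origin", "resistance", "interaction", "residual") %in%
           names(object@ssShares)))
    msgs <- c(msgs, "ssShares must name all four terms")
  if (length(msgs)) msgs else TRUE
})

#' Fitted ANOVA multiblock orthogonal PLS model
#'
#' Result of [fitAmopls()]: predictive score vectors (one set spanning the
#' design-response space), orthogonal score vectors, feature-space loadings
#' for both, the block-contribution matrix lambda, the effect attribution of
#' each predictive component, per-component explained data variance, and the
#' fraction of response sum of squares explained.
#'
#' @slot scoresPred matrix, samples x predictive components (`tp1`, ...).
#' @slot scoresOrth matrix, samples x orthogonal components (`tpo1`, ...).
#' @slot loadingsPred,loadingsOrth matrices, features x components.
#' @slot lambda matrix, components x blocks; each row sums to 1.
#' @slot attribution character, per predictive component the block with the
#'   largest contribution.
#' @slot compVar named numeric, per-component share of total data variance.
#' @slot r2y numeric, fraction of response sum of squares explained by the
#'   predictive scores.
#' @slot blockNames character.
#' @slot nPred,nOrth integer.
#'
#' @export
setClass("AmoplsModel",
  slots = c(scoresPred = "matrix", scoresOrth = "matrix",
            loadingsPred = "matrix", loadingsOrth = "matrix",
            lambda = "matrix", attribution = "character",
            compVar = "numeric", r2y = "numeric",
            blockNames = "character", nPred = "integer", nOrth = "integer"))

setValidity("AmoplsModel", function(object) {
  msgs <- character()
  if (ncol(object@scoresPred) != object@nPred)
    msgs <- c(msgs, "scoresPred must have nPred columns")
  if (ncol(object@scoresOrth) != object@nOrth)
    msgs <- c(msgs, "scoresOrth must have nOrth columns")
  if (nrow(object@lambda) != object@nPred + object@nOrth)
    msgs <- c(msgs, "lambda needs one row per component")
  rs <- rowSums(object@lambda)
  if (length(rs) && any(abs(rs - 1) > 1e-6))
    msgs <- c(msgs, "lambda rows must sum to 1")
  if (length(msgs)) msgs else TRUE
})

#' Permutation-test result for one design effect
#'
#' @slot effect character, tested effect.
#' @slot observed numeric, observed test statistic.
#' @slot nullStats numeric, statistic under label permutation.
#' @slot pValue numeric, `(1 + #(null >= observed)) / (1 + nPerm)`.
#' @slot nPerm,seed integer.
#'
#' @export
setClass("PermutationResult",
  slots = c(effect = "character", observed = "numeric",
            nullStats = "numeric", pValue = "numeric",
            nPerm = "integer", seed = "integer"))

setValidity("PermutationResult", function(object) {
  n <- object@nPerm
  if (length(object@nullStats) != n)
    return("nullStats must have length nPerm")
  lo <- 1 / (n + 1)
  if (object@pValue < lo - 1e-12 || object@pValue > 1 + 1e-12)
    return("pValue outside [1/(nPerm+1), 1]")
  TRUE
})

#' Feature-quality filter report
#'
#' Records, for each quality rule, the features failing it (sets may
#' overlap) and the first failing rule per removed feature, in the rule
#' order: missingness vs blank, QC mean intensity, QC CV, zero IQR.
#'
#' @slot nInput,nRetained integer.
#' @slot removed named list of character vectors, one per rule
#'   (`missingness`, `qc_intensity`, `qc_cv`, `iqr`).
#' @slot firstFailing named character: removed feature -> first failing rule.
#' @slot thresholds named numeric, thresholds the rules used.
#'
#' @export
setClass("FilterReport",
  slots = c(nInput = "integer", nRetained = "integer", removed = "list",
            firstFailing = "character", thresholds = "numeric"))

setValidity("FilterReport", function(object) {
  ok <- c("missingness", "qc_intensity", "qc_cv", "iqr")
  if (!identical(names(object@removed), ok))
    return("removed must list rules missingness, qc_intensity, qc_cv, iqr")
  un <- unique(unlist(object@removed))
  if (object@nRetained != object@nInput - length(un))
    return("nRetained must equal nInput minus the union of removed sets")
  TRUE
})
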