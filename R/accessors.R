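#' Construct a LipidFeatureSet
#'
#' Assembles the package's central container from an intensity matrix in
#' injection-major orientation (rows = injections, columns = features), the
#' per-injection role, and the design factors of the biological samples.
#'
#' @param intensities numeric matrix, rows = injections, columns = features;
#'   `NA` marks a missing cell.
#' @param sampleIds character, one id per injection.
#' @param roles character, one of `"biological"`, `"qc"`, `"blank"`.
#' @param origin,resistance character/factor per injection; must be `NA` for
#'   non-biological injections and set for biological ones.
#' @param featureNames character, lipid shorthand names (unique).
#' @param annotate logical; parse `featureNames` with [parseLipidName()]
#'   into `rowData`.
#'
#' @return A [LipidFeatureSet-class].
#' @export
LipidFeatureSet <- function(intensities, sampleIds, roles, origin = NULL,
                            resistance = NULL, featureNames = colnames(intensities),
                            annotate = TRUE) {
  intensities <- as.matrix(intensities)
  n <- nrow(intensities)
  if (length(sampleIds) != n || length(roles) != n)
    stop("sampleIds and roles must match the number of injections")
  if (is.null(featureNames))
    stop("feature names are required")
  if (is.null(origin)) origin <- rep(NA_character_, n)
  if (is.null(resistance)) resistance <- rep(NA_character_, n)
  cd <- S4Vectors::DataFrame(role = as.character(roles),
                             origin = as.character(origin),
                             resistance = as.character(resistance),
                             row.names = sampleIds)
  m <- t(intensities)                       # store features x samples
  dimnames(m) <- list(featureNames, sampleIds)
  rd <- if (annotate) annotateLipids(featureNames) else
    S4Vectors::DataFrame(row.names = featureNames)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = m), colData = cd, rowData = rd)
  methods::new("LipidFeatureSet", se)
}

#' Intensity matrix in injection-major orientation
#'
#' @param x A [LipidFeatureSet-class].
#' @return numeric matrix, rows = injections, columns = features.
#' @export
intensityMatrix <- function(x) t(SummarizedExperiment::assay(x, "intensity"))

#' Per-injection sample roles
#' @param x A [LipidFeatureSet-class].
#' @return character vector.
#' @export
sampleRoles <- function(x) as.character(SummarizedExperiment::colData(x)$role)

#' Design factors of the biological samples
#'
#' @param x A [LipidFeatureSet-class].
#' @param biologicalOnly drop qc/blank rows (default `TRUE`).
#' @return data.frame with columns `origin`, `resistance`.
#' @export
designFactors <- function(x, biologicalOnly = TRUE) {
  cd <- SummarizedExperiment::colData(x)
  d <- data.frame(origin = as.character(cd$origin),
                  resistance = as.character(cd$resistance),
                  row.names = rownames(cd), stringsAsFactors = FALSE)
  if (biologicalOnly) d <- d[sampleRoles(x) == "biological", , drop = FALSE]
  d
}

#' Subset to biological injections
#' @param x A [LipidFeatureSet-class].
#' @return A [LipidFeatureSet-class] with only biological columns.
#' @export
biologicalSamples <- function(x) x[, sampleRoles(x) == "biological"]

#' @describeIn EffectDecomposition-class named list of pure effect matrices.
#' @param object,x an `EffectDecomposition`.
#' @export
effectMatrices <- function(x) x@effectMatrices

#' @describeIn EffectDecomposition-class sum-of-squares shares per term.
#' @export
ssShares <- function(x) x@ssShares

#' Reconstruct the decomposed matrix from its parts
#' @param x An [EffectDecomposition-class].
#' @return samples x features matrix.
#' @export
reconstruct <- function(x) {
  out <- matrix(x@grandMean, nrow = nrow(x@residuals),
                ncol = length(x@grandMean), byrow = TRUE)
  for (m in x@effectMatrices) out <- out + m
  out + x@residuals
}

#' @describeIn AmoplsModel-class predictive scores (samples x components).
#' @param x an `AmoplsModel`.
#' @export
predictiveScores <- function(x) x@scoresPred

#' @describeIn AmoplsModel-class orthogonal scores.
#' @export
orthogonalScores <- function(x) x@scoresOrth

#' @describeIn AmoplsModel-class block-contribution matrix (rows sum to 1).
#' @export
blockContributions <- function(x) x@lambda

#' @describeIn AmoplsModel-class per-component share of total data variance.
#' @export
componentVariance <- function(x) x@compVar

#' @describeIn AmoplsModel-class effect attribution of each predictive
#'   component (block with the largest contribution).
#' @export
effectAttribution <- function(x) x@attribution

setMethod("show", "LipidFeatureSet", function(object) {
  roles <- sampleRoles(object)
  cat(sprintf("LipidFeatureSet: %d features x %d injections (%d biological, %d QC, %d blank)\n",
              nrow(object), ncol(object), sum(roles == "biological"),
              sum(roles == "qc"), sum(roles == "blank")))
  d <- designFactors(object)
  if (nrow(d))
    cat(sprintf("design: origin {%s} x resistance {%s}\n",
                paste(sort(unique(d$origin)), collapse = ", "),
                paste(sort(unique(d$resistance)), collapse = ", ")))
  invisible(NULL)
})

setMethod("show", "EffectDecomposition", function(object) {
  cat(sprintf("EffectDecomposition: %d samples x %d features\n",
              nrow(object@residuals), ncol(object@residuals)))
  sh <- object@ssShares
  cat("sum-of-squares shares (%):\n")
  print(round(100 * sh, 2))
  invisible(NULL)
})

setMethod("show", "AmoplsModel", function(object) {
  cat(sprintf("AmoplsModel: %d predictive + %d orthogonal component(s), R2Y = %.4f\n",
              object@nPred, object@nOrth, object@r2y))
  cat("component variance (%) and attribution:\n")
  df <- data.frame(variance = round(100 * object@compVar, 2),
                   attribution = c(object@attribution,
                                   rep("orthogonal", object@nOrth)))
  print(df)
  invisible(NULL)
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf("PermutationResult[%s]: observed = %.4g, p = %.4g (%d permutations)\n",
              object@effect, object@observed, object@pValue, object@nPerm))
  invisible(NULL)
})

setMethod("show", "FilterReport", function(object) {
  cat(sprintf("FilterReport: %d -> %d features\n", object@nInput, object@nRetained))
  for (r in names(object@removed))
    cat(sprintf("  failing %-12s: %d\n", r, length(object@removed[[r]])))
  invisible(NULL)
})
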