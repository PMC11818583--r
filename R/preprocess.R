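#' Feature-quality filtering of a lipidomics feature table
#'
#' Applies the four quality rules commonly used on pooled-QC-anchored
#' untargeted runs, each evaluated on the raw (pre-normalization) table:
#'
#' * (a) *missingness vs blank*: a biological cell counts as missing when it
#'   is absent or at most `blankMult` times the feature's mean blank signal;
#'   the feature is dropped when the missing fraction across biological
#'   samples exceeds `missingFrac`. Features with no blank signal use
#'   absolute missingness only.
#' * (b) *QC intensity*: mean intensity over QC injections below `qcMinMean`.
#' * (c) *QC repeatability*: coefficient of variation (sd/mean, `n - 1`
#'   denominator) over QC injections above `qcMaxCv`.
#' * (d) *zero spread*: interquartile range over biological samples equal to
#'   0 (linear-interpolation quartiles on present values).
#'
#' Removal is by the union of the four rule sets; the report additionally
#' attributes each removed feature to its first failing rule in the order
#' (a)(b)(c)(d). Retained features keep their original order. Missingness
#' is assessed across biological samples only (QCs are pooled copies of the
#' samples and blanks carry no biology).
#'
#' @param x A [LipidFeatureSet-class] with at least one QC row and, unless
#'   `requireBlank = FALSE`, at least one blank row.
#' @param missingFrac maximum tolerated missing fraction (default 0.75).
#' @param blankMult blank multiplier defining detection (default 5).
#' @param qcMinMean minimum mean QC intensity (default 1e5).
#' @param qcMaxCv maximum QC CV (default 0.40).
#' @param requireBlank with `FALSE`, the blank-threshold part of rule (a) is
#'   disabled and blank-free tables are accepted.
#' @return list with elements `table` (filtered [LipidFeatureSet-class]) and
#'   `report` ([FilterReport-class]).
#' @export
filterFeatures <- function(x, missingFrac = 0.75, blankMult = 5,
                           qcMinMean = 1e5, qcMaxCv = 0.40,
                           requireBlank = TRUE) {
  roles <- sampleRoles(x)
  if (!any(roles == "qc"))
    stop("no QC rows: QC-dependent filter rules cannot be evaluated")
  if (requireBlank && !any(roles == "blank"))
    stop("no blank rows: set requireBlank = FALSE to disable the blank rule")
  m <- intensityMatrix(x)
  bio <- m[roles == "biological", , drop = FALSE]
  qc <- m[roles == "qc", , drop = FALSE]

  if (requireBlank && any(roles == "blank")) {
    blank <- m[roles == "blank", , drop = FALSE]
    blankMean <- colMeans(blank, na.rm = TRUE)
    blankMean[is.nan(blankMean)] <- 0
  } else blankMean <- rep(0, ncol(m))

  thr <- blankMult * blankMean
  missing <- is.na(bio) | sweep(bio, 2, thr, "<=")
  missing[is.na(missing)] <- TRUE
  missRate <- colMeans(missing)

  qcMean <- apply(qc, 2, function(v) if (all(is.na(v))) 0 else mean(v, na.rm = TRUE))
  qcCv <- vapply(seq_len(ncol(qc)), function(j) {
    v <- qc[, j]; v <- v[!is.na(v)]
    if (length(v) < 2 || mean(v) == 0) Inf else sd(v) / mean(v)
  }, 0)
  iqr <- vapply(seq_len(ncol(bio)), function(j) {
    v <- bio[, j]; v <- v[!is.na(v)]
    if (!length(v)) 0 else diff(quantile(v, c(0.25, 0.75), names = FALSE, type = 7))
  }, 0)

  feats <- rownames(x)
  fails <- list(missingness = missRate > missingFrac,
                qc_intensity = qcMean < qcMinMean,
                qc_cv = qcCv > qcMaxCv,
                iqr = iqr == 0)
  removed <- lapply(fails, function(f) feats[f])
  failM <- do.call(cbind, fails)
  dropped <- rowSums(failM) > 0
  firstRule <- apply(failM[dropped, , drop = FALSE], 1,
                     function(f) names(fails)[which(f)[1]])
  firstFailing <- setNames(as.character(firstRule), feats[dropped])

  report <- methods::new("FilterReport",
    nInput = nrow(x), nRetained = as.integer(sum(!dropped)),
    removed = removed, firstFailing = firstFailing,
    thresholds = c(missing_frac = missingFrac, blank_mult = blankMult,
                   qc_min_mean = qcMinMean, qc_max_cv = qcMaxCv))
  list(table = x[!dropped, ], report = report)
}

#' Probabilistic quotient normalization against the median QC spectrum
#'
#' The reference spectrum is the per-feature median over QC injections.
#' Each injection's dilution factor is the median of the quotients of its
#' present intensities to the reference (features whose reference value is
#' missing or non-positive are excluded); the corrected row is the raw row
#' divided by its factor. QC and blank rows are corrected the same way.
#'
#' @param x A [LipidFeatureSet-class] with at least one QC row; the
#'   reference must be strictly positive for at least `minQuotients`
#'   features.
#' @param minQuotients minimum number of evaluable quotients per row
#'   (default 10); a row below it raises an error naming the row.
#' @return list with elements `table` (corrected [LipidFeatureSet-class]),
#'   `dilutionFactors` (named per-injection positive reals) and
#'   `referenceSpectrum` (per-feature reals).
#' @export
pqnNormalize <- function(x, minQuotients = 10) {
  roles <- sampleRoles(x)
  if (!any(roles == "qc")) stop("PQN needs at least one QC row")
  m <- intensityMatrix(x)
  qc <- m[roles == "qc", , drop = FALSE]
  ref <- apply(qc, 2, function(v) if (all(is.na(v))) NA_real_ else
    median(v, na.rm = TRUE))
  usable <- !is.na(ref) & ref > 0
  if (sum(usable) < minQuotients)
    stop("reference spectrum positive for fewer than ", minQuotients, " features")

  factors <- vapply(seq_len(nrow(m)), function(i) {
    q <- m[i, usable] / ref[usable]
    q <- q[!is.na(q)]
    if (length(q) < minQuotients)
      stop("sample '", rownames(m)[i], "' has fewer than ", minQuotients,
           " evaluable quotients")
    median(q)
  }, 0)
  names(factors) <- rownames(m)

  corrected <- m / factors
  out <- x
  SummarizedExperiment::assay(out, "intensity") <- t(corrected)
  list(table = out, dilutionFactors = factors, referenceSpectrum = ref)
}

#' Impute residual missing values
#'
#' `method = "half_min"` replaces each missing cell with half the feature's
#' minimum observed biological intensity; `method = "none"` asserts that no
#' missing cells remain.
#'
#' @param x A filtered [LipidFeatureSet-class].
#' @param method `"half_min"` or `"none"`.
#' @return A [LipidFeatureSet-class] without missing cells.
#' @export
imputeMissing <- function(x, method = c("half_min", "none")) {
  method <- match.arg(method)
  m <- intensityMatrix(x)
  if (method == "none") {
    if (anyNA(m)) stop("missing cells remain with method = 'none'")
    return(x)
  }
  roles <- sampleRoles(x)
  bio <- m[roles == "biological", , drop = FALSE]
  for (j in seq_len(ncol(m))) {
    if (!anyNA(m[, j])) next
    v <- bio[, j]; v <- v[!is.na(v)]
    if (!length(v))
      stop("feature '", colnames(m)[j], "' entirely missing in biological samples")
    m[is.na(m[, j]), j] <- min(v) / 2
  }
  out <- x
  SummarizedExperiment::assay(out, "intensity") <- t(m)
  out
}

#' Unit-variance scale a matrix column-wise
#'
#' Centers each column to mean 0 and divides by its standard deviation
#' (`n - 1` denominator), returning the parameters needed to back-transform
#' loadings to the original intensity scale.
#'
#' @param m numeric matrix over biological rows, no missing values.
#' @return list with elements `scaled`, `center`, `scale`.
#' @export
uvScale <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("uvScale expects a complete matrix; impute first")
  ctr <- colMeans(m)
  sds <- apply(m, 2, sd)
  zero <- sds == 0
  if (any(zero))
    stop("zero-variance feature(s): ",
         paste(colnames(m)[zero], collapse = ", "))
  scaled <- sweep(sweep(m, 2, ctr), 2, sds, "/")
  list(scaled = scaled, center = ctr, scale = sds)
}

#' Invert unit-variance scaling
#'
#' @param scaled matrix produced by [uvScale()].
#' @param center,scale the parameters returned by [uvScale()].
#' @return matrix on the original scale.
#' @export
uvUnscale <- function(scaled, center, scale) {
  sweep(sweep(scaled, 2, scale, "*"), 2, center, "+")
}
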