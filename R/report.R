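.groupMeansByFactor <- function(x) {
  m <- intensityMatrix(biologicalSamples(x))
  d <- designFactors(x)
  grp <- paste(d$origin, d$resistance, sep = ".")
  means <- rowsum(m, grp, na.rm = TRUE) /
    rowsum((!is.na(m)) * 1, grp)
  list(means = means,
       origin = sub("\\..*$", "", rownames(means)),
       resistance = sub("^.*\\.", "", rownames(means)))
}

#' Normalized lipid class composition per design group
#'
#' For each (origin, resistance) group: the mean intensity of every feature
#' over its replicates, summed within lipid class and divided by the
#' group's total, so shares sum to 1 per group. Features whose name did not
#' parse are pooled under class `"other"`.
#'
#' @param x a normalized [LipidFeatureSet-class].
#' @return data.frame with columns `origin`, `resistance`, `lipid_class`,
#'   `share`.
#' @export
classComposition <- function(x) {
  gm <- .groupMeansByFactor(x)
  rd <- SummarizedExperiment::rowData(x)
  cls <- ifelse(rd$parsed, rd$lipid_class, "other")
  if (any(is.na(gm$means)))
    stop("empty group/feature combination: no observed intensities")
  out <- do.call(rbind, lapply(seq_len(nrow(gm$means)), function(i) {
    tot <- tapply(gm$means[i, ], cls, sum)
    data.frame(origin = gm$origin[i], resistance = gm$resistance[i],
               lipid_class = names(tot),
               share = as.numeric(tot) / sum(tot), row.names = NULL)
  }))
  out
}

#' Resistant-vs-naive log2 fold changes per origin
#'
#' `log2(mean resistant / mean naive)` on normalized intensities, per
#' origin, at species level or aggregated to class-summed means. A
#' non-positive group mean yields `NA` with the reason recorded in the
#' `flag` column rather than an infinite value.
#'
#' @param x a normalized [LipidFeatureSet-class] (PQN-corrected).
#' @param level `"species"` or `"class"`.
#' @return data.frame with columns `feature` (species or class), `origin`,
#'   `log2fc`, `flag`.
#' @export
log2FoldChange <- function(x, level = c("species", "class")) {
  level <- match.arg(level)
  gm <- .groupMeansByFactor(x)
  origins <- unique(gm$origin)
  for (o in origins)
    if (!all(c("naive", "resistant") %in% gm$resistance[gm$origin == o]))
      stop("origin '", o, "' lacks one of the resistance levels")
  m <- gm$means
  if (level == "class") {
    rd <- SummarizedExperiment::rowData(x)
    cls <- ifelse(rd$parsed, rd$lipid_class, "other")
    m <- t(rowsum(t(m), cls))
  }
  out <- do.call(rbind, lapply(origins, function(o) {
    num <- m[gm$origin == o & gm$resistance == "resistant", , drop = TRUE]
    den <- m[gm$origin == o & gm$resistance == "naive", , drop = TRUE]
    bad <- !is.finite(num) | !is.finite(den) | num <= 0 | den <= 0
    data.frame(feature = colnames(m), origin = o,
               log2fc = ifelse(bad, NA_real_, log2(num / den)),
               flag = ifelse(bad, "non-positive group mean", ""),
               row.names = NULL)
  }))
  out
}

#' Chain-length shift table for one lipid class
#'
#' Labels each species of a class as long- or short-chain from its acyl
#' carbon count and reports the per-origin direction of the
#' resistant-vs-naive log2 fold change. For sphingolipid classes the acyl
#' count subtracts the sphingoid backbone (d18 assumed, configurable);
#' glycerolipid classes use total carbons as-is.
#'
#' @param x a normalized [LipidFeatureSet-class].
#' @param classFilter lipid class to tabulate (e.g. `"SM"`).
#' @param acylThreshold species with `acyl_carbons >= acylThreshold` are
#'   labelled `"long"` (default 18).
#' @param sphingoidCarbons backbone carbons subtracted for sphingolipid
#'   classes (default 18).
#' @return data.frame with columns `species`, `acyl_carbons`, `length`,
#'   `origin`, `direction` (sign of the log2 fold change). Empty, with a
#'   warning, when the class is absent.
#' @export
chainLengthShift <- function(x, classFilter, acylThreshold = 18L,
                             sphingoidCarbons = 18L) {
  rd <- SummarizedExperiment::rowData(x)
  keep <- rd$parsed & rd$lipid_class == classFilter
  if (!any(keep)) {
    warning("class '", classFilter, "' absent from the table")
    return(data.frame(species = character(), acyl_carbons = integer(),
                      length = character(), origin = character(),
                      direction = numeric()))
  }
  sub <- x[keep, ]
  rds <- SummarizedExperiment::rowData(sub)
  acyl <- rds$total_carbons -
    if (.isSphingo(classFilter)) sphingoidCarbons else 0L
  fc <- log2FoldChange(sub, level = "species")
  lab <- setNames(ifelse(acyl >= acylThreshold, "long", "short"),
                  rownames(sub))
  ac <- setNames(acyl, rownames(sub))
  data.frame(species = fc$feature,
             acyl_carbons = as.integer(ac[fc$feature]),
             length = lab[fc$feature],
             origin = fc$origin,
             direction = sign(fc$log2fc), row.names = NULL)
}
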