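.sniffSep <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

#' Read a feature table and its sample metadata
#'
#' Reads an MS-DIAL-alignment-style export: a delimited text file
#' (comma or tab, sniffed from the header) whose first column holds sample
#' ids and remaining columns hold lipid features, one injection per row,
#' plus a metadata file with columns `sample_id`, `role`, `origin`,
#' `resistance`. Metadata rows are matched to feature-table rows by sample
#' id; every id must be present in both files.
#'
#' Missing cells may be encoded as empty fields, `NA`, or — because MS-DIAL
#' exports write 0 for non-detected peaks — literal 0 when
#' `zeroIsMissing = TRUE` (the default). A table that looks transposed
#' (sample-id column populated by parseable lipid names while the column
#' headers are not) is rejected rather than silently flipped.
#'
#' @param featuresPath,metadataPath paths to delimited text files.
#' @param zeroIsMissing treat literal 0 as a missing cell.
#' @return A [LipidFeatureSet-class].
#' @export
readFeatureTable <- function(featuresPath, metadataPath, zeroIsMissing = TRUE) {
  for (p in c(featuresPath, metadataPath))
    if (!file.exists(p)) stop("file not found: ", p)
  feat <- read.delim(featuresPath, sep = .sniffSep(featuresPath),
                     check.names = FALSE, stringsAsFactors = FALSE,
                     na.strings = c("", "NA"))
  meta <- read.delim(metadataPath, sep = .sniffSep(metadataPath),
                     check.names = FALSE, stringsAsFactors = FALSE,
                     na.strings = c("", "NA"))
  need <- c("sample_id", "role", "origin", "resistance")
  if (!all(need %in% colnames(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))

  ids <- as.character(feat[[1]])
  featNames <- colnames(feat)[-1]
  dup <- unique(featNames[duplicated(featNames)])
  if (length(dup))
    stop("duplicate feature names: ", paste(dup, collapse = ", "))

  # transposed-orientation heuristic: ids parse as lipid names, headers do not
  idParses <- mean(vapply(ids, function(s) parseLipidName(s)$parsed, TRUE))
  colParses <- mean(vapply(featNames, function(s) parseLipidName(s)$parsed, TRUE))
  if (idParses > 0.5 && colParses <= 0.5)
    stop("feature table appears transposed (rows look like lipid features); ",
         "expected rows = injections, columns = features")

  missingIds <- setdiff(ids, meta$sample_id)
  extraIds <- setdiff(meta$sample_id, ids)
  if (length(missingIds) || length(extraIds))
    stop("sample ids mismatch between feature table and metadata; ",
         if (length(missingIds))
           paste0("absent from metadata: ", paste(missingIds, collapse = ", "), "; "),
         if (length(extraIds))
           paste0("absent from feature table: ", paste(extraIds, collapse = ", ")))
  meta <- meta[match(ids, meta$sample_id), ]

  x <- as.matrix(feat[, -1, drop = FALSE])
  storage.mode(x) <- "double"
  if (zeroIsMissing) x[!is.na(x) & x == 0] <- NA_real_

  LipidFeatureSet(x, sampleIds = ids, roles = meta$role,
                  origin = meta$origin, resistance = meta$resistance,
                  featureNames = featNames)
}

#' Write a feature table and metadata back to delimited text
#'
#' Inverse of [readFeatureTable()]: missing cells are written as empty
#' fields so a round trip preserves missingness exactly.
#'
#' @param x A [LipidFeatureSet-class].
#' @param featuresPath,metadataPath output paths (CSV).
#' @return invisibly, the two paths.
#' @export
writeFeatureTable <- function(x, featuresPath, metadataPath) {
  m <- intensityMatrix(x)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.csv(df, featuresPath, row.names = FALSE, na = "")
  cd <- SummarizedExperiment::colData(x)
  meta <- data.frame(sample_id = rownames(cd), role = cd$role,
                     origin = cd$origin, resistance = cd$resistance)
  write.csv(meta, metadataPath, row.names = FALSE, na = "")
  invisible(c(featuresPath, metadataPath))
}

.writeTable <- function(df, path) {
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE, na = "")
  path
}

.matrixToDf <- function(m, keyName = "id") {
  data.frame(setNames(list(rownames(m)), keyName), m, check.names = FALSE)
}

#' Write the pipeline's result tables
#'
#' Writes comma-delimited tables (full float precision, one header row) for
#' every section present in the result bundle: filter report, effect
#' proportions, scores, loadings, block contributions, permutation
#' p-values, class compositions and fold changes. Absent optional sections
#' (e.g. no permutations were run) are omitted from the manifest.
#'
#' @param results named list with any of the elements `filterReport`
#'   ([FilterReport-class]), `decomposition` ([EffectDecomposition-class]),
#'   `model` ([AmoplsModel-class]), `permutations` (list of
#'   [PermutationResult-class]), `classComposition` (data.frame),
#'   `foldChanges` (data.frame).
#' @param outDir output directory, created if needed.
#' @return character vector of written file paths (the manifest).
#' @export
writeResults <- function(results, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outDir, 2) != 0) stop("output directory not writable: ", outDir)
  manifest <- character()
  add <- function(p) manifest <<- c(manifest, p)

  fr <- results$filterReport
  if (!is.null(fr)) {
    feats <- names(fr@firstFailing)
    df <- data.frame(feature = feats,
                     first_failing_rule = unname(fr@firstFailing))
    attr(df, "header") <- NULL
    add(.writeTable(df, file.path(outDir, "filter_report.csv")))
  }
  dec <- results$decomposition
  if (!is.null(dec)) {
    add(.writeTable(data.frame(effect = names(ssShares(dec)),
                               percent = 100 * unname(ssShares(dec))),
                    file.path(outDir, "effect_proportions.csv")))
  }
  mod <- results$model
  if (!is.null(mod)) {
    sc <- cbind(predictiveScores(mod), orthogonalScores(mod))
    add(.writeTable(.matrixToDf(sc, "sample_id"),
                    file.path(outDir, "scores.csv")))
    ld <- cbind(mod@loadingsPred, mod@loadingsOrth)
    add(.writeTable(.matrixToDf(ld, "feature"),
                    file.path(outDir, "loadings.csv")))
    add(.writeTable(.matrixToDf(blockContributions(mod), "component"),
                    file.path(outDir, "block_contributions.csv")))
  }
  perms <- results$permutations
  if (!is.null(perms) && length(perms)) {
    df <- do.call(rbind, lapply(perms, function(p)
      data.frame(effect = p@effect, observed_stat = p@observed,
                 p_value = p@pValue, n_perm = p@nPerm, seed = p@seed)))
    add(.writeTable(df, file.path(outDir, "permutation_pvalues.csv")))
  }
  if (!is.null(results$classComposition))
    add(.writeTable(results$classComposition,
                    file.path(outDir, "class_composition.csv")))
  if (!is.null(results$foldChanges))
    add(.writeTable(results$foldChanges,
                    file.path(outDir, "log2_fold_changes.csv")))
  manifest
}
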