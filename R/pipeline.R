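#' Assemble a pipeline configuration
#'
#' Flat key-value configuration for [runPipeline()]. Defaults are the
#' package's standard operating values: 75% missingness against 5x blank,
#' QC mean >= 1e5, QC CV <= 40%, zero-IQR removal, PQN, half-minimum
#' imputation, unit-variance scaling, 7 predictive components, automatic
#' orthogonal-component selection, 1000 permutations.
#'
#' @param featuresPath,metadataPath input files for [readFeatureTable()];
#'   alternatively give `simulate` a `SimConfig` to generate the input.
#' @param simulate optional `SimConfig`.
#' @param outDir output directory.
#' @param missingFrac,blankMult,qcMinMean,qcMaxCv filter thresholds.
#' @param imputeMethod `"half_min"` or `"none"`.
#' @param zeroIsMissing treat literal 0 in input files as missing.
#' @param nPred predictive components (`NULL` = rank of the response).
#' @param nOrth number of orthogonal components, or `"auto"`.
#' @param nPerm permutations for significance and auto-selection.
#' @param seed integer.
#' @param allowList optional character vector of feature names to keep
#'   before filtering (stands in for manual analytical curation).
#' @return named list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(featuresPath = NULL, metadataPath = NULL,
                           simulate = NULL, outDir = tempfile("amopls_run_"),
                           missingFrac = 0.75, blankMult = 5,
                           qcMinMean = 1e5, qcMaxCv = 0.40,
                           imputeMethod = "half_min", zeroIsMissing = TRUE,
                           nPred = NULL, nOrth = "auto", nPerm = 1000L,
                           seed = 1L, allowList = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the full analysis pipeline
#'
#' Read (or simulate) -> quality filter -> PQN -> impute -> unit-variance
#' scale -> ANOVA effect decomposition -> AMOPLS fit (with permutation
#' selection of the orthogonal dimension when `nOrth = "auto"`) ->
#' per-effect permutation significance -> class composition and fold-change
#' reports, with every table written to `cfg$outDir` along with a run log
#' and the configuration echo. Any stage failure aborts with the stage
#' name.
#'
#' @param cfg A `PipelineConfig` from [pipelineConfig()].
#' @return list with the in-memory results (`table`, `filterReport`,
#'   `normalization`, `decomposition`, `model`, `nOrth`, `permutations`,
#'   `classComposition`, `foldChanges`) plus `manifest`, the vector of
#'   files written.
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  logLines <- character()
  note <- function(...) {
    line <- sprintf(...)
    logLines <<- c(logLines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  note("lipidAMOPLS %s | seed %d", as.character(utils::packageVersion("lipidAMOPLS")),
       cfg$seed)

  x <- stage("read", {
    if (!is.null(cfg$simulate)) simulateLipidData(cfg$simulate)$table
    else readFeatureTable(cfg$featuresPath, cfg$metadataPath,
                          zeroIsMissing = cfg$zeroIsMissing)
  })
  note("input: %d features x %d injections", nrow(x), ncol(x))
  if (!is.null(cfg$allowList)) {
    x <- x[rownames(x) %in% cfg$allowList, ]
    note("allow-list: %d features kept", nrow(x))
  }

  fl <- stage("filter", filterFeatures(x, missingFrac = cfg$missingFrac,
                                       blankMult = cfg$blankMult,
                                       qcMinMean = cfg$qcMinMean,
                                       qcMaxCv = cfg$qcMaxCv))
  note("filter: %d -> %d features", fl$report@nInput, fl$report@nRetained)

  norm <- stage("pqn", pqnNormalize(fl$table))
  note("pqn: dilution factors in [%.3f, %.3f]",
       min(norm$dilutionFactors), max(norm$dilutionFactors))

  imp <- stage("impute", imputeMissing(norm$table, method = cfg$imputeMethod))
  bio <- biologicalSamples(imp)
  factors <- designFactors(imp)
  sc <- stage("scale", uvScale(intensityMatrix(bio)))
  note("scale: %d biological samples x %d features",
       nrow(sc$scaled), ncol(sc$scaled))

  dec <- stage("decompose", decomposeEffects(sc$scaled, factors))
  note("effect shares (%%): %s",
       paste(sprintf("%s %.1f", names(ssShares(dec)), 100 * ssShares(dec)),
             collapse = ", "))

  nOrth <- cfg$nOrth
  if (identical(nOrth, "auto")) {
    nOrth <- stage("select_orthogonal",
                   selectNOrthogonal(sc$scaled, factors, nPerm = cfg$nPerm,
                                     seed = cfg$seed, nPred = cfg$nPred))
    note("orthogonal components selected by permutation: %d", nOrth)
  }
  model <- stage("fit", fitAmopls(dec, nPred = cfg$nPred,
                                  nOrth = as.integer(nOrth)))
  note("model: R2Y = %.4f; component variance (%%): %s", model@r2y,
       paste(sprintf("%s %.1f", names(componentVariance(model)),
                     100 * componentVariance(model)), collapse = ", "))

  perms <- stage("permute", lapply(c("origin", "resistance", "interaction"),
    function(e) effectSignificance(sc$scaled, factors, e, nPerm = cfg$nPerm,
                                   seed = cfg$seed, nPred = cfg$nPred,
                                   nOrth = as.integer(nOrth))))
  for (pr in perms) note("permutation p[%s] = %.4g", pr@effect, pr@pValue)

  comp <- stage("report", classComposition(imp))
  fc <- stage("report", log2FoldChange(imp, level = "species"))

  manifest <- stage("write", writeResults(
    list(filterReport = fl$report, decomposition = dec, model = model,
         permutations = perms, classComposition = comp, foldChanges = fc),
    cfg$outDir))

  cfgPath <- file.path(cfg$outDir, "config.txt")
  dump <- cfg[!vapply(cfg, is.null, TRUE)]
  dump$simulate <- if (!is.null(cfg$simulate)) "SimConfig (see truth/seed)" else NULL
  writeLines(paste(names(dump),
                   vapply(dump, function(v) paste(format(v), collapse = " "), ""),
                   sep = " = "), cfgPath)
  logPath <- file.path(cfg$outDir, "run_log.txt")
  writeLines(logLines, logPath)
  manifest <- c(manifest, cfgPath, logPath)

  list(table = x, filterReport = fl$report, normalization = norm,
       decomposition = dec, model = model, nOrth = as.integer(nOrth),
       permutations = perms, classComposition = comp, foldChanges = fc,
       manifest = manifest)
}
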