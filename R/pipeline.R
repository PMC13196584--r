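## End-to-end orchestrator: load or simulate a bundle, run the distance-
## based tests, CAT computation, CSR assignment, DistLM/dbRDA and the
## SparCC network, and emit a tabular report with a full run log.

#' Pipeline configuration
#'
#' @param input either a [csrSimConfig()] (synthetic mode) or a directory
#'   path readable by [readBundle()].
#' @param mode `"mag"` (coverage-derived genome tables, no rarefaction) or
#'   `"amplicon"` (integer counts rarefied to `rarefactionDepth` before
#'   relative-abundance transformation).
#' @param seed master seed; fans out deterministically to every stochastic
#'   stage.
#' @param rarefactionDepth rarefaction depth for amplicon mode (default
#'   5089 reads per sample).
#' @param nPerm permutations for PERMANOVA/PERMDISP and the enrichment test
#'   (default 9999).
#' @param alpha BH FDR level for strategy assignment (default 0.05).
#' @param rMin network edge threshold (default 0.20).
#' @param zscoreBy `"level"` (Z-score CAT level means; default) or
#'   `"sample"`.
#' @param sparccResample,sparccExclusionIterations,sparccExclusionThreshold
#'   SparCC parameters.
#' @param outputDir optional directory; when given, all report tables, the
#'   network exports and the run log are written there.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(input = csrSimConfig(), mode = c("mag", "amplicon"),
                           seed = 1L, rarefactionDepth = 5089L,
                           nPerm = 9999L, alpha = 0.05, rMin = 0.20,
                           zscoreBy = c("level", "sample"),
                           sparccResample = 20L,
                           sparccExclusionIterations = 10L,
                           sparccExclusionThreshold = 0.1,
                           outputDir = NULL) {
  cfg <- list(input = input, mode = match.arg(mode), seed = as.integer(seed),
              rarefactionDepth = as.integer(rarefactionDepth),
              nPerm = as.integer(nPerm), alpha = alpha, rMin = rMin,
              zscoreBy = match.arg(zscoreBy),
              sparccResample = as.integer(sparccResample),
              sparccExclusionIterations = as.integer(sparccExclusionIterations),
              sparccExclusionThreshold = sparccExclusionThreshold,
              outputDir = outputDir)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the full CSR analysis pipeline
#'
#' Stages: load/generate -> (amplicon mode only) rarefaction -> relative
#' abundance + square-root Bray-Curtis -> PERMANOVA + PERMDISP + CAP ->
#' CATs -> level Z-scores -> CSR assignment of genomes and traits (with
#' Venn accounting) -> genome-size Welch ANOVA across assigned strategies
#' -> DistLM (AICc stepwise) + dbRDA on CAT predictors with correlation
#' overlays -> SparCC network + Louvain modules + regime dominance. Any
#' stage failure aborts with the stage name; a fixed config and seed yield
#' byte-identical outputs.
#'
#' @param config a [pipelineConfig()].
#' @return list of class `CsrPipelineReport` with elements `experiment`,
#'   `distance`, `permanova`, `permdisp`, `cap`, `similarityClusters`,
#'   `cats`, `zscores`, `csr` (genome/trait assignments + venn),
#'   `genomeSizeAnova`, `distlm`, `dbrda`, `overlay`, `network`
#'   (`correlations`, `graph`, `modules`, `regimeMap`), and `log`.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  log_ <- character()
  noteLog <- function(...) log_ <<- c(log_, paste0(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  noteLog("csrtraits pipeline; master seed ", config$seed,
          "; nPerm ", config$nPerm, "; alpha ", config$alpha,
          "; rMin ", config$rMin, "; mode ", config$mode)

  se <- stage("load", {
    if (inherits(config$input, "CsrSimConfig")) {
      simulateCsrExperiment(config$input)
    } else if (is(config$input, "CsrExperiment")) {
      config$input
    } else readBundle(config$input)
  })
  noteLog("loaded ", nrow(se), " genomes x ", ncol(se), " samples")

  counts <- assay(se, "counts")
  if (config$mode == "amplicon") {
    counts <- stage("rarefy", rarefyCounts(counts, config$rarefactionDepth,
                                           seed = childSeed(config$seed, 10L)))
    dropped <- attr(counts, "dropped")
    if (length(dropped)) noteLog("rarefaction dropped: ",
                                 paste(dropped, collapse = ", "))
    se <- se[, colnames(counts)]
    ## keep the rarefied counts for all downstream stages
    SummarizedExperiment::assay(se, "counts") <- counts
  }

  regimes <- as.character(sampleRegimes(se))
  lev <- colData(se)$level

  D <- stage("distance", sqrtBrayCurtis(t(assay(se, "counts"))))
  pmv <- stage("permanova",
               permanova(D, lev, nPerm = config$nPerm,
                         seed = childSeed(config$seed, 11L)))
  pdp <- stage("permdisp",
               permdisp(D, lev, nPerm = config$nPerm,
                        seed = childSeed(config$seed, 12L)))
  noteLog("PERMANOVA pseudo-F ", format(pmv$statistic, digits = 5),
          " p ", format(pmv$p, digits = 4),
          "; PERMDISP F ", format(pdp$statistic, digits = 5),
          " p ", format(pdp$p, digits = 4))
  cap <- stage("cap", capOrdination(D, lev))
  simClusters <- stage("clustering", upgmaClusters(D, threshold = 85))

  cats <- stage("cats", computeCATs(se))
  zs <- stage("zscores", zscoreLevelMeans(cats, lev))

  csr <- stage("csr_assign",
               classifyCsr(se, nSim = config$nPerm, alpha = config$alpha,
                           seed = childSeed(config$seed, 13L)))
  noteLog("genome labels: ",
          paste(names(csr$venn$regions), csr$venn$regions,
                sep = "=", collapse = " "))

  gsa <- stage("genome_size", {
    lab <- csr$genomes$label[match(rownames(se), csr$genomes$feature)]
    keep <- lab %in% c("C", "R", "S")
    sizes <- rowData(se)$genome_size[keep]
    grp <- lab[keep]
    ns <- table(grp)
    vs <- tapply(sizes, grp, var)
    if (length(ns) >= 2 && all(ns >= 2) && all(vs > 0, na.rm = TRUE))
      genomeSizeWelchAnova(sizes, grp)
    else NULL
  })

  dlm <- stage("distlm", distlmStepwise(D, cats))
  dbr <- stage("dbrda", {
    if (length(dlm$selected)) dbrda(D, dlm$predictors) else NULL
  })
  ovl <- stage("overlay", {
    if (!is.null(dbr))
      vectorOverlay(dbr$scores, cats[, dlm$selected, drop = FALSE],
                    rMin = config$rMin)
    else NULL
  })
  if (!is.null(dbr))
    noteLog("DistLM selected ", length(dlm$selected), " predictors, AICc ",
            format(dlm$aicc, digits = 6), ", R2 ",
            format(dlm$r2, digits = 4),
            "; dbRDA axis1 ", format(dbr$pctTotal[1], digits = 4),
            "% of total")

  net <- stage("network", {
    R <- sparccCorrelations(assay(se, "counts"),
                            nResample = config$sparccResample,
                            exclusionIterations = config$sparccExclusionIterations,
                            exclusionThreshold = config$sparccExclusionThreshold,
                            seed = childSeed(config$seed, 14L))
    gph <- buildNetwork(R, rMin = config$rMin, positiveOnly = TRUE)
    mods <- if (igraph::ecount(gph) > 0)
      louvainModules(gph, seed = childSeed(config$seed, 15L))
    else suppressWarnings(louvainModules(gph, seed = childSeed(config$seed, 15L)))
    regimeMap <- moduleRegimeAssociation(mods$membership, se)
    list(correlations = R, graph = gph, modules = mods,
         regimeMap = regimeMap)
  })
  noteLog("network: ", igraph::vcount(net$graph), " nodes, ",
          igraph::ecount(net$graph), " edges, Q ",
          format(net$modules$Q, digits = 4))

  report <- structure(
    list(experiment = se, distance = D, permanova = pmv, permdisp = pdp,
         cap = cap, similarityClusters = simClusters, cats = cats,
         zscores = zs, csr = csr, genomeSizeAnova = gsa, distlm = dlm,
         dbrda = dbr, overlay = ovl, network = net, log = log_,
         config = config),
    class = "CsrPipelineReport")
  if (!is.null(config$outputDir))
    writeReport(report, config$outputDir)
  report
}

#' Write a pipeline report as tab-separated tables
#'
#' Emits the distance matrix, ordination scores, Z-score table, assignment
#' and Venn tables, DistLM trace, network exports and the run log.
#'
#' @param report a `CsrPipelineReport` from [runPipeline()].
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
writeReport <- function(report, dir) {
  stopifnot(inherits(report, "CsrPipelineReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, file, rowLabel = NULL) {
    df <- as.data.frame(x, check.names = FALSE)
    if (!is.null(rowLabel)) {
      df <- cbind(setNames(data.frame(rownames(x)), rowLabel), df)
    }
    write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wt(report$distance, "distance_matrix.tsv", "sample_id")
  wt(report$cap$scores, "cap_scores.tsv", "sample_id")
  wt(report$cats, "cat_matrix.tsv", "sample_id")
  wt(report$zscores$z, "cat_zscores.tsv", "level")
  wt(report$csr$genomes, "genome_assignments.tsv")
  wt(report$csr$traits, "trait_assignments.tsv")
  wt(data.frame(region = names(report$csr$venn$regions),
                count = as.integer(report$csr$venn$regions)),
     "venn_regions.tsv")
  wt(report$distlm$trace, "distlm_trace.tsv")
  if (!is.null(report$dbrda)) {
    wt(report$dbrda$scores, "dbrda_scores.tsv", "sample_id")
    wt(data.frame(axis = seq_along(report$dbrda$eigenvalues),
                  eigenvalue = report$dbrda$eigenvalues,
                  pct_fitted = report$dbrda$pctFitted,
                  pct_total = report$dbrda$pctTotal),
       "dbrda_axes.tsv")
  }
  if (!is.null(report$overlay) && nrow(report$overlay))
    wt(report$overlay, "overlay_vectors.tsv")
  tests <- data.frame(
    test = c("PERMANOVA", "PERMDISP"),
    statistic = c(report$permanova$statistic, report$permdisp$statistic),
    p = c(report$permanova$p, report$permdisp$p),
    n_perm = c(report$permanova$nPerm, report$permdisp$nPerm))
  wt(tests, "multivariate_tests.tsv")
  exportNetwork(report$network$graph, file.path(dir, "network"),
                membership = report$network$modules$membership,
                seed = childSeed(report$config$seed, 16L))
  wt(report$network$regimeMap, "module_regimes.tsv")
  writeBundle(report$experiment, file.path(dir, "bundle"))
  writeLines(report$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.CsrPipelineReport <- function(x, ...) {
  cat("CsrPipelineReport\n")
  cat(" ", paste(x$log, collapse = "\n  "), "\n")
  invisible(x)
}
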