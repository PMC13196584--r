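#' Construct a CsrExperiment
#'
#' @param counts numeric matrix, genomes x samples (counts or relative
#'   abundances, non-negative).
#' @param traitCounts numeric matrix, genomes x COG categories (gene counts).
#' @param design a [DisturbanceDesign-class].
#' @param sampleData `data.frame`/`DataFrame` with one row per sample;
#'   must contain `level`, `regime`, `replicate`.
#' @param genomeData optional `data.frame`/`DataFrame`, one row per genome
#'   (genome size, completeness, contamination, taxonomy, ...).
#' @param metadata list of free-form metadata (planted truth, seeds, ...).
#'
#' @return A [CsrExperiment-class] object.
#' @seealso [simulateCsrExperiment()] for synthetic construction.
#' @export
CsrExperiment <- function(counts, traitCounts, design, sampleData,
                          genomeData = NULL, metadata = list()) {
  counts <- as.matrix(counts)
  traitCounts <- as.matrix(traitCounts)
  if (is.null(genomeData))
    genomeData <- DataFrame(row.names = rownames(counts))
  se <- SummarizedExperiment(assays = list(counts = counts),
                             rowData = genomeData,
                             colData = DataFrame(sampleData,
                                                 row.names = sampleData$sample_id),
                             metadata = metadata)
  new("CsrExperiment", se, traitCounts = traitCounts, design = design)
}

#' @describeIn CsrExperiment Genome x category trait count matrix.
#' @param object a `CsrExperiment`.
#' @export
setGeneric("traitCounts", function(object) standardGeneric("traitCounts"))

#' @rdname CsrExperiment
#' @export
setMethod("traitCounts", "CsrExperiment", function(object) object@traitCounts)

#' @rdname CsrExperiment
#' @export
setGeneric("experimentDesign",
           function(object) standardGeneric("experimentDesign"))

#' @rdname CsrExperiment
#' @export
setMethod("experimentDesign", "CsrExperiment", function(object) object@design)

#' @rdname CsrExperiment
#' @export
setGeneric("relAbundance", function(object) standardGeneric("relAbundance"))

#' @describeIn CsrExperiment Per-sample relative abundances (columns sum
#'   to 1).
#' @export
setMethod("relAbundance", "CsrExperiment", function(object) {
  x <- assay(object, "counts")
  tot <- colSums(x)
  stopIfNot(all(tot > 0), "every sample must have a positive total")
  sweep(x, 2L, tot, "/")
})

#' @rdname CsrExperiment
#' @export
setGeneric("plantedTruth", function(object) standardGeneric("plantedTruth"))

#' @describeIn CsrExperiment Planted ground truth (synthetic data), a list
#'   with `genome_strategy`, `trait_strategy`, effects and seed, or `NULL`.
#' @export
setMethod("plantedTruth", "CsrExperiment",
          function(object) metadata(object)$truth)

#' @rdname CsrExperiment
#' @export
setMethod("show", "CsrExperiment", function(object) {
  callNextMethod()
  cat("traitCounts:", nrow(object@traitCounts), "genomes x",
      ncol(object@traitCounts), "categories\n")
  cat("design:", length(object@design@levels), "levels,",
      sum(object@design@replicates), "samples expected\n")
  if (!is.null(metadata(object)$truth))
    cat("planted truth present (synthetic data)\n")
  invisible(NULL)
})

## sample regimes as factor in canonical order
sampleRegimes <- function(object) {
  factor(colData(object)$regime, levels = regimeOrder())
}
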