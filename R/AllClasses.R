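#' DisturbanceDesign: a replicated disturbance-frequency experimental design
#'
#' Describes an experiment in which replicated bioreactors (or any replicated
#' communities) are exposed to increasing disturbance frequencies, and maps
#' each frequency level onto one of three regime classes: `undisturbed`
#' (never disturbed), `intermediate` (pulse disturbances) and `press`
#' (disturbance at every cycle).
#'
#' @slot levels integer vector of level ids, ordered `0..L-1`.
#' @slot frequencies numeric vector, disturbance events per day for each
#'   level; must be non-decreasing with level.
#' @slot regimes character vector mapping each level to one of
#'   `"undisturbed"`, `"intermediate"`, `"press"`.
#' @slot replicates integer vector, number of independent replicates per
#'   level.
#' @slot day integer scalar, the sampling day label.
#'
#' @seealso [disturbanceDesign()], [defaultDesign()]
#' @export
setClass("DisturbanceDesign",
  representation(levels = "integer", frequencies = "numeric",
                 regimes = "character", replicates = "integer",
                 day = "integer"))

setValidity("DisturbanceDesign", function(object) {
  msg <- character()
  L <- length(object@levels)
  if (L < 1L) msg <- c(msg, "design needs at least one level")
  if (length(object@frequencies) != L || length(object@regimes) != L ||
      length(object@replicates) != L)
    msg <- c(msg, "levels, frequencies, regimes and replicates must align")
  else {
    if (is.unsorted(object@frequencies))
      msg <- c(msg, "frequencies must be non-decreasing with level id")
    if (!all(object@regimes %in% c("undisturbed", "intermediate", "press")))
      msg <- c(msg, "regimes must be undisturbed, intermediate or press")
    if (any(object@replicates < 1L))
      msg <- c(msg, "each level needs at least one replicate")
  }
  if (length(msg)) msg else TRUE
})

#' CsrExperiment: genome abundances, trait profiles and design in one object
#'
#' A [SummarizedExperiment::SummarizedExperiment] with genomes (MAGs) as rows
#' and samples as columns. The `counts` assay holds coverage-derived genome
#' counts (or relative abundances); `rowData` carries genome metadata
#' (size, completeness, contamination, taxonomy and, for synthetic data, the
#' planted true strategy); `colData` carries the sample metadata (level,
#' regime, replicate, day and any function metrics). Two extra slots hold the
#' genome-by-category trait count matrix and the [DisturbanceDesign-class].
#' Planted truth for trait categories (synthetic data only) and the
#' generator seed live in `metadata()`.
#'
#' @slot traitCounts numeric matrix, genomes x COG categories, gene counts.
#' @slot design a [DisturbanceDesign-class].
#'
#' @seealso [CsrExperiment()], [simulateCsrExperiment()]
#' @export
setClass("CsrExperiment",
  contains = "SummarizedExperiment",
  representation(traitCounts = "matrix", design = "DisturbanceDesign"))

setValidity("CsrExperiment", function(object) {
  msg <- character()
  tc <- object@traitCounts
  if (nrow(tc) != nrow(object))
    msg <- c(msg, "traitCounts must have one row per genome")
  if (!is.null(rownames(tc)) && !identical(rownames(tc), rownames(object)))
    msg <- c(msg, "traitCounts rownames must match genome ids")
  if (any(tc < 0)) msg <- c(msg, "trait counts must be non-negative")
  cd <- colData(object)
  need <- c("level", "regime", "replicate")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})
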