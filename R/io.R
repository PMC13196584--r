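## Readers, writers, rarefaction and table aggregation utilities.

#' Rarefy a count table to even depth
#'
#' Subsamples each sample's counts without replacement to exactly `depth`
#' reads. Samples with fewer than `depth` total reads are dropped with a
#' warning listing their ids; a sample whose total equals `depth` is
#' returned unchanged.
#'
#' @param counts feature x sample integer count matrix.
#' @param depth target depth (default 5089 reads per sample).
#' @param seed integer seed.
#' @return rarefied feature x sample matrix (possibly fewer samples), with
#'   attribute `dropped` naming removed samples.
#' @export
rarefyCounts <- function(counts, depth = 5089L, seed = 1L) {
  x <- as.matrix(counts)
  stopIfNot(all(x == round(x)) && all(x >= 0),
            "counts must be non-negative integers")
  stopIfNot(depth >= 1, "depth must be >= 1")
  tot <- colSums(x)
  drop_ <- colnames(x)[tot < depth]
  if (length(drop_))
    warning("samples below depth ", depth, " dropped: ",
            paste(drop_, collapse = ", "))
  keep <- tot >= depth
  x <- x[, keep, drop = FALSE]
  withSeed(seed, {
    out <- apply(x, 2L, function(cnt) {
      if (sum(cnt) == depth) return(cnt)
      ## subsample individual reads without replacement
      reads <- rep.int(seq_along(cnt), cnt)
      tabulate(sample(reads, depth), nbins = length(cnt))
    })
  })
  rownames(out) <- rownames(x)
  attr(out, "dropped") <- drop_
  out
}

#' Aggregate a per-gene annotation table to genome trait counts
#'
#' Consumes the long-format table produced by functional annotation mappers
#' (one row per gene, with the genome id and the COG category letters of the
#' gene). A gene annotated with several letters (e.g. `"KT"`) contributes
#' one count to each letter under the default policy, or `1/n` to each with
#' `multiPolicy = "fractional"`.
#'
#' @param annotations `data.frame` or TSV path with columns `genome_id` and
#'   `cog_category` (a string of one or more single-letter codes).
#' @param categories trait alphabet to keep (default [cogCategories()]);
#'   letters outside it are ignored.
#' @param multiPolicy `"each"` (default) or `"fractional"`.
#' @return genome x category count matrix.
#' @examples
#' ann <- data.frame(genome_id = "g1", cog_category = c("K", "KT"))
#' aggregateGeneAnnotations(ann)[, c("K", "T")]  # K = 2, T = 1
#' @export
aggregateGeneAnnotations <- function(annotations,
                                     categories = cogCategories(),
                                     multiPolicy = c("each", "fractional")) {
  multiPolicy <- match.arg(multiPolicy)
  if (is.character(annotations) && length(annotations) == 1L)
    annotations <- read.delim(annotations, stringsAsFactors = FALSE)
  stopIfNot(all(c("genome_id", "cog_category") %in% colnames(annotations)),
            "annotation table needs genome_id and cog_category columns")
  letters_ <- strsplit(as.character(annotations$cog_category), "")
  nlet <- lengths(letters_)
  long <- data.frame(
    genome = rep(annotations$genome_id, nlet),
    cat = unlist(letters_, use.names = FALSE),
    w = if (multiPolicy == "each") 1 else rep(1 / nlet, nlet),
    stringsAsFactors = FALSE)
  long <- long[long$cat %in% categories, , drop = FALSE]
  genomes <- unique(annotations$genome_id)
  out <- matrix(0, length(genomes), length(categories),
                dimnames = list(genomes, categories))
  agg <- aggregate(w ~ genome + cat, long, sum)
  out[cbind(agg$genome, agg$cat)] <- agg$w
  out
}

#' Write a CsrExperiment bundle as tab-separated files
#'
#' Writes the abundance table, trait counts, sample metadata, genome
#' metadata and (when present) the planted truth and the generator config
#' echo (YAML), so a synthetic bundle is fully round-trippable.
#'
#' @param se a [CsrExperiment-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
writeBundle <- function(se, dir) {
  stopifnot(is(se, "CsrExperiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(abundance = file.path(dir, "abundance.tsv"),
         traits = file.path(dir, "trait_counts.tsv"),
         samples = file.path(dir, "sample_metadata.tsv"),
         genomes = file.path(dir, "genome_metadata.tsv"))
  wt <- function(x, path, rowLabel) {
    df <- data.frame(rownames(x), as.data.frame(x, check.names = FALSE),
                     check.names = FALSE)
    colnames(df)[1] <- rowLabel
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(assay(se, "counts"), p["abundance"], "genome_id")
  wt(traitCounts(se), p["traits"], "genome_id")
  write.table(as.data.frame(colData(se)), p["samples"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  gd <- as.data.frame(rowData(se))
  gd <- cbind(genome_id = rownames(se), gd)
  write.table(gd, p["genomes"], sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- plantedTruth(se)
  if (!is.null(truth)) {
    p["truth"] <- file.path(dir, "truth.tsv")
    tt <- data.frame(
      id = c(names(truth$genome_strategy), names(truth$trait_strategy)),
      kind = c(rep("genome", length(truth$genome_strategy)),
               rep("trait", length(truth$trait_strategy))),
      strategy = c(unname(truth$genome_strategy),
                   unname(truth$trait_strategy)))
    write.table(tt, p["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg <- metadata(se)$config
  if (!is.null(cfg)) {
    p["config"] <- file.path(dir, "config.yaml")
    cfg2 <- cfg
    cfg2$design <- list(levels = cfg$design@levels,
                        frequencies = cfg$design@frequencies,
                        regimes = cfg$design@regimes,
                        replicates = cfg$design@replicates,
                        day = cfg$design@day)
    class(cfg2) <- NULL
    yaml::write_yaml(cfg2, p["config"])
  }
  invisible(p)
}

#' Read a bundle written by [writeBundle()] back into a CsrExperiment
#'
#' Enforces cross-referential integrity: every genome in the abundance
#' table must have a trait profile, every sample must have metadata, and
#' ids must be unique; violations are reported by name.
#'
#' @param dir directory containing the bundle files.
#' @param design optional [DisturbanceDesign-class]; reconstructed from the
#'   config echo when present, else from the sample metadata.
#' @return A [CsrExperiment-class].
#' @export
readBundle <- function(dir, design = NULL) {
  need <- c(abundance = "abundance.tsv", traits = "trait_counts.tsv",
            samples = "sample_metadata.tsv", genomes = "genome_metadata.tsv")
  paths <- file.path(dir, need)
  names(paths) <- names(need)
  miss <- paths[!file.exists(paths)]
  if (length(miss))
    stop("missing bundle files: ", paste(basename(miss), collapse = ", "),
         call. = FALSE)
  rd <- function(path) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (anyDuplicated(df[[1]]))
      stop("duplicated ids in ", basename(path), ": ",
           paste(unique(df[[1]][duplicated(df[[1]])]), collapse = ", "),
           call. = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
  counts <- rd(paths["abundance"])
  traits <- rd(paths["traits"])
  samples <- read.delim(paths["samples"], stringsAsFactors = FALSE)
  genomes <- read.delim(paths["genomes"], stringsAsFactors = FALSE)
  orphanG <- setdiff(rownames(counts), rownames(traits))
  if (length(orphanG))
    stop("genomes without trait profiles: ",
         paste(orphanG, collapse = ", "), call. = FALSE)
  orphanS <- setdiff(colnames(counts), samples$sample_id)
  if (length(orphanS))
    stop("samples without metadata: ", paste(orphanS, collapse = ", "),
         call. = FALSE)
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  traits <- traits[rownames(counts), , drop = FALSE]
  rownames(genomes) <- genomes$genome_id
  genomes <- genomes[rownames(counts), -1, drop = FALSE]
  if (is.null(design)) {
    cfgPath <- file.path(dir, "config.yaml")
    if (file.exists(cfgPath)) {
      cf <- yaml::read_yaml(cfgPath)$design
      design <- disturbanceDesign(frequencies = cf$frequencies,
                                  regimes = cf$regimes,
                                  replicates = cf$replicates,
                                  levels = cf$levels, day = cf$day)
    } else {
      agg <- unique(samples[, c("level", "regime")])
      agg <- agg[order(agg$level), ]
      design <- disturbanceDesign(
        frequencies = seq(0, 1, length.out = nrow(agg)),
        regimes = agg$regime,
        replicates = as.integer(table(samples$level)[as.character(agg$level)]),
        levels = agg$level,
        day = if ("day" %in% colnames(samples)) samples$day[1] else 0L)
    }
  }
  md <- list()
  truthPath <- file.path(dir, "truth.tsv")
  if (file.exists(truthPath)) {
    tt <- read.delim(truthPath, stringsAsFactors = FALSE)
    md$truth <- list(
      genome_strategy = setNames(tt$strategy[tt$kind == "genome"],
                                 tt$id[tt$kind == "genome"]),
      trait_strategy = setNames(tt$strategy[tt$kind == "trait"],
                                tt$id[tt$kind == "trait"]))
  }
  CsrExperiment(counts = counts, traitCounts = traits, design = design,
                sampleData = samples, genomeData = DataFrame(genomes),
                metadata = md)
}

#' Read a BIOM-format count table
#'
#' Thin wrapper over the biomformat package for count tables delivered as
#' BIOM; returns a plain feature x sample matrix.
#'
#' @param path BIOM file path.
#' @return numeric matrix.
#' @export
readBiomCounts <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("the biomformat package is required to read BIOM files",
         call. = FALSE)
  b <- biomformat::read_biom(path)
  as(biomformat::biom_data(b), "matrix")
}
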