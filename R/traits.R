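## Community-aggregated traits (CATs): per-genome trait fractions,
## abundance-weighted community means, level Z-scores and genome-size
## comparisons.

#' Normalize genome trait counts to per-genome fractions
#'
#' `fraction(g, t) = count(g, t) / sum_t count(g, t)`; each genome's
#' fractions sum to 1. Normalizing within the COG-annotated gene complement
#' (rather than per Mbp) controls for genome size and MAG completeness.
#'
#' @param traitCounts genome x category count matrix (or a
#'   [CsrExperiment-class]).
#' @return genome x category fraction matrix, rows summing to 1.
#' @examples
#' normalizeTraits(matrix(c(2, 3, 5), 1, dimnames = list("g1", c("E","K","L"))))
#' @export
normalizeTraits <- function(traitCounts) {
  if (is(traitCounts, "CsrExperiment")) traitCounts <- traitCounts(traitCounts)
  tc <- as.matrix(traitCounts)
  stopIfNot(all(tc >= 0), "trait counts must be non-negative")
  tot <- rowSums(tc)
  if (any(tot == 0))
    stop("genomes with zero COG-annotated genes: ",
         paste(rownames(tc)[tot == 0], collapse = ", "), call. = FALSE)
  tc / tot
}

#' Compute community-aggregated traits (CATs)
#'
#' The abundance-weighted community mean trait fraction,
#' `CAT(s, t) = sum_g p(s, g) * f(g, t)`, a convex combination of the
#' contributing genomes' trait fractions.
#'
#' @param abundance genome x sample relative abundance matrix (columns sum
#'   to 1 within `1e-6`), or a [CsrExperiment-class] (relative abundances
#'   derived from its counts).
#' @param traitFractions genome x category fraction matrix (from
#'   [normalizeTraits()]); computed from the object when omitted.
#' @return sample x category CAT matrix.
#' @examples
#' ab <- cbind(s1 = c(0.5, 0.5))
#' rownames(ab) <- c("g1", "g2")
#' f <- rbind(g1 = c(K = 0.2, L = 0.8), g2 = c(K = 0.4, L = 0.6))
#' computeCATs(ab, f)  # K = 0.3
#' @export
computeCATs <- function(abundance, traitFractions = NULL) {
  if (is(abundance, "CsrExperiment")) {
    if (is.null(traitFractions))
      traitFractions <- normalizeTraits(traitCounts(abundance))
    abundance <- relAbundance(abundance)
  }
  p <- as.matrix(abundance)
  f <- as.matrix(traitFractions)
  stopIfNot(all(p >= 0), "abundances must be non-negative")
  stopIfNot(all(abs(colSums(p) - 1) < 1e-6),
            "per-sample abundances must sum to 1")
  stopIfNot(!is.null(rownames(p)) && !is.null(rownames(f)) &&
              setequal(rownames(p), rownames(f)),
            "genome sets of abundance and trait tables must be identical")
  f <- f[rownames(p), , drop = FALSE]
  t(p) %*% f
}

#' Z-score CAT level means across disturbance levels
#'
#' For each trait, the mean CAT over each level's replicates is computed and
#' the level means are Z-scored across levels with the sample standard
#' deviation. Traits constant across levels are mapped to all-zero rows and
#' flagged.
#'
#' @param cats sample x trait CAT matrix.
#' @param levels integer/character vector assigning each sample to a level,
#'   or a [DisturbanceDesign-class] whose expanded samples match `cats`
#'   rows, or a [CsrExperiment-class].
#' @return list with `z` (level x trait Z matrix), `levelMeans`, and
#'   `constant` (logical per trait).
#' @export
zscoreLevelMeans <- function(cats, levels) {
  if (is(levels, "CsrExperiment")) levels <- colData(levels)$level
  if (is(levels, "DisturbanceDesign")) levels <- designSamples(levels)$level
  cats <- as.matrix(cats)
  stopIfNot(length(levels) == nrow(cats),
            "one level per sample row is required")
  lv <- factor(levels)
  stopIfNot(nlevels(lv) >= 2, "at least two levels are required")
  m <- apply(cats, 2L, function(v) tapply(v, lv, mean))
  rownames(m) <- paste0("L", levels(lv))
  sdv <- apply(m, 2L, sd)
  constant <- sdv == 0
  z <- scale(m)
  z[, constant] <- 0
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  if (any(constant))
    message("traits constant across levels mapped to zero: ",
            paste(colnames(m)[constant], collapse = ", "))
  list(z = z, levelMeans = m, constant = setNames(constant, colnames(m)))
}

#' Welch's heteroscedastic one-way ANOVA on genome sizes by strategy
#'
#' Compares genome-size distributions across strategy classes without
#' assuming equal variances (Welch 1951, Satterthwaite-type denominator
#' degrees of freedom).
#'
#' @param sizes numeric vector of genome sizes.
#' @param groups strategy label per genome.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @examples
#' genomeSizeWelchAnova(c(1, 2, 3, 2, 3, 4, 10, 11, 12),
#'                      rep(c("C", "R", "S"), each = 3))
#' @export
genomeSizeWelchAnova <- function(sizes, groups) {
  g <- factor(groups)
  stopIfNot(nlevels(g) >= 2, "at least two groups are required")
  ns <- tapply(sizes, g, length)
  vs <- tapply(sizes, g, var)
  bad <- names(ns)[ns < 2 | vs == 0 | is.na(vs)]
  if (length(bad))
    stop("groups with < 2 members or zero variance: ",
         paste(bad, collapse = ", "), call. = FALSE)
  fit <- oneway.test(sizes ~ g, var.equal = FALSE)
  list(F = unname(fit$statistic), df1 = unname(fit$parameter[1]),
       df2 = unname(fit$parameter[2]), p = unname(fit$p.value))
}
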