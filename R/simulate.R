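## Synthetic community generator with planted CSR structure.
##
## Emulates a replicated disturbance-frequency experiment: genomes carry
## strategy-dependent COG trait profiles, fitness depends on whether a
## genome's strategy matches a sample's regime, and counts are drawn by
## Dirichlet-multinomial sampling at log-normal depth.

## baseline COG category composition of a typical bacterial genome;
## rough literature-informed fractions over the 19 default categories,
## normalised at use.
defaultBaselineComposition <- function(categories = cogCategories()) {
  base <- c(C = 0.060, D = 0.012, E = 0.090, F = 0.028, G = 0.070,
            H = 0.050, I = 0.040, J = 0.065, K = 0.080, L = 0.055,
            M = 0.060, N = 0.018, O = 0.045, P = 0.055, Q = 0.022,
            S = 0.130, T = 0.050, U = 0.020, V = 0.020)
  miss <- setdiff(categories, names(base))
  if (length(miss)) base[miss] <- 0.02
  p <- base[categories]
  p / sum(p)
}

## genome-size distribution per strategy (base pairs, log-normal):
## competitors largest location / smallest scale, ruderals smallest location,
## stress-tolerants widest scale; differences deliberately subtle so the
## Welch ANOVA on default sizes stays in the non-significant range.
genomeSizeParams <- function() {
  list(C       = c(meanlog = log(4.1e6), sdlog = 0.15),
       R       = c(meanlog = log(3.7e6), sdlog = 0.18),
       S       = c(meanlog = log(3.9e6), sdlog = 0.35),
       neutral = c(meanlog = log(3.9e6), sdlog = 0.20))
}

#' Generate genomes with strategy-linked trait profiles
#'
#' Each genome receives a total COG-annotated gene count drawn uniformly
#' within `geneRange` and allocated multinomially over the trait categories.
#' For a strategy genome, the baseline probability of every category linked
#' to that strategy (see [defaultTraitStrategyMap()]) is multiplied by
#' `1 + traitEffect` before renormalization. Genome sizes are drawn
#' log-normal with strategy-specific location and scale.
#'
#' @param nC,nR,nS,nNeutral number of genomes per planted strategy class.
#' @param traitEffect non-negative multiplier strength on linked categories.
#' @param geneRange length-2 integer range of total annotated genes.
#' @param categories trait alphabet (default [cogCategories()]).
#' @param traitMap named list linking categories to strategies.
#' @param seed integer seed.
#'
#' @return list with `traitCounts` (genome x category matrix), `genomeSize`,
#'   `geneTotal`, `truth` (`data.frame` genome/strategy), `traitTruth`
#'   (category -> linked strategy string), `categories`, `seed`.
#' @examples
#' g <- generateGenomeTraits(nC = 3, nR = 3, nS = 3, nNeutral = 3, seed = 1)
#' rowSums(g$traitCounts) == g$geneTotal
#' @export
generateGenomeTraits <- function(nC = 15L, nR = 15L, nS = 15L, nNeutral = 15L,
                                 traitEffect = 2,
                                 geneRange = c(1500L, 4000L),
                                 categories = cogCategories(),
                                 traitMap = defaultTraitStrategyMap(),
                                 seed = 1L) {
  n <- nC + nR + nS + nNeutral
  stopIfNot(n > 0, "at least one genome must be requested")
  stopIfNot(traitEffect >= 0, "traitEffect must be non-negative")
  stopIfNot(all(unlist(traitMap) %in% c("C", "R", "S")),
            "traitMap strategies must be C, R or S")
  stopIfNot(all(names(traitMap) %in% categories),
            "traitMap categories must belong to the trait alphabet")
  base <- defaultBaselineComposition(categories)
  strategies <- rep(c("C", "R", "S", "neutral"), c(nC, nR, nS, nNeutral))
  ids <- sprintf("MAG%03d", seq_len(n))
  szp <- genomeSizeParams()
  withSeed(seed, {
    geneTotal <- sample(seq(geneRange[1], geneRange[2]), n, replace = TRUE)
    tc <- matrix(0L, n, length(categories),
                 dimnames = list(ids, categories))
    for (i in seq_len(n)) {
      p <- base
      if (strategies[i] != "neutral") {
        linked <- categoriesForStrategy(traitMap, strategies[i])
        p[linked] <- p[linked] * (1 + traitEffect)
        p <- p / sum(p)
      }
      tc[i, ] <- as.integer(rmultinom(1L, geneTotal[i], p))
    }
    genomeSize <- vapply(strategies, function(s)
      rlnorm(1L, szp[[s]]["meanlog"], szp[[s]]["sdlog"]), numeric(1))
  })
  traitTruth <- vapply(categories, function(k) {
    if (k %in% names(traitMap)) paste(sort(traitMap[[k]]), collapse = "")
    else "neutral"
  }, character(1))
  list(traitCounts = tc,
       genomeSize = setNames(unname(genomeSize), ids),
       geneTotal = setNames(geneTotal, ids),
       truth = data.frame(genome_id = ids, strategy = strategies,
                          stringsAsFactors = FALSE),
       traitTruth = traitTruth,
       traitEffect = traitEffect,
       categories = categories, seed = as.integer(seed))
}

## expected relative abundances per level given planted strategies:
## abundance of genome g in level l  propto  base_g * exp(effect * match)
expectedComposition <- function(baseAbundance, strategies, regimes,
                                fitnessEffect) {
  sapply(regimes, function(rg) {
    boost <- ifelse(strategies != "neutral" &
                      strategyRegime(strategies) == rg,
                    exp(fitnessEffect), 1)
    w <- baseAbundance * boost
    w / sum(w)
  })
}

## hypothesis map: which regime favours each strategy
strategyRegime <- function(strategies) {
  c(C = "undisturbed", R = "intermediate", S = "press",
    neutral = NA_character_)[strategies]
}

#' Generate a sample-by-genome count table across a disturbance design
#'
#' Expected relative abundance of genome *g* at level *l* is proportional to
#' `base_g * exp(fitnessEffect)` when the genome's planted strategy matches
#' the level's regime (C: undisturbed, R: intermediate, S: press) and
#' `base_g` otherwise. Each sample's composition is drawn from a Dirichlet
#' distribution with total concentration `concentration` around that
#' expectation, and counts are multinomial at a log-normal sequencing depth.
#'
#' @param truth `data.frame` with `genome_id` and `strategy` columns (as
#'   produced by [generateGenomeTraits()]).
#' @param design a [DisturbanceDesign-class].
#' @param fitnessEffect non-negative log-scale fitness multiplier.
#' @param concentration Dirichlet total concentration (> 0); larger means
#'   less compositional noise between replicates.
#' @param depthMean,depthCv mean and coefficient of variation of the
#'   log-normal per-sample depth.
#' @param baseSdLog log-scale spread of genome baseline abundances.
#' @param seed integer seed.
#'
#' @return list with `counts` (genome x sample), `sampleData`,
#'   `baseAbundance`, `expected` (genome x level expected relative
#'   abundance), `seed`.
#' @examples
#' g <- generateGenomeTraits(nC = 2, nR = 2, nS = 2, nNeutral = 2, seed = 1)
#' a <- generateAbundanceTable(g$truth, defaultDesign(), seed = 2)
#' all(colSums(a$counts) == a$sampleData$depth)
#' @export
generateAbundanceTable <- function(truth, design = defaultDesign(),
                                   fitnessEffect = 2, concentration = 200,
                                   depthMean = 2e4, depthCv = 0.3,
                                   baseSdLog = 0.6, seed = 1L) {
  stopIfNot(nrow(truth) > 0, "genome list is empty")
  stopIfNot(fitnessEffect >= 0, "fitnessEffect must be non-negative")
  stopIfNot(concentration > 0, "concentration must be positive")
  stopIfNot(depthMean > 0, "depthMean must be positive")
  stopIfNot(all(design@replicates >= 1L), "design needs >= 1 replicate")
  samples <- designSamples(design)
  n <- nrow(truth)
  withSeed(seed, {
    baseAbundance <- setNames(rlnorm(n, 0, baseSdLog), truth$genome_id)
    expected <- expectedComposition(baseAbundance, truth$strategy,
                                    designRegimes(design), fitnessEffect)
    colnames(expected) <- paste0("L", design@levels)
    rownames(expected) <- truth$genome_id
    sdlog <- sqrt(log(1 + depthCv^2))
    depth <- round(rlnorm(nrow(samples), log(depthMean) - sdlog^2 / 2, sdlog))
    depth <- pmax(depth, 1)
    counts <- matrix(0L, n, nrow(samples),
                     dimnames = list(truth$genome_id, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      p <- expected[, paste0("L", samples$level[j])]
      comp <- as.numeric(rdirichlet(1L, concentration * p))
      counts[, j] <- as.integer(rmultinom(1L, depth[j], comp))
    }
  })
  samples$depth <- as.integer(depth)
  list(counts = counts, sampleData = samples,
       baseAbundance = baseAbundance, expected = expected,
       fitnessEffect = fitnessEffect, seed = as.integer(seed))
}

## regime-dependent function metric means emulating the measured reactor
## performance: undisturbed = high nitrate / poor settling, intermediate =
## best TKN removal and settling, press = poorest N removal.
functionMetricParams <- function() {
  list(TKN_removal = list(mean = c(undisturbed = 85, intermediate = 90,
                                   press = 55), sd = 4),
       COD_removal = list(mean = c(undisturbed = 98.5, intermediate = 98.5,
                                   press = 98.0), sd = 0.4),
       neg_SVI     = list(mean = c(undisturbed = -150, intermediate = -90,
                                   press = -120), sd = 12),
       effluent_NO3 = list(mean = c(undisturbed = 20, intermediate = 8,
                                    press = 3), sd = 2))
}

#' Generate regime-dependent ecosystem function metrics
#'
#' Gaussian metrics (TKN and COD removal %, additive-inverse sludge volume
#' index, effluent nitrate) with regime-dependent means, used as overlay
#' variables in constrained ordinations.
#'
#' @param sampleData `data.frame` with `sample_id` and `regime` columns.
#' @param params list of per-metric regime means and sd (see source).
#' @param seed integer seed.
#' @return `data.frame`, one row per sample, one column per metric.
#' @export
generateFunctionMetrics <- function(sampleData,
                                    params = functionMetricParams(),
                                    seed = 1L) {
  stopIfNot(!any(duplicated(names(params))), "metric names must be unique")
  withSeed(seed, {
    out <- lapply(params, function(p)
      rnorm(nrow(sampleData), p$mean[sampleData$regime], p$sd))
  })
  res <- data.frame(sample_id = sampleData$sample_id, out,
                    stringsAsFactors = FALSE)
  rownames(res) <- sampleData$sample_id
  res
}

#' Configuration for the synthetic community generator
#'
#' Collects every generator parameter plus one master seed that fans out
#' deterministically into per-stage child seeds (traits, abundances,
#' function metrics, genome quality), so each stage is independently
#' reproducible.
#'
#' @param nC,nR,nS,nNeutral genomes per planted class.
#' @param traitEffect,fitnessEffect planted effect sizes.
#' @param concentration,depthMean,depthCv,baseSdLog abundance sampling
#'   parameters (see [generateAbundanceTable()]).
#' @param geneRange range of total annotated genes per genome.
#' @param design a [DisturbanceDesign-class].
#' @param categories trait alphabet.
#' @param traitMap category -> strategy links.
#' @param seed master seed.
#' @return list of class `CsrSimConfig`.
#' @export
csrSimConfig <- function(nC = 15L, nR = 15L, nS = 15L, nNeutral = 15L,
                         traitEffect = 2, fitnessEffect = 2,
                         concentration = 200, depthMean = 2e4, depthCv = 0.3,
                         baseSdLog = 0.6, geneRange = c(1500L, 4000L),
                         design = defaultDesign(),
                         categories = cogCategories(),
                         traitMap = defaultTraitStrategyMap(),
                         seed = 1L) {
  cfg <- list(nC = nC, nR = nR, nS = nS, nNeutral = nNeutral,
              traitEffect = traitEffect, fitnessEffect = fitnessEffect,
              concentration = concentration, depthMean = depthMean,
              depthCv = depthCv, baseSdLog = baseSdLog,
              geneRange = geneRange, design = design,
              categories = categories, traitMap = traitMap,
              seed = as.integer(seed))
  class(cfg) <- "CsrSimConfig"
  cfg
}

#' Simulate a complete synthetic CSR experiment
#'
#' One call producing a self-consistent [CsrExperiment-class]: genomes with
#' strategy-linked trait profiles, Dirichlet-multinomial abundance counts
#' across the design, genome quality metadata, regime-dependent function
#' metrics, and the recorded planted truth.
#'
#' @param config a [csrSimConfig()] list.
#' @return A [CsrExperiment-class] with planted truth in `metadata()`.
#' @examples
#' se <- simulateCsrExperiment(csrSimConfig(nC = 3, nR = 3, nS = 3,
#'                                          nNeutral = 3, seed = 7))
#' dim(se)
#' @export
simulateCsrExperiment <- function(config = csrSimConfig()) {
  stopifnot(inherits(config, "CsrSimConfig"))
  g <- generateGenomeTraits(config$nC, config$nR, config$nS, config$nNeutral,
                            traitEffect = config$traitEffect,
                            geneRange = config$geneRange,
                            categories = config$categories,
                            traitMap = config$traitMap,
                            seed = childSeed(config$seed, 1L))
  a <- generateAbundanceTable(g$truth, config$design,
                              fitnessEffect = config$fitnessEffect,
                              concentration = config$concentration,
                              depthMean = config$depthMean,
                              depthCv = config$depthCv,
                              baseSdLog = config$baseSdLog,
                              seed = childSeed(config$seed, 2L))
  fm <- generateFunctionMetrics(a$sampleData,
                                seed = childSeed(config$seed, 3L))
  n <- nrow(g$truth)
  withSeed(childSeed(config$seed, 4L), {
    completeness <- round(runif(n, 70, 100), 1)
    contamination <- round(runif(n, 0, 8), 1)
  })
  genomeData <- DataFrame(
    genome_size = g$genomeSize,
    completeness = completeness,
    contamination = contamination,
    taxonomy = paste0("g__SynGenus", seq_len(n)),
    true_strategy = g$truth$strategy,
    row.names = g$truth$genome_id)
  sampleData <- cbind(a$sampleData, fm[, -1L, drop = FALSE])
  truth <- list(genome_strategy = setNames(g$truth$strategy,
                                           g$truth$genome_id),
                trait_strategy = g$traitTruth,
                trait_effect = config$traitEffect,
                fitness_effect = config$fitnessEffect,
                seed = config$seed)
  CsrExperiment(counts = a$counts, traitCounts = g$traitCounts,
                design = config$design, sampleData = sampleData,
                genomeData = genomeData,
                metadata = list(truth = truth, config = config,
                                expected = a$expected,
                                function_metrics = names(fm)[-1L]))
}
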