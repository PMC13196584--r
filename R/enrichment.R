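## Simulation-based regime enrichment testing and CSR strategy assignment.
##
## For each feature (genome relative abundance, or trait CAT) and each
## disturbance regime, the statistic is the mean feature value inside the
## regime minus the mean outside. Significance is assessed against a null
## built by permuting the sample-to-regime labels (unrestricted, seeded),
## one-sided for enrichment, with Benjamini-Hochberg control across the
## full feature x regime family. A parametric multinomial bootstrap null is
## available as an alternative backend.

#' Permutation test of regime enrichment
#'
#' @param values feature x sample numeric matrix (finite values).
#' @param regimes regime label per sample (character/factor), or a
#'   [CsrExperiment-class] from which regimes are taken. Every sample must
#'   belong to exactly one regime.
#' @param nSim number of label permutations (>= 99; default 9999).
#' @param seed integer seed.
#' @param alpha BH false-discovery level used downstream (recorded only).
#' @param null `"permutation"` (default, label permutation) or
#'   `"multinomial"` (parametric bootstrap: per-permutation feature values
#'   re-drawn multinomially from the pooled mean composition at each
#'   sample's observed total — only meaningful for count-derived values).
#' @param counts integer feature x sample counts, required for the
#'   multinomial backend.
#'
#' @return `data.frame` of class `EnrichmentResult`, one row per feature x
#'   regime: `feature`, `regime`, `effect` (mean in minus mean out), `p`
#'   (one-sided, `(exceedances + 1)/(nSim + 1)`, ties as exceedances), `q`
#'   (BH across the whole family). Attributes `nSim` and `seed` record the
#'   run.
#' @examples
#' v <- rbind(f1 = c(1, 1, 0, 0, 0, 0))
#' rg <- c("undisturbed", "undisturbed", "intermediate", "intermediate",
#'         "press", "press")
#' regimeEnrichmentTest(v, rg, nSim = 999, seed = 1)
#' @export
regimeEnrichmentTest <- function(values, regimes, nSim = 9999L, seed = 1L,
                                 alpha = 0.05,
                                 null = c("permutation", "multinomial"),
                                 counts = NULL) {
  null <- match.arg(null)
  if (is(regimes, "CsrExperiment")) regimes <- as.character(sampleRegimes(regimes))
  values <- as.matrix(values)
  stopIfNot(all(is.finite(values)), "feature values must be finite")
  stopIfNot(ncol(values) == length(regimes),
            "feature vectors must have one value per sample")
  stopIfNot(nSim >= 99, "at least 99 permutations are required")
  rg <- factor(regimes, levels = intersect(regimeOrder(), unique(regimes)))
  stopIfNot(!anyNA(rg), "every sample must map to a known regime")
  stopIfNot(all(table(rg) > 0), "every regime must contain samples")
  S <- ncol(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("feature", seq_len(nrow(values)))

  ## contrast vector per regime: mean(in) - mean(out)
  contrasts <- sapply(levels(rg), function(r) {
    z <- rg == r
    z / sum(z) - (!z) / sum(!z)
  })
  obs <- values %*% contrasts   # features x regimes

  exceed <- matrix(0L, nrow(values), nlevels(rg),
                   dimnames = dimnames(obs))
  withSeed(seed, {
    if (null == "permutation") {
      ## all regimes share each permutation of the sample labels
      block <- 500L
      done <- 0L
      while (done < nSim) {
        b <- min(block, nSim - done)
        perms <- replicate(b, sample.int(S))
        for (r in seq_len(nlevels(rg))) {
          cm <- matrix(contrasts[, r][perms], nrow = S)
          tperm <- values %*% cm
          exceed[, r] <- exceed[, r] +
            rowSums(tperm >= (obs[, r] - 1e-12))
        }
        done <- done + b
      }
    } else {
      stopIfNot(!is.null(counts),
                "multinomial null requires the counts matrix")
      counts <- as.matrix(counts)
      stopIfNot(all(counts >= 0) && all(counts == round(counts)),
                "counts must be non-negative integers")
      pool <- rowSums(counts) / sum(counts)
      tot <- colSums(counts)
      for (s in seq_len(nSim)) {
        sim <- sapply(seq_len(S), function(j) {
          cj <- rmultinom(1L, tot[j], pool)
          cj / tot[j]
        })
        tperm <- sim %*% contrasts
        exceed <- exceed + (tperm >= (obs - 1e-12))
      }
    }
  })
  p <- permPval(exceed, nSim)
  out <- data.frame(
    feature = rep(rownames(values), times = nlevels(rg)),
    regime = rep(levels(rg), each = nrow(values)),
    effect = as.vector(obs),
    p = as.vector(p),
    stringsAsFactors = FALSE)
  out$q <- p.adjust(out$p, method = "BH")
  attr(out, "nSim") <- as.integer(nSim)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "alpha") <- alpha
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}

#' Map enrichment results onto CSR strategy sets
#'
#' A feature is assigned C if significantly enriched in the undisturbed
#' regime (BH q <= alpha), R if in the intermediate regime, S if in the
#' press regime; multi-letter labels record enrichment in several regimes
#' and an empty set maps to `"unassigned"`. Letters appear in the fixed
#' order C < R < S.
#'
#' @param enrichment an `EnrichmentResult` from [regimeEnrichmentTest()].
#' @param alpha FDR level in (0, 1).
#' @return `data.frame` with `feature`, `label`, and per-regime `q` columns.
#' @export
assignStrategies <- function(enrichment, alpha = 0.05) {
  stopIfNot(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  stopIfNot(all(c("feature", "regime", "q") %in% colnames(enrichment)),
            "enrichment must carry feature, regime and q columns")
  need <- regimeOrder()
  stopIfNot(all(need %in% enrichment$regime),
            paste("missing regime in enrichment result; need",
                  paste(need, collapse = ", ")))
  feats <- unique(enrichment$feature)
  qw <- vapply(need, function(r) {
    x <- enrichment[enrichment$regime == r, ]
    setNames(x$q, x$feature)[feats]
  }, numeric(length(feats)))
  qw <- matrix(qw, nrow = length(feats), dimnames = list(feats, need))
  lab <- vapply(seq_along(feats), function(i)
    canonicalLabel(qw[i, "undisturbed"] <= alpha,
                   qw[i, "intermediate"] <= alpha,
                   qw[i, "press"] <= alpha), character(1))
  data.frame(feature = feats, label = lab,
             q_undisturbed = unname(qw[, "undisturbed"]),
             q_intermediate = unname(qw[, "intermediate"]),
             q_press = unname(qw[, "press"]),
             stringsAsFactors = FALSE)
}

#' Venn-region accounting of strategy assignments
#'
#' Counts features in each of the 8 subsets of \{C, R, S\} (including
#' `"unassigned"` for the empty set) plus summary totals.
#'
#' @param assignments `data.frame` from [assignStrategies()] (needs a
#'   `label` column), or a character vector of canonical labels.
#' @return list with `regions` (named integer vector over the 8 canonical
#'   labels) and `totals` (`unique_C`, `unique_R`, `unique_S`, `overlap`,
#'   `unassigned`, `n`).
#' @examples
#' vennCounts(c("C", "C", "CR", "unassigned"))
#' @export
vennCounts <- function(assignments) {
  lab <- if (is.data.frame(assignments)) assignments$label else assignments
  canon <- c("C", "R", "S", "CR", "CS", "RS", "CRS", "unassigned")
  bad <- setdiff(unique(lab), canon)
  if (length(bad))
    stop("non-canonical label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  regions <- setNames(integer(length(canon)), canon)
  tab <- table(lab)
  regions[names(tab)] <- as.integer(tab)
  list(regions = regions,
       totals = c(unique_C = unname(regions["C"]),
                  unique_R = unname(regions["R"]),
                  unique_S = unname(regions["S"]),
                  overlap = sum(regions[c("CR", "CS", "RS", "CRS")]),
                  unassigned = unname(regions["unassigned"]),
                  n = length(lab)))
}

#' Classify genomes (and optionally traits) of an experiment into CSR sets
#'
#' Convenience wrapper: runs [regimeEnrichmentTest()] on genome relative
#' abundances (features = genomes) and on community-aggregated traits
#' (features = COG categories), then [assignStrategies()] on each.
#'
#' @param se a [CsrExperiment-class].
#' @param nSim permutations (default 9999).
#' @param alpha BH FDR level.
#' @param seed integer seed.
#' @return list with `genomes`, `traits` (assignment tables), `genomeEnrichment`,
#'   `traitEnrichment`, and `venn` (on genome labels).
#' @export
classifyCsr <- function(se, nSim = 9999L, alpha = 0.05, seed = 1L) {
  stopifnot(is(se, "CsrExperiment"))
  rg <- as.character(sampleRegimes(se))
  ab <- relAbundance(se)
  ge <- regimeEnrichmentTest(ab, rg, nSim = nSim, seed = seed, alpha = alpha)
  ga <- assignStrategies(ge, alpha = alpha)
  cats <- computeCATs(se)
  te <- regimeEnrichmentTest(t(cats), rg, nSim = nSim,
                             seed = childSeed(seed, 5L), alpha = alpha)
  ta <- assignStrategies(te, alpha = alpha)
  list(genomes = ga, traits = ta, genomeEnrichment = ge,
       traitEnrichment = te, venn = vennCounts(ga))
}
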