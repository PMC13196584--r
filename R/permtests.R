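## One-way permutation tests on dissimilarity matrices: PERMANOVA and
## PERMDISP, both with the (exceedances + 1)/(nPerm + 1) p-value convention
## and seeded, unrestricted permutation of raw observations.

permanovaF <- function(D2, groups) {
  ## D2: squared dissimilarities; groups: factor
  N <- nrow(D2)
  g <- nlevels(groups)
  ssTotal <- sum(D2[upper.tri(D2)]) / N
  ssWithin <- 0
  for (lev in levels(groups)) {
    z <- groups == lev
    ng <- sum(z)
    ssWithin <- ssWithin + sum(D2[z, z][upper.tri(D2[z, z])]) / ng
  }
  ssAmong <- ssTotal - ssWithin
  F <- (ssAmong / (g - 1)) / (ssWithin / (N - g))
  list(F = F, ssTotal = ssTotal, ssWithin = ssWithin, ssAmong = ssAmong,
       df1 = g - 1, df2 = N - g)
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' One-way fixed-factor pseudo-F on a dissimilarity matrix:
#' `SS_total = sum_{i<j} d_ij^2 / N`, `SS_within = sum_groups sum_{i<j in
#' group} d_ij^2 / n_g`, `F = ((SS_total - SS_within)/(g-1)) /
#' (SS_within/(N-g))`, with the p-value from seeded unrestricted permutation
#' of the group labels.
#'
#' @param D symmetric dissimilarity matrix.
#' @param groups group label per sample; every group needs >= 2 samples.
#' @param nPerm number of permutations (default 9999).
#' @param seed integer seed.
#' @return list of class `PermutationTestResult`: `statistic` (pseudo-F),
#'   `p`, `nPerm`, `seed`, `df1`, `df2`, `ssAmong`, `ssWithin`, `ssTotal`.
#' @export
permanova <- function(D, groups, nPerm = 9999L, seed = 1L) {
  D <- as.matrix(D)
  g <- factor(groups)
  stopIfNot(length(groups) == nrow(D), "labels must match the matrix")
  stopIfNot(nlevels(g) >= 2, "at least two groups are required")
  stopIfNot(all(table(g) >= 2), "singleton groups are not allowed")
  D2 <- D^2
  obs <- permanovaF(D2, g)
  withSeed(seed, {
    exceed <- 0L
    for (b in seq_len(nPerm)) {
      Fp <- permanovaF(D2, g[sample.int(length(g))])$F
      if (Fp >= obs$F - 1e-12) exceed <- exceed + 1L
    }
  })
  structure(list(statistic = obs$F, name = "pseudo-F",
                 p = permPval(exceed, nPerm),
                 nPerm = as.integer(nPerm), seed = as.integer(seed),
                 df1 = obs$df1, df2 = obs$df2,
                 ssAmong = obs$ssAmong, ssWithin = obs$ssWithin,
                 ssTotal = obs$ssTotal),
            class = "PermutationTestResult")
}

## distances to group centroids in PCoA space with negative-eigenvalue
## correction: squared distance = real-part contribution minus imaginary-
## part contribution, floored at 0 (Anderson 2006).
centroidDistances <- function(pc, groups) {
  U <- pc$coordinates
  neg <- pc$negative
  d2 <- numeric(nrow(U))
  for (lev in levels(groups)) {
    z <- groups == lev
    cen <- colMeans(U[z, , drop = FALSE])
    dev2 <- sweep(U[z, , drop = FALSE], 2L, cen)^2
    d2[z] <- rowSums(dev2[, !neg, drop = FALSE]) -
      (if (any(neg)) rowSums(dev2[, neg, drop = FALSE]) else 0)
  }
  sqrt(pmax(d2, 0))
}

anovaF <- function(z, groups) {
  N <- length(z); g <- nlevels(groups)
  gm <- mean(z)
  means <- tapply(z, groups, mean)
  ns <- tapply(z, groups, length)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((z - means[groups])^2)
  if (ssw == 0) return(if (ssb == 0) 0 else Inf)
  (ssb / (g - 1)) / (ssw / (N - g))
}

#' PERMDISP: homogeneity of multivariate dispersions
#'
#' Samples are embedded by [principalCoordinates()]; each sample's distance
#' to its group centroid is computed with the negative-eigenvalue correction
#' (imaginary axes subtract, squared distances floored at 0); the one-way
#' ANOVA F on those distances is tested by permuting samples across groups.
#'
#' @inheritParams permanova
#' @return list of class `PermutationTestResult` with `statistic` (F), `p`,
#'   `nPerm`, `seed`, and `distances` (per-sample centroid distance).
#' @export
permdisp <- function(D, groups, nPerm = 9999L, seed = 1L) {
  D <- as.matrix(D)
  g <- factor(groups)
  stopIfNot(length(groups) == nrow(D), "labels must match the matrix")
  stopIfNot(nlevels(g) >= 2, "at least two groups are required")
  stopIfNot(all(table(g) >= 2), "singleton groups are not allowed")
  pc <- principalCoordinates(D)
  z <- centroidDistances(pc, g)
  obs <- anovaF(z, g)
  withSeed(seed, {
    exceed <- 0L
    for (b in seq_len(nPerm)) {
      if (anovaF(z[sample.int(length(z))], g) >= obs - 1e-12)
        exceed <- exceed + 1L
    }
  })
  structure(list(statistic = obs, name = "PERMDISP F",
                 p = permPval(exceed, nPerm),
                 nPerm = as.integer(nPerm), seed = as.integer(seed),
                 distances = setNames(z, rownames(D))),
            class = "PermutationTestResult")
}

#' @export
print.PermutationTestResult <- function(x, ...) {
  cat(x$name, "=", format(x$statistic, digits = 5),
      " p =", format(x$p, digits = 4),
      " (", x$nPerm, "permutations, seed", x$seed, ")\n")
  invisible(x)
}
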