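suppressPackageStartupMessages({
  library(SummarizedExperiment)
})

## small synthetic experiment used across tests
smallConfig <- function(seed = 101L, ...) {
  csrSimConfig(nC = 5L, nR = 5L, nS = 5L, nNeutral = 5L,
               depthMean = 5e3, seed = seed, ...)
}

## tiny design: 3 levels x 2 replicates, one level per regime
tinyDesign <- function(replicates = 2L) {
  disturbanceDesign(frequencies = c(0, 1/2, 1),
                    regimes = c("undisturbed", "intermediate", "press"),
                    replicates = replicates)
}

## independent long-hand Welch ANOVA (Welch 1951), used as a formula oracle
welchOracle <- function(values, groups) {
  g <- split(values, groups)
  k <- length(g)
  ni <- vapply(g, length, numeric(1))
  mi <- vapply(g, mean, numeric(1))
  vi <- vapply(g, var, numeric(1))
  wi <- ni / vi
  W <- sum(wi)
  mw <- sum(wi * mi) / W
  A <- sum(wi * (mi - mw)^2) / (k - 1)
  B <- 1 + (2 * (k - 2) / (k^2 - 1)) * sum((1 - wi / W)^2 / (ni - 1))
  F <- A / B
  df2 <- (k^2 - 1) / (3 * sum((1 - wi / W)^2 / (ni - 1)))
  p <- pf(F, k - 1, df2, lower.tail = FALSE)
  list(F = F, df1 = k - 1, df2 = df2, p = p)
}

## exact one-sided enrichment p for one regime by subset enumeration
exactEnrichP <- function(values, inRegime) {
  n <- length(values)
  k <- sum(inRegime)
  tstat <- function(z) mean(values[z]) - mean(values[!z])
  obs <- tstat(inRegime)
  subsets <- combn(n, k)
  ts <- apply(subsets, 2L, function(idx) {
    z <- rep(FALSE, n); z[idx] <- TRUE; tstat(z)
  })
  mean(ts >= obs - 1e-12)
}
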