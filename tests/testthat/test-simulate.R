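test_that("trait generator conserves gene totals and rejects bad inputs", {
  g <- generateGenomeTraits(nC = 4, nR = 4, nS = 4, nNeutral = 4, seed = 5)
  expect_equal(rowSums(g$traitCounts), g$geneTotal, ignore_attr = TRUE)
  expect_equal(ncol(g$traitCounts), 19L)
  expect_setequal(g$truth$strategy, c("C", "R", "S", "neutral"))
  expect_equal(nrow(g$truth), 16L)

  expect_error(generateGenomeTraits(0, 0, 0, 0), "at least one genome")
  expect_error(generateGenomeTraits(1, 1, 1, 1, traitEffect = -1),
               "non-negative")
})

test_that("zero trait effect leaves strategy and neutral genomes exchangeable", {
  g <- generateGenomeTraits(nC = 40, nR = 0, nS = 0, nNeutral = 40,
                            traitEffect = 0, seed = 7)
  f <- normalizeTraits(g$traitCounts)
  isC <- g$truth$strategy == "C"
  ## C-linked category Q should show no shift when no effect is planted
  expect_gt(wilcox.test(f[isC, "Q"], f[!isC, "Q"])$p.value, 0.01)
})

test_that("planted trait enrichment matches the analytic margin and a Monte-Carlo oracle", {
  effect <- 2
  nPer <- 1000L
  g <- generateGenomeTraits(nC = nPer, nR = 0, nS = 0, nNeutral = nPer,
                            traitEffect = effect, geneRange = c(2000, 2000),
                            seed = 11)
  f <- normalizeTraits(g$traitCounts)
  isC <- g$truth$strategy == "C"

  ## analytic expectation: baseline prob of Q times (1+e), renormalised over
  ## all categories linked to C (Q, I, E, M, V)
  base <- csrtraits:::defaultBaselineComposition()
  linkedC <- c("Q", "I", "E", "M", "V")
  zC <- 1 + effect * sum(base[linkedC])
  expQ_C <- base["Q"] * (1 + effect) / zC
  expQ_N <- base["Q"]

  ## Monte-Carlo oracle: resample the generative model directly
  set.seed(99)
  pC <- base; pC[linkedC] <- pC[linkedC] * (1 + effect); pC <- pC / sum(pC)
  oracleC <- replicate(2000, {
    x <- rmultinom(1, 2000, pC); x["Q", 1] / 2000
  })
  expect_lt(abs(mean(oracleC) - expQ_C), 3 * sd(oracleC) / sqrt(2000))

  seQ <- sd(f[isC, "Q"]) / sqrt(nPer)
  margin <- mean(f[isC, "Q"]) - mean(f[!isC, "Q"])
  expect_lt(abs(margin - (expQ_C - expQ_N)),
            3 * sqrt(seQ^2 + (sd(f[!isC, "Q"]) / sqrt(nPer))^2))
})

test_that("genome sizes follow strategy-specific log-normals", {
  g <- generateGenomeTraits(nC = 300, nR = 300, nS = 300, nNeutral = 0,
                            seed = 3)
  sz <- split(log(g$genomeSize), g$truth$strategy)
  ## competitors largest location, ruderals smallest, stress-tolerants
  ## widest scale
  expect_gt(mean(sz$C), mean(sz$R))
  expect_gt(sd(sz$S), sd(sz$C))
})

test_that("abundance tables conserve depth and respond to planted fitness", {
  g <- generateGenomeTraits(nC = 5, nR = 5, nS = 5, nNeutral = 5, seed = 2)
  a <- generateAbundanceTable(g$truth, defaultDesign(), fitnessEffect = 2,
                              concentration = 200, depthMean = 2e4,
                              seed = 21)
  expect_equal(colSums(a$counts), a$sampleData$depth, ignore_attr = TRUE)
  expect_equal(nrow(a$sampleData), 30L)

  ## independent oracle for the expected composition: recompute the
  ## boosted-and-renormalised expectation from the recorded baselines
  regimes <- c("undisturbed", rep("intermediate", 4), "press")
  expOracle <- sapply(regimes, function(rg) {
    boost <- ifelse(g$truth$strategy == "C" & rg == "undisturbed" |
                      g$truth$strategy == "R" & rg == "intermediate" |
                      g$truth$strategy == "S" & rg == "press",
                    exp(2), 1)
    w <- a$baseAbundance * boost
    w / sum(w)
  })
  expect_equal(unname(a$expected), unname(expOracle), tolerance = 1e-12)

  ## planted-C genomes have their highest mean relative abundance at L0
  rel <- sweep(a$counts, 2, colSums(a$counts), "/")
  totC <- colSums(rel[g$truth$strategy == "C", ])
  cMean <- tapply(totC, a$sampleData$level, mean)
  expect_equal(unname(which.max(cMean)), 1L)

  ## Monte-Carlo oracle on the generative expectation: average Dirichlet
  ## draws around the expected composition at L0 and at L5
  set.seed(5)
  dirDraw <- function(p) {
    x <- rgamma(length(p), 200 * p); x / sum(x)
  }
  mcL0 <- rowMeans(replicate(1e4, dirDraw(a$expected[, "L0"])))
  isC <- g$truth$strategy == "C"
  expect_equal(sum(mcL0[isC]), sum(a$expected[isC, "L0"]), tolerance = 0.02)
  expect_gt(sum(a$expected[isC, "L0"]), max(colSums(a$expected[isC, -1])))
})

test_that("zero fitness effect yields exchangeable levels", {
  g <- generateGenomeTraits(nC = 5, nR = 5, nS = 5, nNeutral = 5, seed = 4)
  a <- generateAbundanceTable(g$truth, defaultDesign(), fitnessEffect = 0,
                              seed = 31)
  expect_true(all(a$expected[, 1] == a$expected[, 2]))
  ## label-permutation test on total planted-C abundance across levels
  rel <- sweep(a$counts, 2, colSums(a$counts), "/")
  v <- colSums(rel[g$truth$strategy == "C", ])
  obs <- var(tapply(v, a$sampleData$level, mean))
  set.seed(8)
  null <- replicate(999, var(tapply(sample(v), a$sampleData$level, mean)))
  expect_gt((sum(null >= obs) + 1) / 1000, 0.01)
})

test_that("simulation bundles are deterministic and round-trippable", {
  cfg <- smallConfig(seed = 77)
  se1 <- simulateCsrExperiment(cfg)
  se2 <- simulateCsrExperiment(cfg)
  expect_identical(assay(se1, "counts"), assay(se2, "counts"))
  expect_identical(traitCounts(se1), traitCounts(se2))

  d1 <- tempfile(); d2 <- tempfile()
  writeBundle(se1, d1); writeBundle(se2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }

  back <- readBundle(d1)
  expect_equal(assay(back, "counts"), assay(se1, "counts"))
  expect_equal(traitCounts(back), traitCounts(se1))
  expect_identical(plantedTruth(back)$genome_strategy,
                   plantedTruth(se1)$genome_strategy)
})

test_that("metadata carries 6 levels x 5 replicates under the default design", {
  se <- simulateCsrExperiment(csrSimConfig(nC = 2, nR = 2, nS = 2,
                                           nNeutral = 2, seed = 1))
  expect_equal(ncol(se), 30L)
  expect_equal(as.integer(table(colData(se)$level)), rep(5L, 6))
})
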