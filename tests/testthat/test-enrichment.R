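test_that("constant features are never called enriched", {
  v <- rbind(flat = rep(2.5, 6))
  rg <- rep(c("undisturbed", "intermediate", "press"), each = 2)
  res <- regimeEnrichmentTest(v, rg, nSim = 199, seed = 1)
  expect_equal(res$effect, rep(0, 3))
  expect_equal(res$p, rep(1, 3))
  expect_true(all(res$q >= res$p))
})

test_that("permutation p-values agree with exhaustive enumeration", {
  rg <- rep(c("undisturbed", "intermediate", "press"), each = 2)
  v <- rbind(pressInd = as.numeric(rg == "press"))
  exact <- exactEnrichP(v[1, ], rg == "press")
  res <- regimeEnrichmentTest(v, rg, nSim = 9999, seed = 42)
  pPress <- res$p[res$regime == "press"]
  expect_lt(abs(pPress - exact), 0.02)
  ## the minimum achievable p for 2-of-6 membership is 1/15
  expect_equal(exact, 1 / 15)

  ## a non-indicator feature, checked against the same oracle
  set.seed(7)
  v2 <- rbind(f = rnorm(6))
  exact2 <- exactEnrichP(v2[1, ], rg == "undisturbed")
  res2 <- regimeEnrichmentTest(v2, rg, nSim = 9999, seed = 43)
  expect_lt(abs(res2$p[res2$regime == "undisturbed"] - exact2), 0.02)
})

test_that("null features give uniform p-values and a calibrated family", {
  g <- generateGenomeTraits(nC = 0, nR = 0, nS = 0, nNeutral = 200,
                            traitEffect = 0, seed = 55)
  a <- generateAbundanceTable(g$truth, defaultDesign(), fitnessEffect = 0,
                              seed = 56)
  rel <- sweep(a$counts, 2, colSums(a$counts), "/")
  res <- regimeEnrichmentTest(rel, a$sampleData$regime, nSim = 499,
                              seed = 57)
  expect_true(all(res$p > 0))
  p <- res$p[res$regime == "press"]
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("strategy sets follow the regime-to-letter map", {
  mk <- function(qu, qi, qp) {
    data.frame(feature = "f", regime = regimeOrder(),
               effect = 0, p = c(qu, qi, qp), q = c(qu, qi, qp))
  }
  expect_equal(assignStrategies(mk(0.01, 0.8, 0.9))$label, "C")
  expect_equal(assignStrategies(mk(0.01, 0.02, 0.9))$label, "CR")
  expect_equal(assignStrategies(mk(0.01, 0.02, 0.03))$label, "CRS")
  expect_equal(assignStrategies(mk(0.8, 0.9, 0.7))$label, "unassigned")
  expect_error(assignStrategies(mk(0.1, 0.1, 0.1)[-1, ]), "missing regime")
})

test_that("venn accounting covers the 8 canonical regions", {
  empty <- vennCounts(character())
  expect_equal(sum(empty$regions), 0L)

  allC <- vennCounts(rep("C", 7))
  expect_equal(unname(allC$regions["C"]), 7L)
  expect_equal(sum(allC$regions), 7L)

  expect_error(vennCounts("RC"), "non-canonical")

  ## recount oracle on a synthetic classification
  se <- simulateCsrExperiment(smallConfig(seed = 31))
  cls <- classifyCsr(se, nSim = 499, seed = 32)
  v <- vennCounts(cls$genomes)
  recount <- table(factor(cls$genomes$label,
                          levels = names(v$regions)))
  expect_equal(as.integer(v$regions), as.integer(recount))
  expect_equal(unname(v$totals["n"]), nrow(cls$genomes))
})

test_that("planted strategy recovery rises with fitness effect", {
  recovery <- function(effect, seed) {
    cfg <- csrSimConfig(nC = 6, nR = 6, nS = 6, nNeutral = 6,
                        fitnessEffect = effect, seed = seed)
    se <- simulateCsrExperiment(cfg)
    cls <- classifyCsr(se, nSim = 499, seed = seed + 1)
    truth <- plantedTruth(se)$genome_strategy
    strat <- names(truth)[truth != "neutral"]
    mean(cls$genomes$label[match(strat, cls$genomes$feature)] ==
           truth[strat])
  }
  lo <- mean(vapply(1:3, function(s) recovery(0.3, 400 + s), numeric(1)))
  hi <- mean(vapply(1:3, function(s) recovery(2.5, 500 + s), numeric(1)))
  expect_gte(hi, lo)
  expect_gte(hi, 0.9)
})

test_that("the multinomial bootstrap backend returns valid p-values", {
  g <- generateGenomeTraits(nC = 3, nR = 3, nS = 3, nNeutral = 3, seed = 61)
  a <- generateAbundanceTable(g$truth, tinyDesign(replicates = 3),
                              fitnessEffect = 1, seed = 62)
  rel <- sweep(a$counts, 2, colSums(a$counts), "/")
  res <- regimeEnrichmentTest(rel, a$sampleData$regime, nSim = 199,
                              seed = 63, null = "multinomial",
                              counts = a$counts)
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_true(all(res$q >= res$p - 1e-12))
  expect_error(regimeEnrichmentTest(rel, a$sampleData$regime, nSim = 199,
                                    null = "multinomial"),
               "counts")
})
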