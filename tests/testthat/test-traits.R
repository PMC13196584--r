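test_that("trait normalization produces per-genome fractions", {
  eq <- matrix(7L, 1, 19, dimnames = list("g1", cogCategories()))
  expect_equal(unname(normalizeTraits(eq)[1, ]), rep(1 / 19, 19))

  toy <- matrix(c(2, 3, 5), 1, dimnames = list("g2", c("E", "K", "L")))
  expect_equal(unname(normalizeTraits(toy)[1, ]), c(0.2, 0.3, 0.5))

  set.seed(1)
  rnd <- matrix(rpois(5 * 19, 30) + 1, 5, 19,
                dimnames = list(paste0("g", 1:5), cogCategories()))
  expect_equal(rowSums(normalizeTraits(rnd)), rep(1, 5),
               tolerance = 1e-12, ignore_attr = TRUE)
  ## invariance under uniform scaling of a genome's counts
  expect_equal(normalizeTraits(rnd * 3), normalizeTraits(rnd))

  bad <- rbind(rnd, gZero = rep(0L, 19))
  expect_error(normalizeTraits(bad), "gZero")
})

test_that("community-aggregated traits are abundance-weighted convex means", {
  f <- rbind(g1 = c(K = 0.2, L = 0.8), g2 = c(K = 0.4, L = 0.6))
  ab <- cbind(s1 = c(g1 = 0.5, g2 = 0.5))
  expect_equal(computeCATs(ab, f)["s1", "K"], 0.3)

  ## all genomes sharing a fraction vector: every CAT row equals it
  f0 <- matrix(rep(c(0.1, 0.9), each = 4), 4, 2,
               dimnames = list(paste0("g", 1:4), c("K", "L")))
  set.seed(2)
  ab4 <- matrix(rgamma(4 * 3, 1), 4, 3,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  ab4 <- sweep(ab4, 2, colSums(ab4), "/")
  cats <- computeCATs(ab4, f0)
  expect_equal(unname(cats), matrix(rep(c(0.1, 0.9), each = 3), 3, 2))

  ## vertex of the simplex: all abundance on one genome
  abv <- cbind(s1 = c(g1 = 1, g2 = 0))
  expect_equal(computeCATs(abv, f)["s1", ], f["g1", ])

  expect_error(computeCATs(ab, f[1, , drop = FALSE]), "identical")
})

test_that("CAT convexity and linearity hold on random inputs", {
  set.seed(3)
  for (rep_ in 1:5) {
    f <- normalizeTraits(matrix(rpois(6 * 4, 20) + 1, 6, 4,
                                dimnames = list(paste0("g", 1:6),
                                                c("E", "K", "L", "T"))))
    ab <- matrix(rgamma(6 * 5, 1), 6, 5,
                 dimnames = list(paste0("g", 1:6), paste0("s", 1:5)))
    ab <- sweep(ab, 2, colSums(ab), "/")
    cats <- computeCATs(ab, f)
    ## every cell within the range of contributing genome fractions
    for (tr in colnames(f)) {
      expect_true(all(cats[, tr] >= min(f[, tr]) - 1e-12))
      expect_true(all(cats[, tr] <= max(f[, tr]) + 1e-12))
    }
    ## linearity: CAT of an abundance mixture = mixture of CATs
    w <- 0.3
    mix <- w * ab[, 1] + (1 - w) * ab[, 2]
    expect_equal(computeCATs(cbind(m = mix), f)[1, ],
                 w * cats[1, ] + (1 - w) * cats[2, ])
  }
})

test_that("level Z-scores standardise level means and flag constants", {
  cats <- cbind(tr = c(1, 1, 2, 2, 3, 3), const = rep(0.5, 6))
  rownames(cats) <- paste0("s", 1:6)
  expect_message(z <- zscoreLevelMeans(cats, rep(0:2, each = 2)),
                 "constant")
  expect_equal(unname(z$z[, "tr"]), c(-1, 0, 1))
  expect_equal(unname(z$z[, "const"]), c(0, 0, 0))
  expect_true(z$constant["const"])
  expect_equal(mean(z$z[, "tr"]), 0, tolerance = 1e-12)
  expect_equal(sd(z$z[, "tr"]), 1, tolerance = 1e-12)

  expect_error(zscoreLevelMeans(cats, rep(0, 6)), "two levels")
})

test_that("Welch's ANOVA matches a long-hand implementation", {
  ## identical value sets across groups: no between-group signal
  same <- genomeSizeWelchAnova(rep(c(1, 2, 3), 3), rep(c("C", "R", "S"),
                                                       each = 3))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)

  vals <- c(1, 2, 3, 2, 3, 4, 10, 11, 12)
  grp <- rep(c("C", "R", "S"), each = 3)
  got <- genomeSizeWelchAnova(vals, grp)
  ora <- welchOracle(vals, grp)
  expect_equal(got$F, ora$F, tolerance = 1e-10)
  expect_equal(got$df2, ora$df2, tolerance = 1e-10)
  expect_equal(got$p, ora$p, tolerance = 1e-10)

  ## two groups: F equals the square of Welch's t
  x <- c(1.2, 2.1, 3.3, 2.8); y <- c(4.5, 6.1, 5.2, 7.3, 6.6)
  two <- genomeSizeWelchAnova(c(x, y), rep(c("a", "b"), c(4, 5)))
  tt <- t.test(x, y)
  expect_equal(two$F, unname(tt$statistic)^2, tolerance = 1e-10)

  expect_error(genomeSizeWelchAnova(c(1, 1, 2, 3), rep(c("a", "b"), each = 2)),
               "a")
})
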