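test_that("square-root Bray-Curtis matches hand arithmetic and vegan", {
  x <- rbind(s1 = c(0.25, 0.75), s2 = c(1, 0), s3 = c(0.25, 0.75))
  D <- sqrtBrayCurtis(x)
  expect_equal(D["s1", "s3"], 0)
  expect_equal(D["s1", "s2"], 0.5774, tolerance = 1e-4)
  disjoint <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(sqrtBrayCurtis(disjoint)["a", "b"], 1)

  set.seed(10)
  y <- matrix(rpois(6 * 8, 20), 6, 8,
              dimnames = list(paste0("s", 1:6), NULL))
  Dv <- as.matrix(vegan::vegdist(sqrt(y / rowSums(y)), method = "bray"))
  expect_equal(unname(sqrtBrayCurtis(y)), unname(Dv), tolerance = 1e-10)

  bad <- rbind(ok = c(1, 2), zero = c(0, 0))
  expect_error(sqrtBrayCurtis(bad), "zero")
})

test_that("principal coordinates recover Euclidean configurations", {
  pts <- c(0, 1, 2)
  D <- as.matrix(dist(pts))
  pc <- principalCoordinates(D)
  expect_equal(length(pc$eigenvalues), 1L)
  ax <- pc$coordinates[, 1]
  expect_equal(sort(diff(sort(ax))), c(1, 1), tolerance = 1e-8,
               ignore_attr = TRUE)

  ## spectral conservation on a Bray-Curtis matrix with negative eigenvalues
  set.seed(11)
  y <- matrix(rpois(10 * 6, 5) + 1, 10, 6,
              dimnames = list(paste0("s", 1:10), NULL))
  Db <- sqrtBrayCurtis(y)
  pcb <- principalCoordinates(Db)
  expect_equal(sum(pcb$eigenvalues), sum(diag(pcb$G)), tolerance = 1e-8)

  zero <- matrix(0, 3, 3)
  expect_equal(length(principalCoordinates(zero)$eigenvalues), 0L)
  expect_error(principalCoordinates(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("PERMANOVA pseudo-F matches a long-hand partition and vegan", {
  ## printed toy distance matrix, two groups of three
  D <- matrix(0, 6, 6)
  vals <- c(0.12, 0.18, 0.75, 0.80, 0.15, 0.70, 0.78, 0.72, 0.77,
            0.10, 0.16, 0.14, 0.74, 0.70, 0.11)
  D[upper.tri(D)] <- vals
  D <- D + t(D)
  rownames(D) <- colnames(D) <- paste0("s", 1:6)
  grp <- rep(c("a", "b"), each = 3)

  ## long-hand sums-of-squares partition
  D2 <- D^2
  ssTot <- sum(D2[upper.tri(D2)]) / 6
  ssW <- sum(D2[1:3, 1:3][upper.tri(D2[1:3, 1:3])]) / 3 +
    sum(D2[4:6, 4:6][upper.tri(D2[4:6, 4:6])]) / 3
  Fhand <- ((ssTot - ssW) / 1) / (ssW / 4)
  res <- permanova(D, grp, nPerm = 999, seed = 2)
  expect_equal(res$statistic, Fhand, tolerance = 1e-8)

  fveg <- vegan::adonis2(as.dist(D) ~ grp, permutations = 2)$F[1]
  expect_equal(res$statistic, fveg, tolerance = 1e-8)

  ## exact enumeration over all 20 assignments of 3+3 labels
  Fs <- apply(combn(6, 3), 2, function(idx) {
    g <- rep("b", 6); g[idx] <- "a"
    csrtraits:::permanovaF(D2, factor(g))$F
  })
  exact <- mean(Fs >= res$statistic - 1e-12)
  expect_lt(abs(res$p - exact), 0.02)
  ## strong separation: p is the minimum achievable given ties
  expect_equal(exact, sum(Fs >= max(Fs) - 1e-12) / 20)

  expect_error(permanova(D, c("a", rep("b", 5)), nPerm = 99), "singleton")
})

test_that("PERMDISP detects dispersion differences and matches vegan", {
  ## rigid translation: equal dispersion by construction
  set.seed(12)
  cloud <- matrix(rnorm(8 * 2), 8, 2)
  pts <- rbind(cloud, cloud + 10)
  rownames(pts) <- paste0("s", 1:16)
  D <- as.matrix(dist(pts))
  grp <- rep(c("a", "b"), each = 8)
  res <- permdisp(D, grp, nPerm = 999, seed = 3)
  expect_lt(res$statistic, 1e-10)
  expect_gt(res$p, 0.9)

  ## doubled spread: observed F matches the centroid-distance ANOVA done
  ## long-hand in Euclidean space, and vegan::betadisper
  pts2 <- rbind(cloud, 2 * cloud + 10)
  D2 <- as.matrix(dist(pts2))
  res2 <- permdisp(D2, grp, nPerm = 999, seed = 4)
  zhand <- unlist(lapply(split(seq_len(16), grp), function(idx) {
    cen <- colMeans(pts2[idx, ])
    sqrt(rowSums(sweep(pts2[idx, ], 2, cen)^2))
  }))
  fit <- anova(lm(zhand ~ grp))
  Fhand <- fit$`F value`[1]
  expect_equal(res2$statistic, Fhand, tolerance = 1e-8)
  bd <- vegan::betadisper(as.dist(D2), grp, type = "centroid")
  expect_equal(res2$statistic, anova(bd)$`F value`[1], tolerance = 1e-6)
})

test_that("group-average similarity clustering cuts where expected", {
  D <- matrix(0.6, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  D[1, 2] <- D[2, 1] <- 0.05
  D[3, 4] <- D[4, 3] <- 0.05
  diag(D) <- 0
  cl <- upgmaClusters(D, threshold = 85)
  expect_equal(length(unique(cl)), 2L)
  expect_equal(cl["s1"], cl["s2"], ignore_attr = TRUE)
  expect_equal(cl["s3"], cl["s4"], ignore_attr = TRUE)

  expect_equal(length(unique(upgmaClusters(D, 99.9))), 4L)
  expect_equal(length(unique(upgmaClusters(D, 0.1))), 1L)
  expect_error(upgmaClusters(D, 0), "percentage")
})

test_that("CAP allocates well-separated groups and rejects degenerate input", {
  set.seed(13)
  pts <- rbind(matrix(rnorm(10 * 2, 0, 0.2), 10, 2),
               matrix(rnorm(10 * 2, 5, 0.2), 10, 2))
  rownames(pts) <- paste0("s", 1:20)
  D <- as.matrix(dist(pts))
  grp <- rep(c("a", "b"), each = 10)
  cap <- capOrdination(D, grp)
  expect_equal(cap$looSuccess, 1)
  expect_true(cap$m >= 1)

  expect_error(capOrdination(D, rep("a", 20)), "two groups")

  ## random labels: LOO success near chance (1/2)
  set.seed(14)
  succ <- replicate(10, {
    capOrdination(D, sample(grp), m = 2)$looSuccess
  })
  expect_lt(abs(mean(succ) - 0.5), 0.25)
})
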