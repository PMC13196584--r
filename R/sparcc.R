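## SparCC: estimation of basis correlations from compositional count data
## via log-ratio variances, robust to the compositionality artifact.
##
## Per resample, component fractions are drawn from a Dirichlet with the
## observed counts plus a 0.5 pseudocount per cell (which also replaces
## zeros before closure); the variation matrix t_ij = var(log(x_i/x_j)) is
## formed, basis variances are solved under the sparsity assumption, and
## the most strongly correlated pairs are iteratively excluded from the
## variance system. The final estimate is the element-wise median across
## resamples, with an exact unit diagonal.

## Solve basis variances omega^2 from the variation matrix T given an
## exclusion indicator matrix M (TRUE = pair participates).
## Row i equation: sum_{j in M_i} t_ij = (n_i - 1) w_i + sum_{j in M_i} w_j
sparccBasisVar <- function(Tm, M) {
  d <- nrow(Tm)
  A <- matrix(0, d, d)
  b <- numeric(d)
  for (i in seq_len(d)) {
    idx <- which(M[i, ] & seq_len(d) != i)
    A[i, i] <- length(idx)
    A[i, idx] <- A[i, idx] + 1
    b[i] <- sum(Tm[i, idx])
  }
  w <- tryCatch(solve(A, b), error = function(e) MASS::ginv(A) %*% b)
  pmax(as.numeric(w), 1e-12)
}

sparccCorFromVar <- function(Tm, w) {
  d <- length(w)
  W <- outer(w, w, "+")
  R <- (W - Tm) / (2 * sqrt(outer(w, w)))
  R[R > 1] <- 1; R[R < -1] <- -1
  diag(R) <- 1
  R
}

sparccOnce <- function(logx, exclusionIterations, exclusionThreshold) {
  d <- ncol(logx)
  Tm <- matrix(0, d, d)
  for (i in seq_len(d - 1L)) for (j in seq.int(i + 1L, d)) {
    Tm[i, j] <- Tm[j, i] <- var(logx[, i] - logx[, j])
  }
  M <- matrix(TRUE, d, d)
  w <- sparccBasisVar(Tm, M)
  R <- sparccCorFromVar(Tm, w)
  for (it in seq_len(exclusionIterations)) {
    Rabs <- abs(R); diag(Rabs) <- 0
    Rabs[!M] <- 0
    mx <- max(Rabs)
    if (mx <= exclusionThreshold) break
    k <- which(Rabs == mx, arr.ind = TRUE)[1L, ]
    M[k[1], k[2]] <- M[k[2], k[1]] <- FALSE
    ## guard: keep every component in at least 3 pair equations
    if (any(rowSums(M) - 1 < 3)) {
      M[k[1], k[2]] <- M[k[2], k[1]] <- TRUE
      break
    }
    w <- sparccBasisVar(Tm, M)
    R <- sparccCorFromVar(Tm, w)
  }
  R
}

#' SparCC compositional correlation estimate
#'
#' @param counts genome x sample count matrix (>= 4 genomes; every genome
#'   must occur in at least one sample), or a [CsrExperiment-class].
#' @param nResample number of Dirichlet resamples (default 20).
#' @param exclusionIterations maximum strongly-correlated-pair exclusions
#'   per resample (default 10).
#' @param exclusionThreshold pairs with `|rho|` above this are excluded
#'   from the basis-variance system (default 0.1).
#' @param seed integer seed.
#' @return genome x genome correlation matrix, diagonal exactly 1.
#' @export
sparccCorrelations <- function(counts, nResample = 20L,
                               exclusionIterations = 10L,
                               exclusionThreshold = 0.1, seed = 1L) {
  if (is(counts, "CsrExperiment")) counts <- assay(counts, "counts")
  x <- as.matrix(counts)
  stopIfNot(nrow(x) >= 4, "SparCC needs at least 4 genomes")
  stopIfNot(all(x >= 0), "counts must be non-negative")
  if (any(rowSums(x) == 0))
    stop("genomes absent from all samples: ",
         paste(rownames(x)[rowSums(x) == 0], collapse = ", "), call. = FALSE)
  d <- nrow(x); n <- ncol(x)
  est <- array(NA_real_, c(d, d, nResample))
  withSeed(seed, {
    for (b in seq_len(nResample)) {
      ## fractions ~ Dirichlet(counts + 0.5) per sample: zero replacement
      ## and closure in one step
      fr <- apply(x + 0.5, 2L, function(cnt) {
        gdraw <- rgamma(d, shape = cnt)
        gdraw / sum(gdraw)
      })
      est[, , b] <- sparccOnce(t(log(fr)), exclusionIterations,
                               exclusionThreshold)
    }
  })
  R <- apply(est, c(1, 2), median)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  dimnames(R) <- list(rownames(x), rownames(x))
  R
}
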