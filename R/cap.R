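## Canonical analysis of principal coordinates (CAP): discriminant analysis
## of a-priori groups on the leading PCoA axes, with the number of axes m
## chosen by leave-one-out allocation success.

capLoo <- function(U, groups) {
  ## leave-one-out allocation success of LDA on the given axes
  ok <- tryCatch({
    fit <- MASS::lda(U, grouping = groups, CV = TRUE)
    mean(fit$class == groups)
  }, error = function(e) NA_real_)
  ok
}

#' Canonical analysis of principal coordinates
#'
#' Embeds the dissimilarities with [principalCoordinates()], then runs a
#' canonical discriminant analysis of group membership on the first `m`
#' positive PCoA axes. When `m` is not given it is chosen to maximise
#' leave-one-out (LOO) allocation success, taking the smallest `m` on ties.
#'
#' @param D symmetric dissimilarity matrix.
#' @param groups group label per sample (>= 2 groups).
#' @param m number of PCoA axes to use; `NULL` (default) selects by LOO
#'   allocation success over `1..mMax`.
#' @param mMax largest m tried during selection (default `N - g - 1`,
#'   bounded by the number of positive eigenvalues).
#' @return list of class `OrdinationResult`: `scores` (canonical axis
#'   scores), `m`, `looSuccess`, `looTrace` (success per candidate m),
#'   `eigenvalues` (PCoA), `groups`, `lda` (the fitted discriminant).
#' @export
capOrdination <- function(D, groups, m = NULL, mMax = NULL) {
  D <- as.matrix(D)
  g <- factor(groups)
  stopIfNot(nlevels(g) >= 2, "CAP needs at least two groups")
  N <- nrow(D)
  stopIfNot(is.null(m) || (m >= 1 && m <= N - 1), "m must be in 1..N-1")
  pc <- principalCoordinates(D)
  U <- pc$coordinates[, !pc$negative, drop = FALSE]
  npos <- ncol(U)
  if (is.null(mMax)) mMax <- max(1L, min(npos, N - nlevels(g) - 1L))
  mMax <- min(mMax, npos)
  looTrace <- NULL
  if (is.null(m)) {
    looTrace <- vapply(seq_len(mMax), function(k)
      capLoo(U[, seq_len(k), drop = FALSE], g), numeric(1))
    cand <- which(looTrace == max(looTrace, na.rm = TRUE))
    m <- cand[1L]   # smallest m on ties
  }
  Um <- U[, seq_len(m), drop = FALSE]
  fit <- MASS::lda(Um, grouping = g)
  scores <- as.matrix(stats::predict(fit, Um)$x)
  rownames(scores) <- rownames(D)
  structure(list(scores = scores, m = m,
                 looSuccess = capLoo(Um, g), looTrace = looTrace,
                 eigenvalues = pc$eigenvalues, groups = g, lda = fit),
            class = "OrdinationResult")
}
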