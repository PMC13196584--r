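## Distance-based linear modelling (DistLM) with AICc stepwise selection,
## distance-based redundancy analysis (dbRDA), and Pearson correlation
## vector overlays.
##
## Partitioning follows McArdle & Anderson (2001): with the Gower-centered
## matrix G and the hat matrix H of the predictor set (intercept included),
## SS_explained = tr(H G H) and SS_residual = tr((I-H) G (I-H)); under
## Euclidean distances on a univariate response this reduces exactly to
## ordinary least squares.

hatMatrix <- function(X) {
  ## pseudoinverse-based hat matrix; tolerant of rank deficiency
  X %*% MASS::ginv(crossprod(X)) %*% t(X)
}

distlmFit <- function(G, X) {
  H <- hatMatrix(X)
  N <- nrow(G)
  ssExplained <- sum(diag(H %*% G %*% H))
  R <- diag(N) - H
  ssRes <- sum(diag(R %*% G %*% R))
  list(ssExplained = ssExplained, ssRes = ssRes, H = H)
}

## AICc = N ln(SS_res / N) + 2 v N / (N - v - 1); v = predictors + intercept.
## A non-positive residual trace (possible under semi-metric distances or a
## saturated fit) makes the criterion undefined; such models are ineligible.
distlmAicc <- function(N, ssRes, v) {
  if (!is.finite(ssRes) || ssRes <= 0 || v >= N - 1) return(Inf)
  N * log(ssRes / N) + 2 * v * N / (N - v - 1)
}

#' DistLM: distance-based linear modelling with AICc stepwise selection
#'
#' Partitions the variation of a dissimilarity matrix by numeric predictors
#' and selects a predictor subset by bidirectional stepwise search
#' (alternating the best single addition and the best single removal),
#' accepting only moves that strictly decrease the small-sample-corrected
#' Akaike information criterion, `AICc = N*ln(SS_res/N) + 2*v*N/(N-v-1)`
#' with `v` = number of fitted predictors + intercept.
#'
#' @param D symmetric dissimilarity matrix (N x N).
#' @param predictors numeric sample x predictor table, one row per sample
#'   in the order of `D`.
#' @param criterion selection criterion; only `"AICc"` is implemented.
#' @return list of class `DistLMModel`: `selected` (predictor names),
#'   `aicc`, `r2` (proportion of total variation explained), `ssExplained`,
#'   `ssRes`, `ssTotal`, `trace` (per-step data.frame), `marginal`
#'   (single-predictor R^2 per candidate), `predictors` (the selected
#'   columns), `G`.
#' @export
distlmStepwise <- function(D, predictors, criterion = "AICc") {
  criterion <- match.arg(criterion, "AICc")
  D <- as.matrix(D)
  X <- as.matrix(predictors)
  stopIfNot(is.numeric(X), "predictors must be numeric")
  stopIfNot(nrow(X) == nrow(D), "predictors must have one row per sample")
  if (is.null(colnames(X)))
    colnames(X) <- paste0("X", seq_len(ncol(X)))
  N <- nrow(D)
  G <- gowerCenter(D)
  ssTotal <- sum(diag(G))
  one <- matrix(1, N, 1)

  fitSubset <- function(sel) {
    Xs <- cbind(one, X[, sel, drop = FALSE])
    f <- distlmFit(G, Xs)
    v <- length(sel) + 1L
    list(aicc = distlmAicc(N, f$ssRes, v),
         ssExplained = f$ssExplained, ssRes = f$ssRes)
  }

  marginal <- vapply(colnames(X), function(p)
    fitSubset(p)$ssExplained / ssTotal, numeric(1))

  sel <- character()
  cur <- fitSubset(sel)
  trace <- data.frame(step = 0L, action = "start", predictor = NA_character_,
                      aicc = cur$aicc, stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    improved <- FALSE
    ## best single addition
    cand <- setdiff(colnames(X), sel)
    if (length(cand) && length(sel) + 2L < N - 1L) {
      fits <- lapply(cand, function(p) fitSubset(c(sel, p)))
      ai <- vapply(fits, `[[`, numeric(1), "aicc")
      if (min(ai) < cur$aicc - 1e-10) {
        k <- which.min(ai)
        sel <- c(sel, cand[k]); cur <- fits[[k]]
        step <- step + 1L; improved <- TRUE
        trace <- rbind(trace, data.frame(step = step, action = "add",
                                         predictor = cand[k],
                                         aicc = cur$aicc))
      }
    }
    ## best single removal
    if (length(sel)) {
      fits <- lapply(sel, function(p) fitSubset(setdiff(sel, p)))
      ai <- vapply(fits, `[[`, numeric(1), "aicc")
      if (min(ai) < cur$aicc - 1e-10) {
        k <- which.min(ai)
        drop_ <- sel[k]
        sel <- setdiff(sel, drop_); cur <- fits[[k]]
        step <- step + 1L; improved <- TRUE
        trace <- rbind(trace, data.frame(step = step, action = "remove",
                                         predictor = drop_,
                                         aicc = cur$aicc))
      }
    }
    if (!improved) break
  }
  structure(list(selected = sel, aicc = cur$aicc,
                 r2 = cur$ssExplained / ssTotal,
                 ssExplained = cur$ssExplained, ssRes = cur$ssRes,
                 ssTotal = ssTotal, trace = trace, marginal = marginal,
                 predictors = X[, sel, drop = FALSE], G = G),
            class = "DistLMModel")
}

#' dbRDA: distance-based redundancy analysis
#'
#' Eigen-analysis of the fitted component `H G H` of a distance-based
#' linear model, giving constrained ordination axes with the percent of
#' fitted and of total variation carried by each.
#'
#' @param D symmetric dissimilarity matrix.
#' @param predictors numeric sample x predictor matrix (e.g. the `predictors`
#'   of a fitted [distlmStepwise()] model); must be non-empty.
#' @return list of class `OrdinationResult`: `scores` (samples x constrained
#'   axes), `eigenvalues`, `pctFitted`, `pctTotal`, `ssExplained`,
#'   `ssTotal`.
#' @export
dbrda <- function(D, predictors) {
  D <- as.matrix(D)
  stopIfNot(!is.null(predictors) && NCOL(predictors) >= 1 &&
              length(predictors) > 0,
            "dbRDA needs a non-empty predictor set")
  X <- as.matrix(predictors)
  stopIfNot(nrow(X) == nrow(D), "predictors must have one row per sample")
  N <- nrow(D)
  G <- gowerCenter(D)
  H <- hatMatrix(cbind(matrix(1, N, 1), X))
  Gfit <- H %*% G %*% H
  e <- eigen((Gfit + t(Gfit)) / 2, symmetric = TRUE)
  keep <- e$values > 1e-9 * max(abs(e$values), .Machine$double.eps)
  lam <- e$values[keep]
  vec <- e$vectors[, keep, drop = FALSE]
  scores <- sweep(vec, 2L, sqrt(lam), "*")
  rownames(scores) <- rownames(D)
  colnames(scores) <- paste0("dbRDA", seq_along(lam))
  ssTotal <- sum(diag(G))
  structure(list(scores = scores, eigenvalues = lam,
                 pctFitted = 100 * lam / sum(lam),
                 pctTotal = 100 * lam / ssTotal,
                 ssExplained = sum(lam), ssTotal = ssTotal),
            class = "OrdinationResult")
}

#' Pearson correlation vectors for ordination overlays
#'
#' Correlates each variable with the first two (or `axes`) ordination axis
#' scores; a variable is kept when the length of its correlation vector,
#' `sqrt(sum(r^2))`, exceeds `rMin`. Constant variables are excluded.
#'
#' @param scores sample x axis score matrix.
#' @param variables sample x variable numeric table (same sample order).
#' @param rMin vector-length threshold in `[0, 1)` (default 0.20).
#' @param axes which axes to correlate against (default first two).
#' @return `data.frame` with `variable`, one `r_<axis>` column per axis and
#'   `length`; zero rows allowed.
#' @export
vectorOverlay <- function(scores, variables, rMin = 0.20,
                          axes = seq_len(min(2L, ncol(scores)))) {
  stopIfNot(rMin >= 0 && rMin < 1, "rMin must be in [0, 1)")
  S <- as.matrix(scores)[, axes, drop = FALSE]
  V <- as.matrix(variables)
  stopIfNot(nrow(V) == nrow(S), "scores and variables must share samples")
  keepVar <- apply(V, 2L, sd) > 0
  V <- V[, keepVar, drop = FALSE]
  if (ncol(V) == 0)
    return(data.frame(variable = character(), length = numeric()))
  r <- cor(V, S)
  len <- sqrt(rowSums(r^2))
  out <- data.frame(variable = colnames(V), r, length = len,
                    row.names = NULL, stringsAsFactors = FALSE)
  colnames(out)[1 + seq_along(axes)] <- paste0("r_", colnames(S))
  out[out$length > rMin, , drop = FALSE]
}
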