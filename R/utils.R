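## Internal helpers shared across modules.

#' Run code with a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded package
#' functions do not clobber the global random stream.
#' @noRd
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

## Deterministic fan-out of a master seed into per-stage child seeds.
## child_k = (seed * 7 + k * 10007) mod (2^31 - 1), always a valid R integer.
childSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.numeric(seed) * 7 + stage * 10007) %% 2147483647)
}

## Dirichlet draws, one row per replicate.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  ## guard against all-zero rows for tiny shapes
  x[x == 0 & rep(alpha, each = n) > 0] <- .Machine$double.xmin
  x / rowSums(x)
}

## Permutation p-value convention used throughout: (exceedances + 1)/(m + 1),
## ties counted as exceedances. Never returns 0.
permPval <- function(exceed, nPerm) (exceed + 1) / (nPerm + 1)

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

## canonical CSR label from a logical triple (C, R, S)
canonicalLabel <- function(c_, r_, s_) {
  lab <- paste0(if (c_) "C" else "", if (r_) "R" else "", if (s_) "S" else "")
  if (lab == "") "unassigned" else lab
}

#' The 19 default COG functional categories
#'
#' Single-letter Clusters of Orthologous Groups (COG) functional classes used
#' as the default trait alphabet. The set covers all categories named in the
#' trait-to-strategy table (Q, I, V, E, M, K, P, F, D, L, T, J) plus the
#' remaining well-populated classes, and excludes the rare or poorly
#' characterised ones (A, B, R, W, X, Y, Z). Configurable in every function
#' that consumes it.
#'
#' @return Character vector of 19 single-letter category codes.
#' @examples
#' cogCategories()
#' @export
cogCategories <- function() {
  c("C", "D", "E", "F", "G", "H", "I", "J", "K", "L",
    "M", "N", "O", "P", "Q", "S", "T", "U", "V")
}

#' Default trait-category to CSR strategy links
#'
#' The mapping between COG functional categories and the life-history
#' strategies whose genomes are expected to be enriched for them:
#' competitors invest in biosynthetic efficiency (secondary metabolites Q,
#' lipid metabolism I), ruderals in rapid metabolic activation (transcription
#' K, inorganic ion transport P), stress-tolerants in persistence and repair
#' (nucleotide metabolism F, cell cycle D, replication/repair L, signal
#' transduction T, translation J); amino-acid metabolism E and cell-envelope
#' biogenesis M span C and R, defense mechanisms V spans C and S.
#'
#' @return Named list mapping each linked category to a character vector of
#'   strategies (subset of `c("C","R","S")`).
#' @examples
#' defaultTraitStrategyMap()
#' @export
defaultTraitStrategyMap <- function() {
  list(Q = "C", I = "C",
       K = "R", P = "R",
       F = "S", D = "S", L = "S", T = "S", J = "S",
       E = c("C", "R"), M = c("C", "R"),
       V = c("C", "S"))
}

## categories linked to a given strategy under a trait->strategies map
categoriesForStrategy <- function(map, strategy) {
  names(map)[vapply(map, function(s) strategy %in% s, logical(1))]
}
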