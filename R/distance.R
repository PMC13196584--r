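## Distances, principal-coordinates embedding and group-average clustering.

#' Bray-Curtis dissimilarity on square-root transformed abundances
#'
#' Samples are closed to relative abundances, square-root transformed to
#' reduce the influence of dominant taxa, and compared with Bray-Curtis:
#' `BC(i, j) = sum_k |y_ik - y_jk| / sum_k (y_ik + y_jk)`.
#'
#' @param x sample x feature matrix of non-negative values (each sample row
#'   must have a positive total), or a [CsrExperiment-class] (samples taken
#'   from columns).
#' @param transform `"sqrt"` (default) or `"none"`.
#' @return symmetric `matrix` of dissimilarities in `[0, 1]`, zero diagonal.
#' @examples
#' x <- rbind(s1 = c(0.25, 0.75), s2 = c(1, 0))
#' sqrtBrayCurtis(x)["s1", "s2"]  # 0.5774
#' @export
sqrtBrayCurtis <- function(x, transform = c("sqrt", "none")) {
  transform <- match.arg(transform)
  if (is(x, "CsrExperiment")) x <- t(assay(x, "counts"))
  x <- as.matrix(x)
  stopIfNot(all(x >= 0), "abundances must be non-negative")
  tot <- rowSums(x)
  if (any(tot == 0))
    stop("samples with zero total: ",
         paste(rownames(x)[tot == 0], collapse = ", "), call. = FALSE)
  y <- x / tot
  if (transform == "sqrt") y <- sqrt(y)
  n <- nrow(y)
  D <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1L)) {
    yi <- y[i, ]
    for (j in seq.int(i + 1L, n)) {
      D[i, j] <- D[j, i] <-
        sum(abs(yi - y[j, ])) / sum(yi + y[j, ])
    }
  }
  D
}

## Gower-centered inner-product matrix G = -1/2 C D^2 C
gowerCenter <- function(D) {
  A <- -0.5 * D^2
  n <- nrow(A)
  rm_ <- rowMeans(A); cm_ <- colMeans(A); gm <- mean(A)
  sweep(sweep(A, 1L, rm_), 2L, cm_) + gm
}

#' Principal coordinates analysis (metric MDS)
#'
#' Eigen-decomposition of the Gower-centered matrix
#' `G = -1/2 * C %*% D^2 %*% C`. Coordinates are eigenvectors scaled by the
#' square root of the absolute eigenvalue; negative eigenvalues (semi-metric
#' distances such as Bray-Curtis) are retained and reported, with their axes
#' flagged as imaginary.
#'
#' @param D symmetric dissimilarity matrix with zero diagonal.
#' @param eps eigenvalues with `|lambda| < eps * max(|lambda|)` are treated
#'   as null and dropped.
#' @return list with `coordinates` (samples x axes, positive axes first),
#'   `eigenvalues` (all retained, decreasing), `negative` (logical per
#'   axis), `G`.
#' @export
principalCoordinates <- function(D, eps = 1e-9) {
  D <- as.matrix(D)
  stopIfNot(isSymmetric(unname(D), tol = 1e-8), "distance matrix must be symmetric")
  G <- gowerCenter(D)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  lam <- e$values
  keep <- abs(lam) > eps * max(abs(lam), .Machine$double.eps)
  lam <- lam[keep]
  vec <- e$vectors[, keep, drop = FALSE]
  if (length(lam) == 0L)
    return(list(coordinates = matrix(0, nrow(D), 0,
                                     dimnames = list(rownames(D), NULL)),
                eigenvalues = numeric(), negative = logical(), G = G))
  ord <- order(lam, decreasing = TRUE)
  lam <- lam[ord]; vec <- vec[, ord, drop = FALSE]
  coords <- sweep(vec, 2L, sqrt(abs(lam)), "*")
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PCo", seq_along(lam))
  list(coordinates = coords, eigenvalues = lam, negative = lam < 0, G = G)
}

#' Group-average (UPGMA) similarity clustering
#'
#' Agglomerates samples by average linkage on the dissimilarities and cuts
#' the tree at dissimilarity `1 - threshold/100`, the convention used for
#' similarity-ellipse groupings in constrained ordinations.
#'
#' @param D symmetric dissimilarity matrix.
#' @param threshold similarity percentage in (0, 100); e.g. 85 groups
#'   samples that are >= 85% similar on average.
#' @return named integer vector, sample -> cluster id.
#' @export
upgmaClusters <- function(D, threshold = 85) {
  stopIfNot(threshold > 0 && threshold < 100,
            "threshold must be a percentage in (0, 100)")
  h <- hclust(as.dist(D), method = "average")
  cutree(h, h = 1 - threshold / 100)
}
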