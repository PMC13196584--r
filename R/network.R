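## Thresholded positive-association networks, Louvain modules and
## module-to-regime dominance mapping.

#' Build a correlation network
#'
#' Undirected weighted graph with an edge for every genome pair whose
#' correlation meets the threshold (inclusive). Isolated nodes are
#' retained.
#'
#' @param R square symmetric correlation matrix with unit diagonal.
#' @param rMin edge threshold (default 0.20, inclusive).
#' @param positiveOnly keep edges with `rho >= rMin` (default); otherwise
#'   `|rho| >= rMin`.
#' @return an [igraph::igraph] graph with edge attribute `weight` (the
#'   correlation) and vertex names from the matrix.
#' @export
buildNetwork <- function(R, rMin = 0.20, positiveOnly = TRUE) {
  R <- as.matrix(R)
  stopIfNot(isSymmetric(unname(R), tol = 1e-8),
            "correlation matrix must be symmetric")
  A <- if (positiveOnly) (R >= rMin) else (abs(R) >= rMin)
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           diag = FALSE)
  ew <- R[igraph::as_edgelist(g, names = FALSE)]
  igraph::E(g)$weight <- ew
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- rownames(R) %||% paste0("n", seq_len(nrow(R)))
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate Newman's modularity Q for a given partition
#'
#' Independent evaluator of
#' `Q = (1/2m) sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j)` on a weighted
#' undirected graph; used to verify the partition returned by
#' [louvainModules()].
#'
#' @param graph an igraph graph (edge weights used if present).
#' @param membership integer/character module id per vertex.
#' @return numeric Q.
#' @export
modularityQ <- function(graph, membership) {
  A <- igraph::as_adjacency_matrix(graph, attr =
         if ("weight" %in% igraph::edge_attr_names(graph)) "weight" else NULL,
         sparse = FALSE)
  k <- rowSums(A)
  m2 <- sum(A)           # 2m
  if (m2 == 0) return(0)
  same <- outer(membership, membership, "==")
  sum((A - outer(k, k) / m2) * same) / m2
}

#' Louvain module detection
#'
#' Multi-level greedy modularity optimisation on the weighted graph;
#' deterministic given the seed. An edgeless graph yields one module per
#' node with `Q = 0` and a warning.
#'
#' @param graph an igraph graph.
#' @param resolution resolution parameter (default 1).
#' @param seed integer seed.
#' @return list with `membership` (named integer per vertex) and `Q`
#'   (modularity of the returned partition, computed with [modularityQ()]).
#' @export
louvainModules <- function(graph, resolution = 1, seed = 1L) {
  if (igraph::ecount(graph) == 0) {
    warning("edgeless graph: every node is its own module, Q = 0")
    mem <- seq_len(igraph::vcount(graph))
    names(mem) <- igraph::V(graph)$name
    return(list(membership = mem, Q = 0))
  }
  withSeed(seed, {
    cl <- igraph::cluster_louvain(graph, resolution = resolution)
  })
  mem <- igraph::membership(cl)
  mem <- setNames(as.integer(mem), igraph::V(graph)$name)
  list(membership = mem, Q = modularityQ(graph, mem))
}

#' Map network modules to their dominant disturbance regime
#'
#' For each module, member relative abundances are summed per sample and
#' averaged per regime; the module is labelled with the regime of maximal
#' mean. Exact ties are broken by regime order (undisturbed < intermediate
#' < press) and flagged.
#'
#' @param membership named module id per genome (from [louvainModules()]).
#' @param abundance genome x sample relative abundance matrix (columns sum
#'   to 1), or a [CsrExperiment-class].
#' @param regimes regime per sample (taken from the object when omitted).
#' @return `data.frame` with `module`, `regime`, `margin` (difference
#'   between best and second-best regime mean), `tie` (logical).
#' @export
moduleRegimeAssociation <- function(membership, abundance, regimes = NULL) {
  if (is(abundance, "CsrExperiment")) {
    if (is.null(regimes)) regimes <- as.character(sampleRegimes(abundance))
    abundance <- relAbundance(abundance)
  }
  p <- as.matrix(abundance)
  stopIfNot(!is.null(names(membership)), "membership must be named")
  miss <- setdiff(names(membership), rownames(p))
  if (length(miss))
    stop("module genomes absent from abundance table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  stopIfNot(length(regimes) == ncol(p), "one regime per sample is required")
  rg <- factor(regimes, levels = regimeOrder())
  mods <- sort(unique(membership))
  out <- lapply(mods, function(mo) {
    members <- names(membership)[membership == mo]
    stopIfNot(length(members) > 0, "empty module")
    tot <- colSums(p[members, , drop = FALSE])
    mu <- tapply(tot, rg, mean)
    mu <- mu[!is.na(mu)]
    best <- max(mu)
    winners <- names(mu)[mu >= best - 1e-15]
    winner <- intersect(regimeOrder(), winners)[1L]
    margin <- if (length(mu) > 1) best - max(mu[names(mu) != winner]) else NA_real_
    data.frame(module = mo, regime = winner, margin = margin,
               tie = length(winners) > 1, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Export a network as GraphML and an edge list
#'
#' Writes the graph in GraphML and as a tab-separated edge list, with an
#' optional module table and Fruchterman-Reingold layout coordinates for
#' plotting parity with external tools (cosmetic only).
#'
#' @param graph an igraph graph.
#' @param dir output directory (created if needed).
#' @param membership optional module ids to include.
#' @param layout logical; write FR layout coordinates (seeded).
#' @param seed seed for the layout.
#' @return invisibly, the paths written.
#' @export
exportNetwork <- function(graph, dir, membership = NULL, layout = TRUE,
                          seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(membership))
    igraph::V(graph)$module <- as.integer(membership[igraph::V(graph)$name])
  paths <- c(graphml = file.path(dir, "network.graphml"),
             edges = file.path(dir, "edges.tsv"))
  igraph::write_graph(graph, paths["graphml"], format = "graphml")
  el <- igraph::as_data_frame(graph, what = "edges")
  write.table(el, paths["edges"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(membership)) {
    paths["modules"] <- file.path(dir, "modules.tsv")
    write.table(data.frame(genome = names(membership),
                           module = as.integer(membership)),
                paths["modules"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (layout && igraph::vcount(graph) > 0) {
    withSeed(seed, {
      xy <- igraph::layout_with_fr(graph)
    })
    paths["layout"] <- file.path(dir, "layout.tsv")
    write.table(data.frame(genome = igraph::V(graph)$name,
                           x = xy[, 1], y = xy[, 2]),
                paths["layout"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(paths)
}
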