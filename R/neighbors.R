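#' Exact k-nearest-neighbor graph in PCA space
#'
#' Builds the k-nearest-neighbor graph (Euclidean distance, exact brute
#' force) over nuclei in the embedding. Ties in distance are broken by the
#' lower nucleus index, deterministically.
#'
#' @param embedding Nuclei-by-components numeric matrix.
#' @param k Number of neighbors per nucleus (default 20; must be < n).
#' @return A list of class `sn_knn`: `idx` (n x k neighbor index matrix),
#'   `dist` (matching distances), `graph` (undirected igraph, unique edges),
#'   `k`.
#' @export
build_neighbor_graph <- function(embedding, k = 20) {
  n <- nrow(embedding)
  if (k >= n) stop_config("k (%d) must be smaller than n_nuclei (%d)", k, n)
  d <- as.matrix(stats::dist(embedding))
  idx <- matrix(0L, n, k)
  ndist <- matrix(0, n, k)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))   # distance, then index: deterministic
    ord <- ord[ord != i][seq_len(k)]
    idx[i, ] <- ord
    ndist[i, ] <- d[i, ord]
  }
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(idx)))
  edges <- unique(t(apply(edges, 1L, sort)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  structure(list(idx = idx, dist = ndist, graph = g, k = k, n = n),
            class = "sn_knn")
}

#' Community detection on a neighbor graph
#'
#' Modularity-based Leiden community detection at a given resolution. This
#' is substitutable plumbing feeding cell typing: any function returning a
#' label per nucleus for a graph can be plugged in via `method`.
#'
#' @param graph An `sn_knn` object from [build_neighbor_graph()] or an
#'   igraph graph.
#' @param resolution Resolution parameter (default 0.5); lower values give
#'   fewer, larger communities.
#' @param seed Integer seed for the (stochastic) refinement.
#' @param method A function `f(igraph, resolution)` returning integer
#'   labels, or `NULL` for the built-in Leiden call.
#' @return Integer cluster labels (1-based), one per nucleus.
#' @export
detect_communities <- function(graph, resolution = 0.5, seed = 1,
                               method = NULL) {
  g <- if (inherits(graph, "sn_knn")) graph$graph else graph
  if (igraph::vcount(g) == 0) stop_config("empty graph")
  set_seed_strict(seed)
  if (is.function(method)) {
    labels <- method(g, resolution)
  } else {
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5)
    labels <- igraph::membership(cl)
  }
  as.integer(as.integer(factor(labels)))
}
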