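#' Distinguishing HVGs per cluster with leave-one-fold-out validation
#'
#' For every cluster, finds the genes significantly overexpressed versus all
#' other clusters combined in each of k leave-one-fold-out computations.
#' Nuclei are split into k random folds stratified by cluster; for each
#' computation one fold is left out and a one-vs-rest two-sided Wilcoxon
#' rank-sum test (normal approximation with tie correction) is applied to
#' total-count-normalized (median-total target), log1p-transformed data with
#' Benjamini-Hochberg correction across genes within a cluster. A gene is a
#' distinguishing HVG if in all k computations it is overexpressed with
#' `l2fc > l2fc_min` and adjusted p < `alpha`; its stored l2fc is the
#' cross-fold mean.
#'
#' @param counts Nuclei-by-genes count matrix.
#' @param cluster_labels Cluster label per nucleus.
#' @param k Number of folds (default 10); every cluster must have >= k nuclei.
#' @param l2fc_min Minimum log2 fold change (default 1.0).
#' @param alpha Adjusted-p threshold (default 0.01).
#' @param seed Integer seed for the fold split.
#' @return A named list of class `sn_cluster_profiles`, one entry per
#'   cluster, each with `cluster`, `n_nuclei`, and `hvgs` (data frame:
#'   `gene`, `mean_l2fc`, `max_adj_p`). The gene universe is attached as an
#'   attribute.
#' @export
find_distinguishing_hvgs <- function(counts, cluster_labels, k = 10,
                                     l2fc_min = 1.0, alpha = 0.01, seed = 1) {
  cluster_labels <- as.character(cluster_labels)
  if (length(cluster_labels) != nrow(counts)) {
    stop_config("cluster_labels length != number of nuclei")
  }
  sizes <- table(cluster_labels)
  if (any(sizes < k)) {
    small <- names(sizes)[which.min(sizes)]
    stop_config(paste0(
      "cluster '%s' has %d < k = %d nuclei; use a smaller k"),
      small, min(sizes), k)
  }
  set_seed_strict(seed)
  folds <- integer(length(cluster_labels))
  for (cl in names(sizes)) {
    idx <- which(cluster_labels == cl)
    folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  lognorm <- normalize_total(counts)
  lognorm <- methods::as(methods::as(lognorm, "generalMatrix"),
                         "CsparseMatrix")
  lognorm@x <- log1p(lognorm@x)
  genes <- colnames(counts) %||% as.character(seq_len(ncol(counts)))
  clusters <- names(sizes)
  pass <- array(FALSE, dim = c(length(clusters), length(genes), k),
                dimnames = list(clusters, genes, NULL))
  l2fc_store <- array(NA_real_, dim = dim(pass), dimnames = dimnames(pass))
  adjp_store <- array(NA_real_, dim = dim(pass), dimnames = dimnames(pass))
  for (f in seq_len(k)) {
    keep <- folds != f
    x <- as.matrix(lognorm[keep, , drop = FALSE])
    lab <- cluster_labels[keep]
    nn <- nrow(x)
    rk <- apply(x, 2L, rank)
    tie_term <- vapply(seq_len(ncol(x)), function(j) {
      t <- rle(sort(x[, j]))$lengths
      sum(t^3 - t)
    }, numeric(1))
    for (cl in clusters) {
      inc <- lab == cl
      n1 <- sum(inc)
      n2 <- nn - n1
      r1 <- colSums(rk[inc, , drop = FALSE])
      mu <- n1 * (nn + 1) / 2
      sig2 <- n1 * n2 / 12 * ((nn + 1) - tie_term / (nn * (nn - 1)))
      z <- (r1 - mu) / sqrt(pmax(sig2, 1e-12))
      p <- 2 * pnorm(-abs(z))
      adj <- bh_adjust(p)
      mean_in <- colMeans(x[inc, , drop = FALSE])
      mean_out <- colMeans(x[!inc, , drop = FALSE])
      l2fc <- log2((expm1(mean_in) + 1e-9) / (expm1(mean_out) + 1e-9))
      ok <- z > 0 & l2fc > l2fc_min & adj < alpha
      pass[cl, , f] <- ok
      l2fc_store[cl, , f] <- l2fc
      adjp_store[cl, , f] <- adj
    }
  }
  profiles <- lapply(clusters, function(cl) {
    all_folds <- apply(pass[cl, , , drop = FALSE], 2L, all)
    sel <- which(all_folds)
    hv <- data.frame(
      gene = genes[sel],
      mean_l2fc = if (length(sel)) {
        rowMeans(matrix(l2fc_store[cl, sel, ], nrow = length(sel)))
      } else numeric(0),
      max_adj_p = if (length(sel)) {
        apply(matrix(adjp_store[cl, sel, ], nrow = length(sel)), 1L, max)
      } else numeric(0),
      stringsAsFactors = FALSE)
    hv <- hv[order(-hv$mean_l2fc), , drop = FALSE]
    rownames(hv) <- NULL
    structure(list(cluster = cl, n_nuclei = unname(sizes[cl]), hvgs = hv),
              class = "sn_cluster_profile")
  })
  names(profiles) <- clusters
  structure(profiles, class = "sn_cluster_profiles", universe = genes, k = k)
}

#' Marker-database log-likelihood scores for a cluster profile
#'
#' The log-likelihood that a cluster is of a given cell type is the sum,
#' over the type's positive marker genes, of the cluster's stored mean l2fc
#' if the marker is a distinguishing HVG, and 0 otherwise. No
#' cell-type-specificity or other weighting is applied. With
#' `use_negative = TRUE` the analogous sum over negative markers is
#' subtracted. Marker genes absent from the matrix's gene universe
#' contribute 0 and are reported in the `missing` attribute.
#'
#' @param profile An `sn_cluster_profile` (one entry of
#'   [find_distinguishing_hvgs()] output).
#' @param db Marker database (named list with `positive`/`negative` vectors).
#' @param use_negative Subtract negative-marker contributions
#'   (default `FALSE`).
#' @param universe Optional gene universe; defaults to the profile's.
#' @return Named numeric vector of log-likelihoods per cell type, with
#'   attributes `contributing` (number of positive markers that are
#'   distinguishing HVGs per type) and `missing` (markers outside the
#'   universe).
#' @export
loglikelihood_scores <- function(profile, db, use_negative = FALSE,
                                 universe = NULL) {
  if (length(db) == 0) stop_config("marker database is empty")
  universe <- universe %||% attr(profile, "universe")
  hv <- setNames(profile$hvgs$mean_l2fc, profile$hvgs$gene)
  score_set <- function(markers) {
    sum(hv[intersect(markers, names(hv))])
  }
  ll <- numeric(length(db))
  contributing <- integer(length(db))
  missing <- character(0)
  for (i in seq_along(db)) {
    pos <- db[[i]]$positive %||% character(0)
    ll[i] <- score_set(pos)
    contributing[i] <- length(intersect(pos, names(hv)))
    if (!is.null(universe)) {
      missing <- c(missing, setdiff(pos, universe))
    }
    if (use_negative) {
      neg <- db[[i]]$negative %||% character(0)
      ll[i] <- ll[i] - score_set(neg)
      if (!is.null(universe)) missing <- c(missing, setdiff(neg, universe))
    }
  }
  names(ll) <- names(db)
  names(contributing) <- names(db)
  structure(ll, contributing = contributing, missing = unique(missing))
}

#' Assign cell types to cluster profiles
#'
#' Each cluster receives the cell type with the maximal log-likelihood
#' score. Clusters whose scores are all zero are labeled `"unassigned"`.
#' Ties are broken by the larger number of contributing markers, then
#' lexicographically, and flagged.
#'
#' @param profiles Output of [find_distinguishing_hvgs()].
#' @param db Marker database.
#' @param use_negative Passed to [loglikelihood_scores()].
#' @return A data frame of class `sn_cell_type_assignment`: `cluster`,
#'   `cell_type`, `ll`, `n_contributing`, `tie`; the full score matrix is
#'   attached as attribute `scores`.
#' @export
assign_cell_types <- function(profiles, db, use_negative = FALSE) {
  if (length(db) == 0) stop_config("marker database is empty")
  universe <- attr(profiles, "universe")
  rows <- lapply(profiles, function(pr) {
    ll <- loglikelihood_scores(pr, db, use_negative, universe = universe)
    contrib <- attr(ll, "contributing")
    if (all(ll == 0)) {
      return(data.frame(cluster = pr$cluster, cell_type = "unassigned",
                        ll = 0, n_contributing = 0L, tie = FALSE,
                        stringsAsFactors = FALSE))
    }
    best <- which(ll == max(ll))
    tie <- length(best) > 1
    if (tie) {
      best <- best[order(-contrib[best], names(ll)[best])]
    }
    data.frame(cluster = pr$cluster, cell_type = names(ll)[best[1]],
               ll = unname(ll[best[1]]),
               n_contributing = unname(contrib[best[1]]), tie = tie,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  scores <- do.call(rbind, lapply(profiles, function(pr) {
    as.numeric(loglikelihood_scores(pr, db, use_negative,
                                    universe = universe))
  }))
  dimnames(scores) <- list(names(profiles), names(db))
  attr(out, "scores") <- scores
  class(out) <- c("sn_cell_type_assignment", class(out))
  out
}

#' Merge contiguous same-type clusters and subcluster listed targets
#'
#' Two refinement rounds over an initial clustering: (1) clusters assigned
#' the same cell type that are contiguous in the nearest-neighbor graph
#' (sharing at least `contig_frac` of the smaller cluster's neighbor edges)
#' are merged; (2) each cluster listed in `subcluster_targets` (by its
#' post-merge label) is re-clustered in isolation at low resolution; then
#' cell typing is re-run on the final labels through the same likelihood
#' pipeline.
#'
#' @param counts Nuclei-by-genes count matrix.
#' @param cluster_labels Initial cluster label per nucleus.
#' @param assignments Output of [assign_cell_types()] for those labels.
#' @param db Marker database.
#' @param embedding PCA embedding used for the neighbor graph and
#'   subclustering.
#' @param subcluster_targets Character vector of post-merge cluster labels
#'   to subcluster (config input; default none).
#' @param resolution Leiden resolution for subclustering (default 0.1).
#' @param knn_k Neighbors for the contiguity graph (default 20).
#' @param contig_frac Edge-share threshold defining contiguity
#'   (default 0.01).
#' @param k,l2fc_min,alpha,seed Passed to [find_distinguishing_hvgs()] for
#'   the re-typing round.
#' @return A list of class `sn_refinement`: `labels` (final label per
#'   nucleus), `assignments` (re-typing result), `merges` (old -> merged
#'   label map).
#' @export
refine_clusters <- function(counts, cluster_labels, assignments, db,
                            embedding, subcluster_targets = NULL,
                            resolution = 0.1, knn_k = 20, contig_frac = 0.01,
                            k = 10, l2fc_min = 1.0, alpha = 0.01, seed = 1) {
  labels <- as.character(cluster_labels)
  knn <- build_neighbor_graph(embedding, k = min(knn_k, nrow(embedding) - 1))
  # cluster-level contiguity from the directed kNN edge lists
  from <- rep(labels, each = knn$k)
  to <- labels[as.vector(t(knn$idx))]
  cross <- from != to
  etab <- table(from[cross], to[cross])
  sizes <- table(labels)
  type_of <- setNames(assignments$cell_type, assignments$cluster)
  cls <- names(sizes)
  gm <- igraph::make_empty_graph(n = length(cls), directed = FALSE)
  igraph::V(gm)$name <- cls
  for (a in cls) for (b in cls) {
    if (a < b && type_of[a] == type_of[b] && type_of[a] != "unassigned") {
      eab <- 0
      if (a %in% rownames(etab) && b %in% colnames(etab)) {
        eab <- eab + etab[a, b]
      }
      if (b %in% rownames(etab) && a %in% colnames(etab)) {
        eab <- eab + etab[b, a]
      }
      frac <- eab / (knn$k * 2 * min(sizes[a], sizes[b]))
      if (frac >= contig_frac) gm <- igraph::add_edges(gm, c(a, b))
    }
  }
  comp <- igraph::components(gm)$membership
  merged_name <- vapply(seq_len(max(comp)), function(m) {
    members <- names(comp)[comp == m]
    members[1]
  }, character(1))
  merge_map <- setNames(merged_name[comp], names(comp))
  labels <- unname(merge_map[labels])
  # subcluster the listed targets in isolation
  for (tg in subcluster_targets %||% character(0)) {
    rows <- which(labels == tg)
    if (!length(rows)) stop_config("subcluster target '%s' not found", tg)
    sub_emb <- embedding[rows, , drop = FALSE]
    sub_knn <- build_neighbor_graph(sub_emb,
                                    k = min(knn_k, length(rows) - 1))
    sub_lab <- detect_communities(sub_knn, resolution = resolution,
                                  seed = derive_seed(seed, match(tg, subcluster_targets)))
    labels[rows] <- paste0(tg, ".", sub_lab)
  }
  profiles <- find_distinguishing_hvgs(counts, labels, k = k,
                                       l2fc_min = l2fc_min, alpha = alpha,
                                       seed = seed)
  new_assign <- assign_cell_types(profiles, db)
  structure(list(labels = labels, assignments = new_assign,
                 merges = merge_map),
            class = "sn_refinement")
}
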