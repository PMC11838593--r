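#' Per-donor mean normalized expression of DEGs
#'
#' For each differentially expressed gene of each cell type of interest,
#' computes its mean normalized expression (per-nucleus total-count scaling
#' to the median nucleus total) across all of that cell type's nuclei, per
#' case donor. Rows are labeled `cell-type_direction_gene` so that the same
#' gene appearing as a DEG in two cell types yields two distinct rows.
#' Donors without nuclei of a row's cell type get a missing value (dropped
#' pairwise in the correlation step) and are reported.
#'
#' @param counts Nuclei-by-genes count matrix.
#' @param nuclei Nucleus annotations with `donor` and `cell_type`.
#' @param degs Data frame with columns `cell_type`, `gene`, `direction`
#'   (`"up"`/`"down"`).
#' @param case_donors Character vector of case-group donor ids.
#' @return Numeric DEG-by-donor matrix with labeled rows; missing entries
#'   are `NA`.
#' @export
donor_mean_expression <- function(counts, nuclei, degs, case_donors) {
  absent <- setdiff(degs$gene, colnames(counts))
  if (length(absent)) {
    stop_config("DEG gene(s) absent from the matrix: %s",
                paste(head(absent, 5), collapse = ", "))
  }
  norm <- normalize_total(counts)
  labels <- paste(degs$cell_type, degs$direction, degs$gene, sep = "_")
  out <- matrix(NA_real_, nrow = nrow(degs), ncol = length(case_donors),
                dimnames = list(labels, case_donors))
  missing_pairs <- character(0)
  for (ct in unique(degs$cell_type)) {
    ct_rows <- which(degs$cell_type == ct)
    for (d in case_donors) {
      nuc <- which(nuclei$donor == d & nuclei$cell_type == ct)
      if (!length(nuc)) {
        missing_pairs <- c(missing_pairs, paste0(d, ":", ct))
        next
      }
      sub <- norm[nuc, degs$gene[ct_rows], drop = FALSE]
      out[ct_rows, d] <- Matrix::colMeans(sub)
    }
  }
  if (length(missing_pairs)) {
    message(sprintf("missing donor x cell-type entries (NA): %s",
                    paste(unique(missing_pairs), collapse = ", ")))
  }
  out
}

#' Significance-gated similarity and distance between DEG pairs
#'
#' Cross-donor Pearson correlations of DEG mean expression, with the
#' two-tailed test at level `p_threshold`; the similarity of a DEG pair is
#' the correlation magnitude if significant and 0 otherwise:
#' `sim = |r|` if `p < 0.05` else `0`. Distances for clustering are
#' `dist = 1 / (1 + sim)`, a strictly decreasing map from sim in `[0, 1]`
#' onto `[0.5, 1]` whose nonlinearity compresses the dynamic range so only
#' pronounced similarity separates clusters. Correlations use
#' pairwise-complete donors with a minimum of `min_donors` shared; rows
#' without variance get sim 0 and are flagged.
#'
#' @param expr DEG-by-donor matrix from [donor_mean_expression()].
#' @param p_threshold Significance level (default 0.05).
#' @param min_donors Minimum shared donors per pair (default 3).
#' @return A list of class `sn_coord_graph`: `r`, `p`, `sim`, `dist`
#'   (square matrices), `labels`, `degenerate` (zero-variance rows).
#' @export
similarity_matrix <- function(expr, p_threshold = 0.05, min_donors = 3) {
  n <- nrow(expr)
  if (n < 2) stop_config("need at least 2 DEG rows")
  labels <- rownames(expr) %||% as.character(seq_len(n))
  r <- p <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  degenerate <- logical(n)
  for (i in seq_len(n)) {
    xi <- expr[i, ]
    if (sd(xi, na.rm = TRUE) == 0 || sum(!is.na(xi)) < min_donors) {
      degenerate[i] <- TRUE
    }
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(expr[i, ]) & !is.na(expr[j, ])
      m <- sum(ok)
      if (m < min_donors || degenerate[i] || degenerate[j]) next
      xi <- expr[i, ok]
      xj <- expr[j, ok]
      if (sd(xi) == 0 || sd(xj) == 0) next
      rij <- cor(xi, xj)
      r[i, j] <- r[j, i] <- rij
      # two-tailed test of Pearson r (t form; identical to the
      # beta-assumption p-value for bivariate-normal data)
      tt <- rij * sqrt((m - 2) / max(1 - rij^2, 1e-15))
      p[i, j] <- p[j, i] <- 2 * pt(-abs(tt), df = m - 2)
    }
  }
  sim <- ifelse(!is.na(r) & !is.na(p) & p < p_threshold, abs(r), 0)
  diag(sim) <- 1
  dist <- 1 / (1 + sim)
  structure(list(r = r, p = p, sim = sim, dist = dist, labels = labels,
                 degenerate = setNames(degenerate, labels),
                 p_threshold = p_threshold),
            class = "sn_coord_graph")
}

#' Hierarchical clustering of DEGs with dendrogram-order splitting
#'
#' Average-linkage agglomerative clustering on the significance-gated
#' distances, cut at `initial_cut` to form initial DEG clusters; within each
#' initial cluster, DEGs are ordered by dendrogram leaf order, the pairwise
#' distance between each adjacent leaf pair is computed, and the cluster is
#' split wherever that distance is at least `split_sd` standard deviations
#' above the cluster's mean adjacent distance. Subclusters are named
#' `C<cluster>S<subcluster>` (subcluster index 0-based, in leaf order) and a
#' subcluster is retained when its mean pairwise similarity is at least
#' `min_mean_sim`. Singletons have undefined mean similarity and are never
#' retained.
#'
#' @param graph An `sn_coord_graph` from [similarity_matrix()].
#' @param initial_cut Linkage-distance tree cut defining initial clusters
#'   (default 0.95, i.e. clusters merge while average similarity exceeds
#'   about 0.05).
#' @param split_sd Split threshold in SD units (default 3.0).
#' @param min_mean_sim Retention threshold on mean pairwise similarity
#'   (default 0.75).
#' @return A list of class `sn_subclusters`: `table` (data frame: `name`,
#'   `cluster`, `n`, `mean_sim`, `retained`), `members` (named list of DEG
#'   labels), `assignment` (subcluster name per DEG), `hclust`.
#' @export
cluster_and_split <- function(graph, initial_cut = 0.95, split_sd = 3.0,
                              min_mean_sim = 0.75) {
  labels <- graph$labels
  n <- length(labels)
  if (n < 2) {
    tab <- data.frame(name = "C1S0", cluster = 1L, n = n,
                      mean_sim = NA_real_, retained = FALSE,
                      stringsAsFactors = FALSE)
    return(structure(list(table = tab,
                          members = setNames(list(labels), "C1S0"),
                          assignment = setNames(rep("C1S0", n), labels),
                          hclust = NULL),
                     class = "sn_subclusters"))
  }
  d <- graph$dist
  hc <- hclust(as.dist(d), method = "average")
  initial <- cutree(hc, h = initial_cut)
  leaf_order <- hc$order
  assignment <- setNames(rep(NA_character_, n), labels)
  rows <- list()
  members <- list()
  # clusters numbered by order of first appearance along the dendrogram
  cluster_seq <- unique(initial[leaf_order])
  for (ci in seq_along(cluster_seq)) {
    cl <- cluster_seq[ci]
    leaves <- leaf_order[initial[leaf_order] == cl]
    segs <- list(leaves)
    if (length(leaves) > 2) {
      adj <- vapply(seq_len(length(leaves) - 1), function(i) {
        d[leaves[i], leaves[i + 1]]
      }, numeric(1))
      cutpts <- integer(0)
      if (length(adj) >= 2 && sd(adj) > 0) {
        thr <- mean(adj) + split_sd * sd(adj)
        cutpts <- which(adj >= thr)
      }
      if (length(cutpts)) {
        bounds <- c(0, cutpts, length(leaves))
        segs <- lapply(seq_len(length(bounds) - 1), function(b) {
          leaves[(bounds[b] + 1):bounds[b + 1]]
        })
      }
    }
    for (si in seq_along(segs)) {
      nm <- sprintf("C%dS%d", ci, si - 1)
      seg <- segs[[si]]
      ms <- if (length(seg) > 1) {
        sm <- graph$sim[seg, seg]
        mean(sm[upper.tri(sm)])
      } else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        name = nm, cluster = ci, n = length(seg), mean_sim = ms,
        retained = !is.na(ms) && ms >= min_mean_sim,
        stringsAsFactors = FALSE)
      members[[nm]] <- labels[seg]
      assignment[labels[seg]] <- nm
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, members = members, assignment = assignment,
                 hclust = hc, initial_cut = initial_cut,
                 split_sd = split_sd, min_mean_sim = min_mean_sim),
            class = "sn_subclusters")
}

#' @export
print.sn_subclusters <- function(x, ...) {
  cat(sprintf("%d DEG subcluster(s), %d retained (mean pairwise sim >= %g)\n",
              nrow(x$table), sum(x$table$retained), x$min_mean_sim))
  print(x$table)
  invisible(x)
}
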