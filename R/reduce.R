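#' Rank highly variable genes by standardized variance
#'
#' Seurat-v3-style ("vst") HVG ranking: a local polynomial trend of
#' log10(variance) on log10(mean) is fit across expressed genes (loess,
#' span 0.3), counts are standardized per gene by the trend-predicted
#' standard deviation with clipping at `sqrt(n)`, and genes are ranked by
#' the variance of the clipped standardized values. Constant or all-zero
#' genes score 0 and fall to the bottom in stable (input) order.
#'
#' @param counts Nuclei-by-genes count matrix (sparse supported).
#' @param span Loess span of the mean-variance trend (default 0.3).
#' @return A data frame of class `sn_hvg_ranking`, one row per gene ordered
#'   by decreasing standardized variance, with columns `gene`, `mean`,
#'   `variance`, `score`, `rank`.
#' @export
rank_hvgs <- function(counts, span = 0.3) {
  n <- nrow(counts)
  if (n < 2) stop_config("HVG ranking needs at least 2 nuclei")
  genes <- colnames(counts) %||% as.character(seq_len(ncol(counts)))
  mu <- Matrix::colMeans(counts)
  ex2 <- Matrix::colMeans(counts^2)
  v <- (ex2 - mu^2) * n / (n - 1)
  v <- pmax(v, 0)
  score <- numeric(length(mu))
  use <- mu > 0 & v > 0
  if (sum(use) >= 10) {
    # widen the span for small gene sets so the local fit stays determined
    span_eff <- max(span, min(1, 15 / sum(use)))
    fit <- loess(log10(v[use]) ~ log10(mu[use]), span = span_eff, degree = 2)
    sd_pred <- sqrt(10^fitted(fit))
    clip <- sqrt(n)
    cs <- csum <- numeric(sum(use))
    idx_use <- which(use)
    x <- methods::as(methods::as(counts, "generalMatrix"), "CsparseMatrix")
    p <- x@p
    xs <- x@x
    for (k in seq_along(idx_use)) {
      j <- idx_use[k]
      nz <- if (p[j + 1] > p[j]) xs[(p[j] + 1):p[j + 1]] else numeric(0)
      z <- (nz - mu[j]) / sd_pred[k]
      z <- pmin(z, clip)
      z0 <- min(-mu[j] / sd_pred[k], clip)
      n_zero <- n - length(nz)
      s1 <- sum(z) + n_zero * z0
      s2 <- sum(z^2) + n_zero * z0^2
      score[j] <- (s2 - s1^2 / n) / (n - 1)
    }
  }
  ord <- order(-score)  # stable: ties keep input gene order
  out <- data.frame(gene = genes[ord], mean = mu[ord], variance = v[ord],
                    score = score[ord], rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  class(out) <- c("sn_hvg_ranking", class(out))
  out
}

#' Marker retention along the HVG ranking, with elbow suggestion
#'
#' For each prefix size n of the HVG ranking, counts how many marker-database
#' genes (present in the matrix's gene universe) fall within the top n HVGs.
#' The suggested elbow is the point of maximum perpendicular distance from
#' the chord joining the curve's endpoints; it is advisory only - the number
#' of HVGs actually retained is a configuration choice.
#'
#' @param ranking Output of [rank_hvgs()].
#' @param db Marker database: named list, each entry with a `positive`
#'   character vector (see [read_marker_db()]).
#' @return A list of class `sn_retention_curve`: `curve` (data frame
#'   `n_hvgs`, `n_markers_retained`), `elbow` (suggested n), `n_markers`
#'   (database markers present in the universe).
#' @export
marker_retention_curve <- function(ranking, db) {
  if (length(db) == 0) stop_config("marker database is empty")
  markers <- unique(unlist(lapply(db, `[[`, "positive")))
  present <- markers[markers %in% ranking$gene]
  retained <- cumsum(ranking$gene %in% present)
  nn <- seq_along(retained)
  # max perpendicular distance from the chord (x scaled to the y range so
  # both axes carry comparable weight)
  x <- (nn - 1) / max(nn - 1)
  y <- if (max(retained) > 0) retained / max(retained) else retained
  d <- abs((y[length(y)] - y[1]) * x - (x[length(x)] - x[1]) * y +
             x[length(x)] * y[1] - y[length(y)] * x[1])
  elbow <- which.max(d)
  structure(list(curve = data.frame(n_hvgs = nn,
                                    n_markers_retained = retained),
                 elbow = elbow,
                 n_markers = length(present)),
            class = "sn_retention_curve")
}

#' Scale counts and compute a truncated PCA with stored transforms
#'
#' Per-gene zero-centering and unit-standard-deviation scaling (no value
#' capping) of the HVG submatrix, followed by a truncated PCA. The scaling
#' means and standard deviations and the PCA loadings are stored so the
#' embedding can later be projected back to corrected counts.
#'
#' @param counts Nuclei-by-genes count matrix.
#' @param hvgs Character vector of HVG names (subset of `colnames(counts)`).
#' @param n_components Number of principal components retained (default 25).
#' @return A list of class `sn_pca`: `embedding` (nuclei x components),
#'   `transform` (class `sn_pca_transform`: `genes`, `means`, `sds`,
#'   `loadings` with orthonormal columns, `n_components`, plus any
#'   zero-variance genes excluded from scaling).
#' @export
scale_and_pca <- function(counts, hvgs, n_components = 25) {
  missing <- setdiff(hvgs, colnames(counts))
  if (length(missing)) {
    stop_config("HVGs absent from the matrix: %s",
                paste(head(missing, 5), collapse = ", "))
  }
  x <- as.matrix(counts[, hvgs, drop = FALSE])
  m <- colMeans(x)
  s <- apply(x, 2L, sd)
  zero_var <- s == 0
  if (any(zero_var)) {
    warning(sprintf("%d zero-variance gene(s) excluded from scaling: %s",
                    sum(zero_var),
                    paste(head(hvgs[zero_var], 5), collapse = ", ")))
    x <- x[, !zero_var, drop = FALSE]
    m <- m[!zero_var]
    s <- s[!zero_var]
  }
  if (n_components > min(nrow(x), ncol(x))) {
    stop_config("n_components (%d) exceeds min(n_nuclei, n_hvgs) = %d",
                n_components, min(nrow(x), ncol(x)))
  }
  z <- sweep(sweep(x, 2L, m, `-`), 2L, s, `/`)
  sv <- svd(z, nu = 0, nv = n_components)
  loadings <- sv$v
  rownames(loadings) <- colnames(x)
  embedding <- z %*% loadings
  rownames(embedding) <- rownames(counts)
  transform <- structure(list(genes = colnames(x), means = m, sds = s,
                              loadings = loadings,
                              n_components = n_components,
                              excluded = hvgs[zero_var]),
                         class = "sn_pca_transform")
  structure(list(embedding = embedding, transform = transform),
            class = "sn_pca")
}

#' Batch-correction hook in PCA space
#'
#' Pluggable batch correction applied to the PCA embedding. The default is
#' the identity (no correction); `"center"` removes per-batch mean offsets in
#' PCA space by recentering every batch on the global mean. Any function
#' `f(embedding, batch_labels)` returning a corrected embedding of the same
#' shape can be plugged in.
#'
#' @param embedding Nuclei-by-components matrix.
#' @param batch_labels Vector of batch labels, one per row.
#' @param method `"identity"` (default), `"center"`, or a function.
#' @return Corrected embedding, same dimensions.
#' @export
apply_batch_correction <- function(embedding, batch_labels,
                                   method = c("identity", "center")) {
  if (length(batch_labels) != nrow(embedding)) {
    stop_config("batch_labels length (%d) != number of nuclei (%d)",
                length(batch_labels), nrow(embedding))
  }
  if (is.function(method)) {
    out <- method(embedding, batch_labels)
    if (!all(dim(out) == dim(embedding))) {
      stop_config("batch-correction hook changed the embedding dimensions")
    }
    return(out)
  }
  method <- match.arg(method)
  if (method == "identity") return(embedding)
  global <- colMeans(embedding)
  for (b in unique(batch_labels)) {
    rows <- batch_labels == b
    offset <- colMeans(embedding[rows, , drop = FALSE]) - global
    embedding[rows, ] <- sweep(embedding[rows, , drop = FALSE], 2L, offset, `-`)
  }
  embedding
}

#' Back-project a (corrected) PCA embedding to integer counts
#'
#' Reverses the scale-and-PCA pipeline to produce corrected, count-like
#' data in the original nuclei-by-genes basis. Per gene the steps are:
#' (1) project the embedding back through the stored loadings; (2) set the
#' lowest 1% of the corrected distribution (values at or below the 1st
#' percentile) to the scaled zero-count value, removing correction-induced
#' negative dips - a no-op wherever at least ~1% of the gene's values are
#' zero counts and the data were not corrected; (3) shift the distribution
#' so its minimum matches the uncorrected counterpart's scaled minimum;
#' (4) rescale with the stored means and standard deviations; (5) clamp any
#' remaining negative values to zero; (6) truncate toward zero to integers
#' (with a 1e-6 guard against float round-off). In the limit of full-rank
#' PCA and identity batch correction the original counts are recovered
#' exactly.
#'
#' Genes outside the transform (non-HVGs, or zero-variance genes excluded
#' from scaling) pass through unchanged from `original`.
#'
#' @param embedding Nuclei-by-components matrix (possibly batch-corrected).
#' @param transform The `sn_pca_transform` stored by [scale_and_pca()].
#' @param original The uncorrected nuclei-by-genes count matrix.
#' @param zero_tail Fraction of each gene's corrected distribution zeroed
#'   (default 0.01).
#' @return Sparse integer nuclei-by-genes matrix of corrected counts.
#' @export
backproject_counts <- function(embedding, transform, original,
                               zero_tail = 0.01) {
  if (!inherits(transform, "sn_pca_transform") ||
      is.null(transform$means) || is.null(transform$sds)) {
    stop_config("transform must carry stored scaling means and sds")
  }
  if (ncol(embedding) != ncol(transform$loadings)) {
    stop_config("embedding components (%d) != transform components (%d)",
                ncol(embedding), ncol(transform$loadings))
  }
  y <- embedding %*% t(transform$loadings)  # corrected scaled data
  genes <- transform$genes
  orig <- as.matrix(original[, genes, drop = FALSE])
  out <- as.matrix(original)
  for (k in seq_along(genes)) {
    m <- transform$means[k]
    s <- transform$sds[k]
    col <- y[, k]
    z0 <- (0 - m) / s
    q1 <- quantile(col, zero_tail, type = 7, names = FALSE)
    col[col <= q1] <- z0
    target_min <- (min(orig[, k]) - m) / s
    col <- col + (target_min - min(col))
    x <- col * s + m
    x[x < 0] <- 0
    out[, genes[k]] <- trunc(x + 1e-6)
  }
  res <- methods::as(methods::as(Matrix::Matrix(out, sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
  dimnames(res) <- dimnames(original)
  res
}
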