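#' Per-nucleus QC metrics
#'
#' Computes, for every nucleus, the mitochondrial UMI fraction, the number of
#' detected genes (count > 0) and the total UMI count. Nuclei with zero total
#' UMIs get a mitochondrial fraction of 0 and are flagged.
#'
#' @param counts Sparse or dense nuclei-by-genes count matrix.
#' @param mito A logical vector flagging mitochondrial genes (length
#'   `ncol(counts)`), or `NULL` to flag genes by the "MT-" name prefix.
#' @return A data frame of class `sn_qc_metrics` with columns `barcode`,
#'   `mito_fraction`, `n_genes`, `n_umis`, `flagged_zero`.
#' @export
compute_qc_metrics <- function(counts, mito = NULL) {
  if (is.null(mito)) {
    if (is.null(colnames(counts))) {
      stop_config("counts must have gene names when mito is not supplied")
    }
    mito <- startsWith(colnames(counts), "MT-")
  }
  if (length(mito) != ncol(counts)) {
    stop_config("mito flag length (%d) != number of genes (%d)",
                length(mito), ncol(counts))
  }
  n_umis <- Matrix::rowSums(counts)
  mito_umis <- if (any(mito)) {
    Matrix::rowSums(counts[, mito, drop = FALSE])
  } else {
    rep(0, nrow(counts))
  }
  n_genes <- Matrix::rowSums(counts > 0)
  mito_fraction <- ifelse(n_umis > 0, mito_umis / n_umis, 0)
  out <- data.frame(
    barcode = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    mito_fraction = mito_fraction,
    n_genes = as.integer(n_genes),
    n_umis = as.integer(n_umis),
    flagged_zero = n_umis == 0,
    stringsAsFactors = FALSE)
  class(out) <- c("sn_qc_metrics", class(out))
  out
}

#' Upper-tail heuristic nucleus filter
#'
#' Removes nuclei in the upper tails of the QC metric distributions computed
#' over the full dataset (all libraries combined). For each metric the cutoff
#' is the empirical `(1 - tail)` quantile (linear interpolation, type 7) and
#' nuclei strictly above any cutoff are removed. There is no lower-tail
#' filter on genes/nucleus: low-gene-count nuclei are retained by design and
#' left to cell-type-specific filtering downstream.
#'
#' @param metrics Output of [compute_qc_metrics()].
#' @param mito_tail Upper-tail fraction removed on the mitochondrial fraction
#'   (default 0.10).
#' @param genes_tail Upper-tail fraction on genes/nucleus (default 0.05).
#' @param umi_tail Upper-tail fraction on UMIs/nucleus (default 0.05).
#' @return A list of class `sn_qc_filter`: `kept` (barcodes), `keep`
#'   (logical vector aligned with `metrics`), `cutoffs` (named realized
#'   cutoff values), `removed` (per-metric removal counts).
#' @export
tail_filter <- function(metrics, mito_tail = 0.10, genes_tail = 0.05,
                        umi_tail = 0.05) {
  if (nrow(metrics) < 1) stop_config("tail_filter needs at least one nucleus")
  tails <- c(mito = mito_tail, genes = genes_tail, umi = umi_tail)
  if (any(tails <= 0 | tails >= 1)) {
    stop_config("tail fractions must be in (0, 1)")
  }
  cutoffs <- c(
    mito_fraction = unname(quantile(metrics$mito_fraction, 1 - mito_tail,
                                    type = 7, names = FALSE)),
    n_genes = unname(quantile(metrics$n_genes, 1 - genes_tail,
                              type = 7, names = FALSE)),
    n_umis = unname(quantile(metrics$n_umis, 1 - umi_tail,
                             type = 7, names = FALSE)))
  over <- cbind(
    mito_fraction = metrics$mito_fraction > cutoffs["mito_fraction"],
    n_genes = metrics$n_genes > cutoffs["n_genes"],
    n_umis = metrics$n_umis > cutoffs["n_umis"])
  keep <- !apply(over, 1L, any)
  structure(list(kept = metrics$barcode[keep],
                 keep = keep,
                 cutoffs = cutoffs,
                 removed = colSums(over),
                 n_removed = sum(!keep),
                 tails = tails),
            class = "sn_qc_filter")
}

#' @export
print.sn_qc_filter <- function(x, ...) {
  cat(sprintf("QC tail filter: kept %d nuclei, removed %d\n",
              length(x$kept), x$n_removed))
  cat(sprintf("realized cutoffs: mito fraction > %.4g, genes > %.4g, UMIs > %.4g\n",
              x$cutoffs["mito_fraction"], x$cutoffs["n_genes"],
              x$cutoffs["n_umis"]))
  invisible(x)
}
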