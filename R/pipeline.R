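#' Run the end-to-end pipeline on a cohort
#'
#' Orchestrates the stages in their analysis order - QC tail filtering,
#' HVG ranking and selection, PCA with batch-correction hook and
#' back-projection to corrected counts, neighbor-graph clustering,
#' likelihood cell typing, consensus differential expression for requested
#' contrasts, and composition tests - and returns a manifest of realized,
#' data-dependent values (QC cutoffs, HVG count, cluster count, per-stage
#' record counts). All stage seeds derive from the global seed through a
#' fixed splitting scheme, so a rerun with identical config and seed
#' reproduces identical outputs.
#'
#' @param cohort An `sn_cohort` (from [simulate_cohort()]) or a list with
#'   `counts`, `nuclei`, `genes`, `donors`, `marker_db` (e.g. from
#'   [read_counts()] plus [read_marker_db()]).
#' @param config Named list of stage parameters; any subset of:
#'   `qc` (`enabled`, `mito_tail`, `genes_tail`, `umi_tail`),
#'   `reduce` (`n_hvgs`, `n_pcs`, `batch_hook`),
#'   `cluster` (`k`, `resolution`),
#'   `celltype` (`enabled`, `k`, `l2fc_min`, `alpha`),
#'   `dea` (list of `list(cell_type, contrast, formula_kind, k, alpha)`),
#'   `proportions` (`enabled`, `alpha`),
#'   `use_corrected_counts` (default `TRUE`: DEA consumes back-projected
#'   corrected counts).
#' @param seed Global integer seed.
#' @param out Optional directory; when given, stage outputs and the
#'   manifest (JSON) are written under it.
#' @return A list of class `sn_pipeline_run` with the stage results and
#'   `manifest`.
#' @export
run_pipeline <- function(cohort, config = list(), seed = 1, out = NULL) {
  stages_cfg <- utils::modifyList(list(
    qc = list(enabled = TRUE, mito_tail = 0.10, genes_tail = 0.05,
              umi_tail = 0.05),
    reduce = list(n_hvgs = NULL, n_pcs = 25, batch_hook = "identity"),
    cluster = list(k = 20, resolution = 0.5),
    celltype = list(enabled = TRUE, k = 10, l2fc_min = 1.0, alpha = 0.01),
    dea = list(),
    proportions = list(enabled = TRUE, alpha = 0.05),
    use_corrected_counts = TRUE), config)
  counts <- cohort$counts
  nuclei <- cohort$nuclei
  manifest <- list(seed = seed,
                   n_nuclei_input = nrow(counts),
                   n_genes = ncol(counts))
  results <- list()

  if (isTRUE(stages_cfg$qc$enabled)) {
    metrics <- compute_qc_metrics(counts, mito = cohort$genes$mito)
    filt <- tail_filter(metrics,
                        mito_tail = stages_cfg$qc$mito_tail,
                        genes_tail = stages_cfg$qc$genes_tail,
                        umi_tail = stages_cfg$qc$umi_tail)
    counts <- counts[filt$keep, , drop = FALSE]
    nuclei <- nuclei[filt$keep, , drop = FALSE]
    manifest$qc <- list(cutoffs = as.list(filt$cutoffs),
                        n_removed = filt$n_removed,
                        n_kept = length(filt$kept))
    results$qc <- filt
  }
  manifest$n_nuclei_analyzed <- nrow(counts)

  ranking <- rank_hvgs(counts)
  n_hvgs <- stages_cfg$reduce$n_hvgs %||%
    marker_retention_curve(ranking, cohort$marker_db)$elbow
  n_hvgs <- min(n_hvgs, sum(ranking$score > 0))
  hvgs <- ranking$gene[seq_len(n_hvgs)]
  n_pcs <- min(stages_cfg$reduce$n_pcs, n_hvgs, nrow(counts))
  pca <- scale_and_pca(counts, hvgs, n_components = n_pcs)
  emb <- apply_batch_correction(pca$embedding, nuclei$library,
                                method = stages_cfg$reduce$batch_hook)
  corrected <- backproject_counts(emb, pca$transform, counts)
  manifest$reduce <- list(n_hvgs = n_hvgs, n_pcs = n_pcs,
                          batch_hook = if (is.function(
                            stages_cfg$reduce$batch_hook)) "custom" else
                              stages_cfg$reduce$batch_hook)
  results$ranking <- ranking
  results$pca <- pca
  results$corrected <- corrected

  knn <- build_neighbor_graph(emb, k = min(stages_cfg$cluster$k,
                                           nrow(emb) - 1))
  clusters <- detect_communities(knn,
                                 resolution = stages_cfg$cluster$resolution,
                                 seed = derive_seed(seed, 2))
  manifest$cluster <- list(n_clusters = length(unique(clusters)))
  results$clusters <- clusters

  analysis_counts <- if (isTRUE(stages_cfg$use_corrected_counts)) corrected
    else counts

  if (isTRUE(stages_cfg$celltype$enabled)) {
    k_ct <- min(stages_cfg$celltype$k, min(table(clusters)))
    profiles <- find_distinguishing_hvgs(
      analysis_counts, clusters, k = k_ct,
      l2fc_min = stages_cfg$celltype$l2fc_min,
      alpha = stages_cfg$celltype$alpha, seed = derive_seed(seed, 3))
    assignments <- assign_cell_types(profiles, cohort$marker_db)
    nuclei$assigned_type <-
      assignments$cell_type[match(clusters, assignments$cluster)]
    manifest$celltype <- list(
      k = k_ct,
      assigned = as.list(table(assignments$cell_type)))
    results$profiles <- profiles
    results$assignments <- assignments
  }

  if (length(stages_cfg$dea)) {
    dea_nuclei <- nuclei
    if (!is.null(nuclei$assigned_type)) {
      dea_nuclei$cell_type <- nuclei$assigned_type
    }
    results$dea <- list()
    manifest$dea <- list()
    for (i in seq_along(stages_cfg$dea)) {
      spec_i <- stages_cfg$dea[[i]]
      res <- crossfold_consensus_dea(
        analysis_counts, dea_nuclei, cohort$donors,
        cell_type = spec_i$cell_type, contrast = spec_i$contrast,
        formula_kind = spec_i$formula_kind %||% "sud",
        k = spec_i$k %||% 3, alpha = spec_i$alpha %||% 0.05,
        seed = derive_seed(seed, 10 + i))
      key <- paste0(spec_i$cell_type, ":", paste(spec_i$contrast,
                                                 collapse = "_vs_"))
      results$dea[[key]] <- res
      manifest$dea[[key]] <- list(n_consensus = nrow(res$consensus),
                                  n_tested = res$n_genes_tested)
    }
  }

  if (isTRUE(stages_cfg$proportions$enabled) &&
      !is.null(nuclei$assigned_type %||% nuclei$cell_type)) {
    type_col <- nuclei$assigned_type %||% nuclei$cell_type
    prop_nuc <- data.frame(donor = nuclei$donor, cell_type = type_col,
                           stringsAsFactors = FALSE)
    props <- proportion_mle(prop_nuc)
    donor_groups <- setNames(cohort$donors$group, cohort$donors$donor)
    comp <- proportion_ks_tests(props, donor_groups,
                                alpha = stages_cfg$proportions$alpha)
    manifest$proportions <- list(
      n_tests = nrow(comp), n_significant = sum(comp$significant))
    results$proportions <- list(table = props, tests = comp)
  }

  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_counts(corrected, file.path(out, "corrected_counts"),
                 nuclei = nuclei, genes = cohort$genes,
                 donors = cohort$donors)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(c(results, list(manifest = manifest, nuclei = nuclei)),
            class = "sn_pipeline_run")
}

#' Read a pipeline config from YAML
#'
#' Thin wrapper for file-based configuration of [run_pipeline()].
#' @param path YAML file.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}
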