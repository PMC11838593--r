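#' Cohort simulation configuration
#'
#' Builds and validates the configuration for [simulate_cohort()]. Defaults
#' mirror the postmortem substantia nigra cohort the pipeline was designed
#' around: six donor groups crossing substance-use-disorder status (SUD+/-)
#' with HIV level (HIV-, HIV+u undetectable, HIV+d detectable), 12 major cell
#' types dominated by oligodendrocytes, negative-binomial counts with
#' lognormal library-size variation, and a small set of mitochondrial genes
#' ("MT-" prefix) driving the QC mitochondrial fraction.
#'
#' @param n_donors_per_group Named integer vector over the six donor groups.
#' @param n_nuclei_per_donor Nuclei sequenced per donor.
#' @param cell_type_fractions Named probabilities per cell type (sum to 1).
#' @param n_genes Total genes simulated (must cover all marker genes).
#' @param markers_per_type Positive marker genes planted per cell type.
#' @param marker_l2fc Log2 overexpression of a marker gene in its own type.
#' @param planted_degs `NULL`, or a data frame with columns `cell_type`,
#'   `gene`, `group` (case donor group whose donors carry the effect),
#'   `l2fc`, and optionally `base_mean` (baseline mean count per nucleus for
#'   the gene; ensures planted effects sit on expressed genes).
#' @param coordination_blocks `NULL`, or a list of blocks, each a list with
#'   `cell_type`, `genes` (character), `factor_sd` (SD of the shared
#'   per-donor latent factor, log2 units) and optional `loadings` (per-gene,
#'   default 1) and `base_mean`.
#' @param nb_dispersion Negative-binomial dispersion alpha
#'   (variance = mu + alpha * mu^2).
#' @param library_size_lognormal_sigma Lognormal sigma of per-nucleus
#'   library-size factors.
#' @param base_mean_meanlog,base_mean_sdlog Lognormal parameters of baseline
#'   per-gene mean counts.
#' @param mito_gene_count Number of mitochondrial genes.
#' @param mito_base_mean Baseline mean count of each mitochondrial gene
#'   (before the per-nucleus mitochondrial-load factor).
#' @param mito_load_sdlog Lognormal sigma of the per-nucleus mitochondrial
#'   load factor (drives the spread of QC mitochondrial fractions).
#' @param seed Integer seed; identical configs and seeds give bit-identical
#'   cohorts.
#' @return A validated list of class `sn_cohort_config`.
#' @export
cohort_config <- function(n_donors_per_group = c(
                            "SUD-HIV-" = 13, "SUD+HIV-" = 15,
                            "SUD-HIV+u" = 10, "SUD+HIV+u" = 20,
                            "SUD-HIV+d" = 7, "SUD+HIV+d" = 25),
                          n_nuclei_per_donor = 1000,
                          cell_type_fractions = c(
                            ODC = 0.55, OPC = 0.10, Microglia = 0.09,
                            Astrocyte = 0.06, DA = 0.04, GABA = 0.04,
                            Endothelial = 0.03, Pericyte = 0.03, SMC = 0.02,
                            Ependymal = 0.01, Tcell = 0.015,
                            Macrophage = 0.015),
                          n_genes = 2000,
                          markers_per_type = 5,
                          marker_l2fc = 2.0,
                          planted_degs = NULL,
                          coordination_blocks = NULL,
                          nb_dispersion = 0.5,
                          library_size_lognormal_sigma = 0.35,
                          base_mean_meanlog = log(0.2),
                          base_mean_sdlog = 1.2,
                          mito_gene_count = 13,
                          mito_base_mean = 0.6,
                          mito_load_sdlog = 0.6,
                          seed = 1) {
  cfg <- list(
    n_donors_per_group = n_donors_per_group,
    n_nuclei_per_donor = n_nuclei_per_donor,
    cell_type_fractions = cell_type_fractions,
    n_genes = n_genes,
    markers_per_type = markers_per_type,
    marker_l2fc = marker_l2fc,
    planted_degs = planted_degs,
    coordination_blocks = coordination_blocks,
    nb_dispersion = nb_dispersion,
    library_size_lognormal_sigma = library_size_lognormal_sigma,
    base_mean_meanlog = base_mean_meanlog,
    base_mean_sdlog = base_mean_sdlog,
    mito_gene_count = mito_gene_count,
    mito_base_mean = mito_base_mean,
    mito_load_sdlog = mito_load_sdlog,
    seed = seed)
  class(cfg) <- "sn_cohort_config"
  validate_cohort_config(cfg)
  cfg
}

donor_groups_6 <- c("SUD-HIV-", "SUD+HIV-", "SUD-HIV+u",
                    "SUD+HIV+u", "SUD-HIV+d", "SUD+HIV+d")

validate_cohort_config <- function(cfg) {
  g <- cfg$n_donors_per_group
  if (length(g) != 6 || is.null(names(g)) ||
      !setequal(names(g), donor_groups_6)) {
    stop_config("n_donors_per_group must be named over the 6 groups: %s",
                paste(donor_groups_6, collapse = ", "))
  }
  f <- cfg$cell_type_fractions
  if (is.null(names(f)) || any(f < 0)) {
    stop_config("cell_type_fractions must be a named non-negative vector")
  }
  if (abs(sum(f) - 1) > 1e-9) {
    stop_config("cell_type_fractions must sum to 1 (got %.12f)", sum(f))
  }
  if (cfg$nb_dispersion <= 0) stop_config("nb_dispersion must be positive")
  n_markers <- cfg$markers_per_type * length(f)
  if (cfg$n_genes < n_markers + cfg$mito_gene_count) {
    stop_config("n_genes (%d) must cover %d marker and %d mitochondrial genes",
                cfg$n_genes, n_markers, cfg$mito_gene_count)
  }
  if (!is.null(cfg$planted_degs)) {
    pd <- cfg$planted_degs
    need <- c("cell_type", "gene", "group", "l2fc")
    if (!all(need %in% names(pd))) {
      stop_config("planted_degs needs columns %s", paste(need, collapse = ", "))
    }
    if (any(!is.finite(pd$l2fc))) stop_config("planted l2fc must be finite")
    if (any(!pd$group %in% donor_groups_6)) {
      stop_config("planted_degs group must be one of the 6 donor groups")
    }
    if (any(!pd$cell_type %in% names(f))) {
      stop_config("planted_degs cell_type must be a configured cell type")
    }
  }
  for (blk in cfg$coordination_blocks %||% list()) {
    if (is.null(blk$genes) || is.null(blk$cell_type) ||
        is.null(blk$factor_sd)) {
      stop_config("each coordination block needs cell_type, genes, factor_sd")
    }
    if (blk$factor_sd < 0) stop_config("coordination factor_sd must be >= 0")
  }
  invisible(cfg)
}

gene_universe <- function(cfg) {
  types <- names(cfg$cell_type_fractions)
  markers <- unlist(lapply(types, function(t) {
    paste0("MK-", t, "-", seq_len(cfg$markers_per_type))
  }))
  mito <- if (cfg$mito_gene_count > 0) {
    paste0("MT-", seq_len(cfg$mito_gene_count))
  } else character(0)
  n_bg <- cfg$n_genes - length(markers) - length(mito)
  bg <- sprintf("G%05d", seq_len(n_bg))
  list(genes = c(markers, mito, bg), markers = markers, mito = mito, bg = bg)
}

#' Simulate a synthetic multi-donor snRNA-seq cohort
#'
#' Draws a full cohort with the statistical structure the downstream stages
#' assume: negative-binomial counts with per-gene baseline means, per-nucleus
#' lognormal library-size factors, cell-type marker genes overexpressed by
#' `marker_l2fc` in their own type, mitochondrial genes with per-nucleus load
#' variation, optional planted differential-expression effects in the case
#' donor group, and optional donor-level coordination blocks in which a
#' shared latent factor multiplies member-gene means by `2^(factor * loading)`.
#'
#' @param config A [cohort_config()] object.
#' @return A list of class `sn_cohort` with elements `counts` (sparse
#'   nuclei-by-genes integer dgCMatrix), `nuclei` (data frame: barcode,
#'   donor, group, cell type, library), `genes` (data frame: gene, mito
#'   flag), `donors` (donor covariate table, see [build_design()]),
#'   `marker_db` (cell type -> positive markers), and `truth` (ground-truth
#'   labels: nucleus cell types, marker map, planted DEGs, coordination
#'   block membership).
#' @export
simulate_cohort <- function(config) {
  validate_cohort_config(config)
  set_seed_strict(config$seed)
  uni <- gene_universe(config)
  genes <- uni$genes
  G <- length(genes)
  types <- names(config$cell_type_fractions)

  base_mean <- exp(rnorm(G, config$base_mean_meanlog, config$base_mean_sdlog))
  names(base_mean) <- genes
  base_mean[uni$mito] <- config$mito_base_mean
  pd <- config$planted_degs
  if (!is.null(pd) && !is.null(pd$base_mean)) {
    ok <- !is.na(pd$base_mean)
    base_mean[pd$gene[ok]] <- pd$base_mean[ok]
  }
  for (blk in config$coordination_blocks %||% list()) {
    if (!is.null(blk$base_mean)) base_mean[blk$genes] <- blk$base_mean
  }
  missing_genes <- setdiff(
    c(pd$gene, unlist(lapply(config$coordination_blocks, `[[`, "genes"))),
    genes)
  if (length(missing_genes)) {
    stop_config("planted genes not in the simulated gene universe: %s",
                paste(head(missing_genes, 5), collapse = ", "))
  }

  # cell-type multipliers: markers up in own type
  type_mult <- matrix(1, nrow = length(types), ncol = G,
                      dimnames = list(types, genes))
  for (t in types) {
    type_mult[t, paste0("MK-", t, "-", seq_len(config$markers_per_type))] <-
      2^config$marker_l2fc
  }

  donors <- simulate_donor_table(config)
  n_d <- nrow(donors)
  n_per <- config$n_nuclei_per_donor

  # Donor-level latent coordination factors. Raw draws are iid normal, then
  # decorrelated across blocks within each donor group (Gram-Schmidt against
  # the constant and the preceding factors, rescaled to the block's factor
  # SD), so that planted blocks are mutually uncorrelated in-sample within
  # any group used as a case set - not merely in expectation. Without this,
  # chance factor-factor correlation at realistic donor counts can make two
  # "independent" blocks genuinely coordinated, invalidating ground truth.
  blocks <- config$coordination_blocks %||% list()
  block_factors <- if (length(blocks)) {
    f_raw <- matrix(rnorm(n_d * length(blocks)), nrow = n_d)
    for (grp in unique(donors$group)) {
      idx <- which(donors$group == grp)
      if (length(idx) > length(blocks) + 1) {
        seg <- scale(f_raw[idx, , drop = FALSE], center = TRUE, scale = FALSE)
        q <- qr.Q(qr(seg))
        f_raw[idx, ] <- q * sqrt(length(idx) - 1)
      }
    }
    lapply(seq_along(blocks), function(b) f_raw[, b] * blocks[[b]]$factor_sd)
  } else {
    list()
  }

  counts_list <- vector("list", n_d)
  ct_all <- character(0)
  mito_idx <- match(uni$mito, genes)
  for (d in seq_len(n_d)) {
    ct <- sample(types, n_per, replace = TRUE,
                 prob = config$cell_type_fractions)
    lib <- exp(rnorm(n_per, 0, config$library_size_lognormal_sigma))
    mu <- type_mult[ct, , drop = FALSE]
    mu <- sweep(mu, 2L, base_mean, `*`)
    # planted DEG effects for this donor's group
    if (!is.null(pd)) {
      hits <- which(pd$group == donors$group[d])
      for (i in hits) {
        rows <- ct == pd$cell_type[i]
        if (any(rows)) {
          j <- match(pd$gene[i], genes)
          mu[rows, j] <- mu[rows, j] * 2^pd$l2fc[i]
        }
      }
    }
    # coordination blocks: shared donor factor, multiplicative in l2fc units
    for (b in seq_along(blocks)) {
      blk <- blocks[[b]]
      rows <- ct == blk$cell_type
      if (any(rows)) {
        j <- match(blk$genes, genes)
        loadings <- blk$loadings %||% rep(1, length(j))
        mult <- 2^(block_factors[[b]][d] * loadings)
        mu[rows, j] <- sweep(mu[rows, j, drop = FALSE], 2L, mult, `*`)
      }
    }
    mu <- mu * lib
    if (length(mito_idx)) {
      mload <- exp(rnorm(n_per, 0, config$mito_load_sdlog))
      mu[, mito_idx] <- mu[, mito_idx, drop = FALSE] * mload
    }
    x <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                        size = 1 / config$nb_dispersion),
                nrow = n_per)
    counts_list[[d]] <- methods::as(methods::as(Matrix::Matrix(
      x, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
    ct_all <- c(ct_all, ct)
  }
  counts <- do.call(rbind, counts_list)
  barcodes <- sprintf("N%07d", seq_len(nrow(counts)))
  dimnames(counts) <- list(barcodes, genes)

  nuclei <- data.frame(
    barcode = barcodes,
    donor = rep(donors$donor, each = n_per),
    group = rep(donors$group, each = n_per),
    cell_type = ct_all,
    library = rep(donors$library, each = n_per),
    stringsAsFactors = FALSE)
  gene_tab <- data.frame(gene = genes,
                         mito = startsWith(genes, "MT-"),
                         stringsAsFactors = FALSE)
  marker_db <- lapply(setNames(types, types), function(t) {
    list(positive = paste0("MK-", t, "-", seq_len(config$markers_per_type)),
         negative = character(0))
  })
  truth <- list(
    cell_type = setNames(ct_all, barcodes),
    markers = data.frame(
      gene = uni$markers,
      cell_type = rep(types, each = config$markers_per_type),
      stringsAsFactors = FALSE),
    planted_degs = pd,
    coordination_blocks = blocks,
    block_factors = block_factors)
  structure(list(counts = counts, nuclei = nuclei, genes = gene_tab,
                 donors = donors, marker_db = marker_db, truth = truth,
                 config = config),
            class = "sn_cohort")
}

#' Simulate a null cohort
#'
#' Identical generator to [simulate_cohort()] with all planted
#' differential-expression effects and coordination blocks removed; used for
#' type-I-error suites.
#'
#' @inheritParams simulate_cohort
#' @export
simulate_null <- function(config) {
  config$planted_degs <- NULL
  config$coordination_blocks <- NULL
  simulate_cohort(config)
}

# Donor covariate table with the design-matrix covariates: mixed-type,
# drawn from simple parametric distributions resembling the cohort.
simulate_donor_table <- function(config) {
  g <- config$n_donors_per_group[donor_groups_6]
  group <- rep(names(g), times = g)
  n <- length(group)
  sud <- ifelse(startsWith(group, "SUD+"), "yes", "no")
  hiv <- sub("^SUD[+-]", "", group)
  cd4 <- character(n)
  for (i in seq_len(n)) {
    cd4[i] <- if (hiv[i] == "HIV-") ">500" else if (hiv[i] == "HIV+u") {
      sample(c("<200", "[200,500]", ">500"), 1, prob = c(0.2, 0.4, 0.4))
    } else {
      sample(c("<200", "[200,500]", ">500"), 1, prob = c(0.5, 0.3, 0.2))
    }
  }
  data.frame(
    donor = sprintf("D%03d", seq_len(n)),
    group = group,
    hiv_level = hiv,
    sud_opc = sud,
    sud_other = sample(c("yes", "no"), n, TRUE, prob = c(0.3, 0.7)),
    age = round(rnorm(n, 54, 11.4), 1),
    sex = sample(c("male", "female"), n, TRUE, prob = c(51, 39) / 90),
    race = sample(c("Black or African American", "White", "Asian"),
                  n, TRUE, prob = c(0.5, 0.4, 0.1)),
    ethnicity = sample(c("Hispanic or Latino", "Not Hispanic or Latino"),
                       n, TRUE, prob = c(0.33, 0.67)),
    overdose_death = ifelse(sud == "yes",
                            sample(c("yes", "no"), n, TRUE, c(0.4, 0.6)),
                            sample(c("yes", "no"), n, TRUE, c(0.05, 0.95))),
    pmi = round(exp(rnorm(n, log(12), 0.5)), 1),
    tissue_location = sample(c("coronal", "midbrain"), n, TRUE),
    cd4_nadir = cd4,
    library = paste0("L", sprintf("%02d", ((seq_len(n) - 1) %/% 4) + 1)),
    stringsAsFactors = FALSE)
}

#' @export
print.sn_cohort <- function(x, ...) {
  cat(sprintf("snRNA-seq cohort: %d nuclei x %d genes, %d donors, %d groups\n",
              nrow(x$counts), ncol(x$counts), nrow(x$donors),
              length(unique(x$donors$group))))
  cat(sprintf("cell types: %s\n",
              paste(names(x$config$cell_type_fractions), collapse = ", ")))
  if (!is.null(x$truth$planted_degs)) {
    cat(sprintf("planted DEGs: %d; coordination blocks: %d\n",
                nrow(x$truth$planted_degs),
                length(x$truth$coordination_blocks)))
  }
  invisible(x)
}
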