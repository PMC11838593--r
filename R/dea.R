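#' Build the donor-level GLM design matrix
#'
#' Constructs the design used by the negative-binomial Wald fits: a 6-level
#' combined (HIV level, SUD) donor-group factor plus covariates. The SUD
#' formula (`formula_kind = "sud"`) adds CD4 nadir to account for long-term
#' immunosuppression when testing substance-use effects; the HIV formula
#' (`"hiv"`) excludes it because CD4 nadir closely recapitulates HIV
#' viral-load variation. Numeric covariates are standardized to mean 0, SD 1.
#' Categorical covariates that covary perfectly (induce the same partition
#' of donors) are detected and all but the first removed; single-level
#' covariates are dropped. Treatment coding with declared reference levels
#' is used throughout.
#'
#' @param donors Donor table with columns `donor`, `hiv_level`, `sud_opc`,
#'   `sud_other`, `age`, `sex`, `race`, `ethnicity`, `overdose_death`,
#'   `pmi`, `tissue_location`, `cd4_nadir`.
#' @param formula_kind `"sud"` (includes CD4 nadir) or `"hiv"` (excludes it).
#' @return A list of class `sn_design`: `design` (donor-by-coefficient
#'   matrix), `group` (6-level factor per donor), `group_levels`,
#'   `donors` (donor ids in row order), `dropped` (covariates removed and
#'   why).
#' @export
build_design <- function(donors, formula_kind = c("sud", "hiv")) {
  formula_kind <- match.arg(formula_kind)
  numeric_covs <- c("age", "pmi")
  cat_covs <- c("sud_other", "sex", "race", "ethnicity", "overdose_death",
                "tissue_location")
  if (formula_kind == "sud") cat_covs <- c(cat_covs, "cd4_nadir")
  need <- c("donor", "hiv_level", "sud_opc", numeric_covs, cat_covs)
  miss <- setdiff(need, names(donors))
  if (length(miss)) {
    stop_config("donor table lacks covariates: %s",
                paste(miss, collapse = ", "))
  }
  group <- paste0(ifelse(donors$sud_opc == "yes", "SUD+", "SUD-"),
                  donors$hiv_level)
  group <- factor(group, levels = intersect(donor_groups_6, unique(group)))
  dropped <- character(0)
  # drop single-level categorical covariates (unfittable)
  keep_cat <- character(0)
  parts <- list()
  for (cc in cat_covs) {
    v <- factor(donors[[cc]])
    if (nlevels(v) < 2) {
      dropped <- c(dropped, sprintf("%s (single level)", cc))
      next
    }
    partition <- paste(as.integer(v))
    dup <- FALSE
    for (prev in keep_cat) {
      if (identical_partition(parts[[prev]], as.integer(v))) {
        dropped <- c(dropped,
                     sprintf("%s (covaries perfectly with %s)", cc, prev))
        dup <- TRUE
        break
      }
    }
    if (!dup) {
      keep_cat <- c(keep_cat, cc)
      parts[[cc]] <- as.integer(v)
    }
  }
  df <- data.frame(group = group)
  for (nc in numeric_covs) {
    x <- donors[[nc]]
    df[[nc]] <- if (sd(x) > 0) (x - mean(x)) / sd(x) else {
      dropped <- c(dropped, sprintf("%s (constant)", nc))
      NULL
    }
  }
  for (cc in keep_cat) df[[cc]] <- factor(donors[[cc]])
  design <- stats::model.matrix(~ ., data = df)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    aliased <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop_config("design is rank-deficient after pruning; aliased columns: %s",
                paste(aliased, collapse = ", "))
  }
  rownames(design) <- donors$donor
  structure(list(design = design, group = group,
                 group_levels = levels(group), donors = donors$donor,
                 formula_kind = formula_kind, dropped = dropped),
            class = "sn_design")
}

identical_partition <- function(a, b) {
  # two categorical covariates covary perfectly iff they induce the same
  # partition of donors (their contingency table is a permutation pattern)
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

#' Negative-binomial Wald differential expression for one cell type
#'
#' Per-gene negative-binomial GLM (log link) over single nuclei with
#' donor-level covariates, testing a pairwise donor-group contrast by Wald
#' statistic. Size factors use the median-of-ratios estimator, falling back
#' to a positive-count geometric-mean variant when no gene is expressed in
#' every nucleus (the usual single-cell case). Per-gene dispersions are
#' estimated by maximum likelihood (profile in alpha with a moment-based
#' start), the GLM is refit at the estimated dispersion, and the Wald
#' statistic is l2fc/SE with a two-sided normal p-value and
#' Benjamini-Hochberg correction over tested genes.
#'
#' This engine is a deliberately transparent approximation of the DESeq2
#' model (no dispersion-trend shrinkage, no independent filtering, no
#' outlier replacement); the package's contribution is the cross-fold
#' consensus wrapper around it.
#'
#' @param counts Integer nuclei-by-genes count matrix for one cell type.
#' @param design An `sn_design` from [build_design()].
#' @param nucleus_donor Donor id per nucleus (maps design rows to nuclei).
#' @param contrast Character vector `c(groupA, groupB)`: l2fc is
#'   log2(groupA / groupB).
#' @param min_nonzero_frac Genes with a smaller fraction of nonzero nuclei
#'   are not tested (default 0: only all-zero genes are excluded).
#' @return A data frame of class `sn_dea_fit`: `gene`, `base_mean`
#'   (mean of normalized counts), `l2fc`, `se`, `stat`, `pvalue`, `adj_p`,
#'   `status`.
#' @export
nb_wald_fit <- function(counts, design, nucleus_donor, contrast,
                        min_nonzero_frac = 0) {
  if (!inherits(design, "sn_design")) stop_config("design must be sn_design")
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (any(counts@x %% 1 != 0)) stop_config("counts must be integers")
  if (length(nucleus_donor) != nrow(counts)) {
    stop_config("nucleus_donor length != number of nuclei")
  }
  lv <- design$group_levels
  if (!all(contrast %in% lv)) {
    stop_config("contrast levels must be among: %s", paste(lv, collapse = ", "))
  }
  per_level <- table(design$group)
  if (any(per_level[contrast] < 2)) {
    stop_config("need >= 2 donors in each contrasted level")
  }
  ridx <- match(nucleus_donor, design$donors)
  if (any(is.na(ridx))) stop_config("nucleus donor not in design")
  X <- design$design[ridx, , drop = FALSE]

  nz_frac <- Matrix::colMeans(counts > 0)
  testable <- if (min_nonzero_frac > 0) nz_frac >= min_nonzero_frac else
    nz_frac > 0
  genes <- colnames(counts) %||% as.character(seq_len(ncol(counts)))

  sf <- size_factors(counts)
  off <- log(sf)
  cvec <- contrast_vector(design, contrast)

  out <- data.frame(gene = genes, base_mean = NA_real_, l2fc = NA_real_,
                    se = NA_real_, stat = NA_real_, pvalue = NA_real_,
                    adj_p = NA_real_, status = "not_tested",
                    stringsAsFactors = FALSE)
  norm_means <- Matrix::colMeans(Matrix::Diagonal(x = 1 / sf) %*% counts)
  out$base_mean <- norm_means
  if (all(cvec == 0)) {
    # contrasting a level with itself: the l2fc is identically zero
    out$l2fc[testable] <- 0
    out$se[testable] <- 0
    out$stat[testable] <- 0
    out$pvalue[testable] <- 1
    out$adj_p[testable] <- 1
    out$status[testable] <- "ok"
    class(out) <- c("sn_dea_fit", class(out))
    return(out)
  }
  dense <- as.matrix(counts[, testable, drop = FALSE])
  p <- ncol(X)
  res <- matrix(NA_real_, nrow = ncol(dense), ncol = 3)  # l2fc, se, alpha
  status <- rep("ok", ncol(dense))
  for (j in seq_len(ncol(dense))) {
    y <- dense[, j]
    fit <- tryCatch(nb_glm_gene(y, X, off), error = function(e) NULL)
    if (is.null(fit)) {
      status[j] <- "untestable"
      next
    }
    est <- drop(crossprod(cvec, fit$beta)) / log(2)
    vc <- drop(crossprod(cvec, fit$cov %*% cvec))
    if (!is.finite(vc) || vc <= 0) {
      status[j] <- "untestable"
      next
    }
    res[j, ] <- c(est, sqrt(vc) / log(2), fit$alpha)
  }
  idx <- which(testable)
  out$l2fc[idx] <- res[, 1]
  out$se[idx] <- res[, 2]
  out$status[idx] <- status
  out$stat[idx] <- out$l2fc[idx] / out$se[idx]
  out$pvalue[idx] <- 2 * pnorm(-abs(out$stat[idx]))
  tested <- !is.na(out$pvalue)
  out$adj_p[tested] <- bh_adjust(out$pvalue[tested])
  attr(out, "size_factors") <- sf
  attr(out, "dispersion") <- setNames(rep(NA_real_, length(genes)), genes)
  attr(out, "dispersion")[idx] <- res[, 3]
  class(out) <- c("sn_dea_fit", class(out))
  out
}

# Median-of-ratios size factors; poscounts-style geometric means over
# positive entries when no gene has all-positive counts.
size_factors <- function(counts) {
  x <- methods::as(methods::as(counts, "generalMatrix"), "CsparseMatrix")
  n <- nrow(x)
  nz_per_gene <- diff(x@p)
  all_pos <- nz_per_gene == n
  if (any(all_pos)) {
    lg <- vapply(which(all_pos), function(j) {
      mean(log(x@x[(x@p[j] + 1):x@p[j + 1]]))
    }, numeric(1))
    dense <- as.matrix(x[, all_pos, drop = FALSE])
    sf <- apply(dense, 1L, function(row) {
      exp(median(log(row) - lg))
    })
  } else {
    # positive-count variant: gene geometric mean over positive entries,
    # averaged over all nuclei; ratios over positive entries only
    lg <- vapply(seq_len(ncol(x)), function(j) {
      if (x@p[j + 1] == x@p[j]) return(NA_real_)
      sum(log(x@x[(x@p[j] + 1):x@p[j + 1]])) / n
    }, numeric(1))
    use <- which(!is.na(lg))
    dense <- as.matrix(x[, use, drop = FALSE])
    lgu <- lg[use]
    sf <- apply(dense, 1L, function(row) {
      pos <- row > 0
      if (!any(pos)) return(NA_real_)
      exp(median(log(row[pos]) - lgu[pos]))
    })
    sf[is.na(sf)] <- 1
  }
  sf <- sf / exp(mean(log(sf)))
  sf
}

contrast_vector <- function(design, contrast) {
  cols <- colnames(design$design)
  cvec <- numeric(length(cols))
  for (sgn in c(1, -1)) {
    level <- contrast[if (sgn == 1) 1 else 2]
    col <- paste0("group", level)
    if (col %in% cols) cvec[cols == col] <- cvec[cols == col] + sgn
    # reference level contributes nothing (treatment coding)
  }
  cvec
}

# One-gene NB GLM: IRLS at a moment-started dispersion, ML refinement of
# alpha on the profile likelihood, one refit, observed-information
# covariance.
nb_glm_gene <- function(y, X, off, max_iter = 25, tol = 1e-6) {
  alpha0 <- moment_dispersion(y, off)
  fit <- nb_irls(y, X, off, alpha0, max_iter, tol)
  mu <- fit$mu
  obj <- function(la) {
    a <- exp(la)
    -sum(stats::dnbinom(y, mu = mu, size = 1 / a, log = TRUE))
  }
  opt <- optimize(obj, interval = c(log(1e-8), log(100)))
  alpha <- exp(opt$minimum)
  fit <- nb_irls(y, X, off, alpha, max_iter, tol, beta0 = fit$beta)
  w <- fit$mu / (1 + alpha * fit$mu)
  info <- crossprod(X * sqrt(w))
  cov <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(cov)) stop("singular information matrix")
  list(beta = fit$beta, cov = cov, alpha = alpha, mu = fit$mu)
}

moment_dispersion <- function(y, off) {
  mu <- mean(y / exp(off))
  v <- var(y / exp(off))
  max((v - mu) / mu^2, 1e-4)
}

nb_irls <- function(y, X, off, alpha, max_iter = 25, tol = 1e-6,
                    beta0 = NULL) {
  if (is.null(beta0)) {
    z0 <- log((y + 0.5) / exp(off))
    beta <- qr.coef(qr(X), z0)
  } else {
    beta <- beta0
  }
  beta[is.na(beta)] <- 0
  eta <- drop(X %*% beta) + off
  for (it in seq_len(max_iter)) {
    mu <- pmin(pmax(exp(eta), 1e-10), 1e10)
    w <- mu / (1 + alpha * mu)
    z <- (eta - off) + (y - mu) / mu
    sw <- sqrt(w)
    fit <- .lm.fit(X * sw, z * sw)
    new_beta <- fit$coefficients
    if (any(!is.finite(new_beta))) stop("divergent IRLS")
    delta <- max(abs(new_beta - beta))
    beta <- new_beta
    eta <- drop(X %*% beta) + off
    if (delta < tol) break
  }
  list(beta = beta, mu = pmin(pmax(exp(eta), 1e-10), 1e10))
}

#' Cross-fold consensus differential expression
#'
#' The package's consensus wrapper: nuclei of one cell type are split into
#' k disjoint random folds stratified by donor (every donor contributes
#' nuclei to every fold where possible), [nb_wald_fit()] is run per fold,
#' and consensus DEGs are the genes with adjusted p < `alpha` in every
#' fold. Reported effect sizes are cross-fold means of l2fc and of
#' normalized counts. Random subsetting perturbs spuriously low dispersion
#' estimates, so requiring significance in every fold suppresses the false
#' positives they cause.
#'
#' @param counts Nuclei-by-genes count matrix (all cell types).
#' @param nuclei Nucleus annotation data frame with `donor` and `cell_type`
#'   columns, aligned with `counts` rows.
#' @param donors Donor covariate table (see [build_design()]).
#' @param cell_type Cell type analyzed.
#' @param contrast `c(groupA, groupB)` donor-group contrast.
#' @param formula_kind `"sud"` or `"hiv"` (see [build_design()]).
#' @param k Number of folds (default 3, set by power analysis).
#' @param alpha Adjusted-p threshold for significance in each fold
#'   (default 0.05).
#' @param seed Integer seed for the fold split.
#' @param l2fc_min Optional additional absolute-l2fc cutoff on consensus
#'   DEGs (default 0 = off).
#' @return A list of class `sn_dea`: `consensus` (data frame: gene,
#'   mean_l2fc, mean_base_mean, direction, max_adj_p), `folds` (per-fold
#'   `sn_dea_fit` results), `fold_assignment`, `k`, `contrast`,
#'   `n_genes_tested`.
#' @export
crossfold_consensus_dea <- function(counts, nuclei, donors, cell_type,
                                    contrast, formula_kind = c("sud", "hiv"),
                                    k = 3, alpha = 0.05, seed = 1,
                                    l2fc_min = 0) {
  formula_kind <- match.arg(formula_kind)
  rows <- which(nuclei$cell_type == cell_type)
  if (!length(rows)) stop_config("no nuclei of cell type '%s'", cell_type)
  sub <- counts[rows, , drop = FALSE]
  sub_donor <- nuclei$donor[rows]
  design <- build_design(donors, formula_kind)
  set_seed_strict(seed)
  fold <- integer(length(rows))
  few <- character(0)
  for (d in unique(sub_donor)) {
    idx <- which(sub_donor == d)
    if (length(idx) < k) few <- c(few, d)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  if (length(few)) {
    message(sprintf("%d donor(s) contribute to fewer than %d folds: %s",
                    length(few), k, paste(head(few, 5), collapse = ", ")))
  }
  fits <- vector("list", k)
  for (f in seq_len(k)) {
    inf <- fold == f
    fits[[f]] <- nb_wald_fit(sub[inf, , drop = FALSE], design,
                             sub_donor[inf], contrast,
                             min_nonzero_frac = if (k > 1) 1 / k else 0)
  }
  genes <- colnames(counts) %||% as.character(seq_len(ncol(counts)))
  sig <- sapply(fits, function(ft) {
    !is.na(ft$adj_p) & ft$adj_p < alpha
  })
  tested_all <- sapply(fits, function(ft) !is.na(ft$pvalue))
  consensus_flag <- rowSums(sig) == k
  l2fc_mat <- sapply(fits, `[[`, "l2fc")
  bm_mat <- sapply(fits, `[[`, "base_mean")
  adjp_mat <- sapply(fits, `[[`, "adj_p")
  mean_l2fc <- rowMeans(l2fc_mat)
  if (l2fc_min > 0) {
    consensus_flag <- consensus_flag & abs(mean_l2fc) > l2fc_min
  }
  sel <- which(consensus_flag)
  consensus <- data.frame(
    gene = genes[sel],
    mean_l2fc = mean_l2fc[sel],
    mean_base_mean = rowMeans(bm_mat)[sel],
    direction = ifelse(mean_l2fc[sel] > 0, "up", "down"),
    max_adj_p = if (length(sel)) {
      apply(adjp_mat[sel, , drop = FALSE], 1L, max)
    } else numeric(0),
    stringsAsFactors = FALSE)
  consensus <- consensus[order(consensus$max_adj_p), , drop = FALSE]
  rownames(consensus) <- NULL
  structure(list(consensus = consensus, folds = fits,
                 fold_assignment = fold, k = k, contrast = contrast,
                 cell_type = cell_type, alpha = alpha,
                 n_genes_tested = sum(rowSums(tested_all) == k)),
            class = "sn_dea")
}

#' @export
print.sn_dea <- function(x, ...) {
  cat(sprintf(
    "consensus DEA: %s, %s vs %s, k = %d folds, adj p < %g in all folds\n",
    x$cell_type, x$contrast[1], x$contrast[2], x$k, x$alpha))
  cat(sprintf("%d consensus DEG(s) of %d genes tested in all folds\n",
              nrow(x$consensus), x$n_genes_tested))
  if (nrow(x$consensus)) print(head(x$consensus, 10))
  invisible(x)
}
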