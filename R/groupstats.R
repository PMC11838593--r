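#' Per-donor cell-type occurrence probabilities
#'
#' Binomial maximum-likelihood estimates of cell-type occurrence per donor:
#' for a donor with k nuclei of a type among n total, `p_hat = k / n`.
#' Donors with zero typed nuclei are excluded with a warning.
#'
#' @param nuclei Nucleus annotations with `donor` and `cell_type`.
#' @param cell_types Optional cell-type universe ordering the columns;
#'   defaults to the types present.
#' @return A donor-by-cell-type matrix of proportions (rows sum to 1), with
#'   per-donor totals in attribute `n`.
#' @export
proportion_mle <- function(nuclei, cell_types = NULL) {
  tab <- table(nuclei$donor, nuclei$cell_type)
  if (!is.null(cell_types)) {
    m <- matrix(0L, nrow = nrow(tab), ncol = length(cell_types),
                dimnames = list(rownames(tab), cell_types))
    common <- intersect(colnames(tab), cell_types)
    m[, common] <- tab[, common]
    tab <- m
  }
  n <- rowSums(tab)
  if (any(n == 0)) {
    warning(sprintf("excluding %d donor(s) with zero typed nuclei",
                    sum(n == 0)))
    tab <- tab[n > 0, , drop = FALSE]
    n <- n[n > 0]
  }
  out <- sweep(unclass(tab), 1L, n, `/`)
  attr(out, "n") <- n
  out
}

#' Pairwise Kolmogorov-Smirnov tests of cell-type proportions
#'
#' For each unordered pair of donor groups and every cell type in the
#' proportion table, compares the two groups' distributions of per-donor
#' occurrence probabilities with a two-sample KS test,
#' Benjamini-Hochberg-corrected within each group pair across the cell
#' types. The exact small-sample KS distribution is used when both groups
#' have at most 25 donors; the asymptotic form otherwise. Exactly
#' `choose(G, 2) * T` tests are emitted for G groups and T cell types;
#' types absent from a group are flagged but still tested.
#'
#' @param proportions Donor-by-cell-type matrix from [proportion_mle()].
#' @param donor_groups Named group label per donor (names = donor ids) or a
#'   vector aligned with the table rows.
#' @param alpha Significance level on adjusted p (default 0.05).
#' @param exact_max Largest per-group donor count for the exact KS mode
#'   (default 25).
#' @return A data frame of class `sn_composition_tests`: `group1`, `group2`,
#'   `cell_type`, `statistic`, `p`, `adj_p`, `significant`, `method`,
#'   `absent` (type has all-zero proportions in at least one group).
#' @export
proportion_ks_tests <- function(proportions, donor_groups, alpha = 0.05,
                                exact_max = 25) {
  donors <- rownames(proportions)
  groups <- if (!is.null(names(donor_groups))) {
    unname(donor_groups[donors])
  } else donor_groups
  if (length(groups) != nrow(proportions)) {
    stop_config("donor_groups must cover every table row")
  }
  glev <- unique(groups)
  pairs <- combn(glev, 2)
  rows <- list()
  for (pp in seq_len(ncol(pairs))) {
    g1 <- pairs[1, pp]
    g2 <- pairs[2, pp]
    i1 <- which(groups == g1)
    i2 <- which(groups == g2)
    if (length(i1) < 2 || length(i2) < 2) {
      message(sprintf("pair (%s, %s) skipped: a group has < 2 donors",
                      g1, g2))
      next
    }
    exact <- length(i1) <= exact_max && length(i2) <= exact_max
    res <- lapply(colnames(proportions), function(ct) {
      x <- proportions[i1, ct]
      y <- proportions[i2, ct]
      kt <- suppressWarnings(ks.test(x, y, exact = exact))
      data.frame(group1 = g1, group2 = g2, cell_type = ct,
                 statistic = unname(kt$statistic), p = kt$p.value,
                 method = if (exact) "exact" else "asymptotic",
                 absent = all(x == 0) || all(y == 0),
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$adj_p <- bh_adjust(res$p)  # BH family: cell types within this pair
    rows[[length(rows) + 1]] <- res
  }
  out <- do.call(rbind, rows)
  out$significant <- out$adj_p < alpha
  rownames(out) <- NULL
  out <- out[, c("group1", "group2", "cell_type", "statistic", "p",
                 "adj_p", "significant", "method", "absent")]
  class(out) <- c("sn_composition_tests", class(out))
  out
}

#' Random-sampling significance test for DEG-set overlaps
#'
#' Tests whether the overlap observed between two DEG sets exceeds random
#' expectation: per iteration, `n1` and `n2` genes are drawn without
#' replacement, independently, from the HVG background, and the upper bound
#' on the p-value is the fraction of iterations with an overlap at least as
#' large as observed. When no iteration qualifies, the bound
#' `< 1/iterations` is reported. The Monte-Carlo estimate converges on the
#' hypergeometric tail `P(X >= observed)`, `X ~ Hypergeom(background, n1,
#' n2)`, which is also returned for reference.
#'
#' @param n1,n2 DEG counts of the two analyses.
#' @param observed_overlap Observed overlap (must be `<= min(n1, n2)`).
#' @param background_size Background gene count (default 20000 HVGs).
#' @param iterations Sampling iterations (default 1e5).
#' @param seed Integer seed.
#' @return A list of class `sn_overlap_test`: `p` (Monte-Carlo upper bound,
#'   numeric), `p_label` (string, `"< 1/iterations"` when no iteration
#'   qualifies), `hits`, `iterations`, `p_hypergeom`.
#' @export
overlap_permutation_test <- function(n1, n2, observed_overlap,
                                     background_size = 20000,
                                     iterations = 100000, seed = 1) {
  if (n1 > background_size || n2 > background_size) {
    stop_config("n1 and n2 must not exceed background_size")
  }
  if (observed_overlap > min(n1, n2)) {
    stop_config("observed_overlap (%d) exceeds min(n1, n2) = %d",
                observed_overlap, min(n1, n2))
  }
  if (observed_overlap < 0) stop_config("observed_overlap must be >= 0")
  set_seed_strict(seed)
  hits <- 0L
  member <- logical(background_size)
  for (it in seq_len(iterations)) {
    a <- sample.int(background_size, n1)
    b <- sample.int(background_size, n2)
    member[a] <- TRUE
    ov <- sum(member[b])
    member[a] <- FALSE
    if (ov >= observed_overlap) hits <- hits + 1L
  }
  p <- hits / iterations
  p_hyper <- stats::phyper(observed_overlap - 1, n1,
                           background_size - n1, n2, lower.tail = FALSE)
  structure(list(
    p = p,
    p_label = if (hits == 0) sprintf("< %g", 1 / iterations) else
      format(p, digits = 4),
    hits = hits, iterations = iterations,
    p_hypergeom = p_hyper,
    n1 = n1, n2 = n2, observed_overlap = observed_overlap,
    background_size = background_size),
    class = "sn_overlap_test")
}

#' @export
print.sn_overlap_test <- function(x, ...) {
  cat(sprintf(
    "DEG overlap test: n1 = %d, n2 = %d, overlap = %d, background = %d\n",
    x$n1, x$n2, x$observed_overlap, x$background_size))
  cat(sprintf("p upper bound %s (%d/%d iterations); hypergeometric tail %.3g\n",
              x$p_label, x$hits, x$iterations, x$p_hypergeom))
  invisible(x)
}
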