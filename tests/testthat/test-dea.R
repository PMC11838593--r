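test_that("the design matrix standardizes, prunes and selects covariates per formula", {
  co <- simulate_cohort(single_type_config(3, donors = group_sizes(5),
                                           n_nuclei = 5, n_genes = 100))
  d <- build_design(co$donors, "sud")
  age_col <- d$design[, "age"]
  expect_equal(mean(age_col), 0, tolerance = 1e-9)
  expect_equal(sd(age_col), 1, tolerance = 1e-9)
  expect_true(any(grepl("^cd4_nadir", colnames(d$design))))
  dh <- build_design(co$donors, "hiv")
  expect_false(any(grepl("^cd4_nadir", colnames(dh$design))))
  expect_true(all(paste0("group", d$group_levels[-1]) %in%
                    colnames(d$design)))
})

test_that("perfectly covarying categorical covariates collapse to one", {
  co <- simulate_cohort(single_type_config(5, donors = group_sizes(4),
                                           n_nuclei = 5, n_genes = 100))
  don <- co$donors
  # make tissue_location a relabeling of sex: identical donor partition
  don$tissue_location <- ifelse(don$sex == "male", "coronal", "midbrain")
  d <- build_design(don, "hiv")
  expect_true(any(grepl("covaries perfectly", d$dropped)))
  expect_true(xor(any(grepl("^sex", colnames(d$design))),
                  any(grepl("^tissue_location", colnames(d$design)))))
})

test_that("rank-deficient designs fail loudly, naming aliased columns", {
  co <- simulate_cohort(single_type_config(7, donors = group_sizes(4),
                                           n_nuclei = 5, n_genes = 100))
  don <- co$donors
  # numeric covariate equal to a group indicator: aliased with the factor
  don$age <- as.numeric(don$group == "SUD+HIV-")
  expect_error(build_design(don, "hiv"), "aliased")
})

test_that("contrasting a level with itself gives identically zero l2fc", {
  co <- simulate_cohort(single_type_config(9, donors = group_sizes(3),
                                           n_nuclei = 20, n_genes = 60))
  d <- build_design(co$donors, "hiv")
  fit <- nb_wald_fit(co$counts, d, co$nuclei$donor,
                     c("SUD+HIV-", "SUD+HIV-"))
  tested <- fit$status == "ok"
  expect_true(any(tested))
  expect_true(all(fit$l2fc[tested] == 0))
  expect_true(all(fit$pvalue[tested] == 1))
})

test_that("non-integer counts are rejected", {
  co <- simulate_cohort(single_type_config(9, donors = group_sizes(3),
                                           n_nuclei = 10, n_genes = 60))
  d <- build_design(co$donors, "hiv")
  bad <- co$counts * 1.0
  bad[1, which(bad[1, ] > 0)[1]] <- 1.5
  expect_error(nb_wald_fit(bad, d, co$nuclei$donor,
                           c("SUD+HIV-", "SUD-HIV-")), "integer")
})

test_that("the NB Wald engine controls type I error on null data", {
  # enough donors that the full covariate design is overdetermined
  co <- simulate_null(single_type_config(13, donors = group_sizes(4),
                                         n_nuclei = 25, n_genes = 2000))
  d <- build_design(co$donors, "hiv")
  fit <- nb_wald_fit(co$counts, d, co$nuclei$donor,
                     c("SUD+HIV-", "SUD-HIV-"))
  tested <- !is.na(fit$adj_p)
  expect_gt(sum(tested), 500)
  expect_lte(mean(fit$adj_p[tested] < 0.05), 0.05)
})

test_that("planted effects are recovered with small bias", {
  pd <- planted_deg_frame(n = 10, l2fc = 2)
  co <- simulate_cohort(single_type_config(
    17, donors = group_sizes(3, "SUD-HIV-" = 6, "SUD+HIV-" = 6),
    n_nuclei = 60, n_genes = 150, planted_degs = pd))
  d <- build_design(co$donors, "sud")
  fit <- nb_wald_fit(co$counts, d, co$nuclei$donor,
                     c("SUD+HIV-", "SUD-HIV-"))
  est <- fit$l2fc[match(pd$gene, fit$gene)]
  expect_lt(abs(median(est) - 2), 0.3)
})

test_that("swapping the contrast negates every l2fc exactly", {
  co <- simulate_cohort(single_type_config(19, donors = group_sizes(3),
                                           n_nuclei = 30, n_genes = 80))
  d <- build_design(co$donors, "hiv")
  f1 <- nb_wald_fit(co$counts, d, co$nuclei$donor,
                    c("SUD+HIV+u", "SUD-HIV-"))
  f2 <- nb_wald_fit(co$counts, d, co$nuclei$donor,
                    c("SUD-HIV-", "SUD+HIV+u"))
  ok <- f1$status == "ok" & f2$status == "ok"
  expect_equal(f1$l2fc[ok], -f2$l2fc[ok], tolerance = 1e-12)
})

test_that("k = 1 consensus equals a single Wald fit and consensus nests in folds", {
  pd <- planted_deg_frame(n = 5, l2fc = 2)
  co <- simulate_cohort(single_type_config(
    21, donors = group_sizes(3, "SUD-HIV-" = 8, "SUD+HIV-" = 8),
    n_nuclei = 60, n_genes = 120, planted_degs = pd))
  d <- build_design(co$donors, "sud")
  single <- nb_wald_fit(co$counts, d, co$nuclei$donor,
                        c("SUD+HIV-", "SUD-HIV-"))
  k1 <- crossfold_consensus_dea(co$counts, co$nuclei, co$donors, "DA",
                                c("SUD+HIV-", "SUD-HIV-"), "sud",
                                k = 1, seed = 2)
  sig_single <- single$gene[!is.na(single$adj_p) & single$adj_p < 0.05]
  expect_setequal(k1$consensus$gene, sig_single)
  expect_equal(setNames(k1$consensus$mean_l2fc, k1$consensus$gene),
               setNames(single$l2fc, single$gene)[k1$consensus$gene])
  k3 <- crossfold_consensus_dea(co$counts, co$nuclei, co$donors, "DA",
                                c("SUD+HIV-", "SUD-HIV-"), "sud",
                                k = 3, seed = 2)
  for (f in seq_len(3)) {
    fold_sig <- k3$folds[[f]]$gene[!is.na(k3$folds[[f]]$adj_p) &
                                     k3$folds[[f]]$adj_p < 0.05]
    expect_true(all(k3$consensus$gene %in% fold_sig))
  }
  expect_gte(mean(pd$gene %in% k3$consensus$gene), 0.8)
})
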