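# Shared fixture builders: everything is generated in code at test time.

group_sizes <- function(base = 2, ...) {
  out <- c("SUD-HIV-" = base, "SUD+HIV-" = base, "SUD-HIV+u" = base,
           "SUD+HIV+u" = base, "SUD-HIV+d" = base, "SUD+HIV+d" = base)
  dots <- c(...)
  out[names(dots)] <- dots
  out
}

four_type_cohort <- function(seed, n_nuclei = 100, n_genes = 300,
                             marker_l2fc = 2, donors = group_sizes(2)) {
  simulate_cohort(cohort_config(
    n_donors_per_group = donors,
    n_nuclei_per_donor = n_nuclei,
    cell_type_fractions = c(ODC = 0.25, Microglia = 0.25,
                            Astrocyte = 0.25, DA = 0.25),
    n_genes = n_genes, marker_l2fc = marker_l2fc, seed = seed))
}

single_type_config <- function(seed, donors = group_sizes(2),
                               n_nuclei = 100, n_genes = 400, ...) {
  cohort_config(
    n_donors_per_group = donors,
    n_nuclei_per_donor = n_nuclei,
    cell_type_fractions = c(DA = 1.0),
    n_genes = n_genes, seed = seed, ...)
}

planted_deg_frame <- function(n = 20, l2fc = 2, group = "SUD+HIV-",
                              base_mean = 1.0) {
  data.frame(cell_type = "DA", gene = sprintf("G%05d", seq_len(n)),
             group = group, l2fc = l2fc, base_mean = base_mean,
             stringsAsFactors = FALSE)
}

# minimal hand-built cluster profile for likelihood arithmetic tests
mock_profile <- function(l2fcs) {
  structure(list(cluster = "mock", n_nuclei = 100L,
                 hvgs = data.frame(gene = names(l2fcs),
                                   mean_l2fc = unname(l2fcs),
                                   max_adj_p = 1e-4,
                                   stringsAsFactors = FALSE)),
            class = "sn_cluster_profile")
}

ari <- snconsensus:::adjusted_rand_index
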