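test_that("planted markers survive every fold; null and sub-threshold genes do not", {
  co <- four_type_cohort(31, n_nuclei = 60, n_genes = 200, marker_l2fc = 3)
  prof <- find_distinguishing_hvgs(co$counts, co$truth$cell_type, k = 10,
                                   seed = 5)
  for (t in names(co$marker_db)) {
    expect_setequal(prof[[t]]$hvgs$gene, co$marker_db[[t]]$positive)
  }
  # a background gene with identical distribution everywhere is never called
  bg <- setdiff(colnames(co$counts),
                unlist(lapply(co$marker_db, `[[`, "positive")))
  for (t in names(prof)) {
    expect_length(intersect(prof[[t]]$hvgs$gene, bg), 0)
  }
})

test_that("the l2fc gate excludes significant but weak overexpression", {
  # markers planted at l2fc 0.5: significant by rank-sum yet below the gate
  co <- four_type_cohort(37, n_nuclei = 150, n_genes = 200,
                         marker_l2fc = 0.5)
  prof_gated <- find_distinguishing_hvgs(co$counts, co$truth$cell_type,
                                         k = 5, l2fc_min = 1.0, seed = 2)
  prof_open <- find_distinguishing_hvgs(co$counts, co$truth$cell_type,
                                        k = 5, l2fc_min = 0.1, seed = 2)
  got_gated <- unlist(lapply(prof_gated, function(p) p$hvgs$gene))
  got_open <- unlist(lapply(prof_open, function(p) p$hvgs$gene))
  markers <- unlist(lapply(co$marker_db, `[[`, "positive"))
  expect_length(intersect(got_gated, markers), 0)
  expect_gt(length(intersect(got_open, markers)), 0)
})

test_that("clusters smaller than k are rejected with advice", {
  co <- four_type_cohort(3, n_nuclei = 20, n_genes = 150)
  lab <- co$truth$cell_type
  lab[1:5] <- "tiny"
  lab[-(1:5)][lab[-(1:5)] == "tiny"] <- "ODC"
  expect_error(find_distinguishing_hvgs(co$counts, lab, k = 10),
               "smaller k")
})

test_that("log-likelihood evaluates the marker sums exactly", {
  pr <- mock_profile(c(A = 2.0, B = 1.5))
  db <- list(ct = list(positive = c("A", "B", "C"), negative = character(0)))
  expect_equal(unname(loglikelihood_scores(pr, db)["ct"]), 3.5)
  db0 <- list(ct = list(positive = c("X", "Y"), negative = character(0)))
  expect_equal(unname(loglikelihood_scores(pr, db0)["ct"]), 0)
  pr2 <- mock_profile(c(A = 2.0, B = 1.5))
  dbn <- list(ct = list(positive = "A", negative = "B"))
  expect_equal(unname(loglikelihood_scores(pr2, dbn, use_negative = TRUE)["ct"]),
               0.5)
  expect_equal(unname(loglikelihood_scores(pr2, dbn, use_negative = FALSE)["ct"]),
               2.0)
})

test_that("log-likelihood is additive over disjoint marker sets and unweighted", {
  pr <- mock_profile(c(A = 2, B = 1.5, C = 0.8, D = 3))
  db <- list(u = list(positive = c("A", "B", "C", "D")),
             p1 = list(positive = c("A", "C")),
             p2 = list(positive = c("B", "D")),
             perm = list(positive = c("D", "B", "C", "A")))
  ll <- loglikelihood_scores(pr, db)
  expect_equal(unname(ll["u"]), unname(ll["p1"] + ll["p2"]))
  expect_equal(unname(ll["u"]), unname(ll["perm"]))  # order never matters
  expect_true(all(ll >= 0))
})

test_that("assignment takes the argmax with deterministic, flagged ties", {
  pr <- mock_profile(c(A = 2.0, B = 1.5))
  profs <- structure(list(c1 = pr), class = "sn_cluster_profiles",
                     universe = c("A", "B"))
  db <- list(good = list(positive = c("A", "B")),
             poor = list(positive = "Z"))
  a <- assign_cell_types(profs, db)
  expect_equal(a$cell_type, "good")
  expect_false(a$tie)
  db_none <- list(x = list(positive = "Z"), y = list(positive = "W"))
  expect_equal(assign_cell_types(profs, db_none)$cell_type, "unassigned")
  # exact tie on ll: more contributing markers wins, then lexicographic
  db_tie <- list(zb = list(positive = c("A", "B")),
                 za = list(positive = c("A", "B")))
  at <- assign_cell_types(profs, db_tie)
  expect_true(at$tie)
  expect_equal(at$cell_type, "za")
  expect_error(assign_cell_types(profs, list()), "empty")
})

test_that("typing is exact on planted clusters and refinement merges and splits", {
  co <- four_type_cohort(41, n_nuclei = 120, n_genes = 250, marker_l2fc = 3)
  rk <- rank_hvgs(co$counts)
  pca <- scale_and_pca(co$counts, rk$gene[1:150], n_components = 15)
  # split ODC artificially in two; merge should reunite them
  lab <- co$truth$cell_type
  odc <- which(lab == "ODC")
  lab[odc[seq_along(odc) %% 2 == 0]] <- "ODCa"
  lab[lab == "ODC"] <- "ODCb"
  prof <- find_distinguishing_hvgs(co$counts, lab, k = 5, seed = 3)
  asg <- assign_cell_types(prof, co$marker_db)
  expect_equal(sort(unique(asg$cell_type)),
               c("Astrocyte", "DA", "Microglia", "ODC"))
  ref <- refine_clusters(co$counts, lab, asg, co$marker_db, pca$embedding,
                         k = 5, seed = 3)
  expect_equal(length(unique(ref$labels)), 4)
  expect_setequal(ref$assignments$cell_type,
                  c("Astrocyte", "DA", "Microglia", "ODC"))
  # no targets listed: labels unchanged apart from merges
  expect_setequal(unique(ref$labels),
                  unique(ref$merges[unique(lab)]))
  # a cluster hiding two planted types is separated by target subclustering
  lab2 <- co$truth$cell_type
  lab2[lab2 %in% c("DA", "Microglia")] <- "mixed"
  prof2 <- find_distinguishing_hvgs(co$counts, lab2, k = 5, seed = 3)
  asg2 <- assign_cell_types(prof2, co$marker_db)
  ref2 <- refine_clusters(co$counts, lab2, asg2, co$marker_db, pca$embedding,
                          subcluster_targets = "mixed", resolution = 0.5,
                          k = 5, seed = 3)
  expect_true(all(c("DA", "Microglia") %in% ref2$assignments$cell_type))
  truth_mixed <- co$truth$cell_type[lab2 == "mixed"]
  got_mixed <- ref2$labels[lab2 == "mixed"]
  typed <- ref2$assignments$cell_type[match(got_mixed,
                                            ref2$assignments$cluster)]
  expect_gte(mean(typed == truth_mixed), 0.95)
  expect_error(
    refine_clusters(co$counts, lab2, asg2, co$marker_db, pca$embedding,
                    subcluster_targets = "nope", k = 5),
    "not found")
})
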