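make_expr <- function(rows, donors = NULL) {
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- donors %||% paste0("d", seq_len(ncol(m)))
  m
}

test_that("donor mean expression averages normalized counts per donor and cell type", {
  # equal nucleus totals so normalization factors are exactly 1
  counts <- Matrix::Matrix(matrix(
    c(2, 4, 4, 2,
      4, 2, 2, 4), nrow = 4,
    dimnames = list(paste0("n", 1:4), c("gA", "gB"))), sparse = TRUE)
  nuclei <- data.frame(barcode = paste0("n", 1:4),
                       donor = c("d1", "d1", "d2", "d2"),
                       cell_type = c("DA", "DA", "DA", "MG"))
  degs <- data.frame(cell_type = c("DA", "MG"), gene = c("gA", "gA"),
                     direction = c("up", "down"))
  expr <- donor_mean_expression(counts, nuclei, degs, c("d1", "d2"))
  expect_equal(rownames(expr), c("DA_up_gA", "MG_down_gA"))
  expect_equal(expr["DA_up_gA", "d1"], 3)   # mean of {2, 4}
  expect_equal(expr["DA_up_gA", "d2"], 4)
  # d1 has no MG nuclei: missing value
  expect_true(is.na(expr["MG_down_gA", "d1"]))
  expect_equal(expr["MG_down_gA", "d2"], 2)
  expect_error(
    donor_mean_expression(counts, nuclei,
                          data.frame(cell_type = "DA", gene = "nope",
                                     direction = "up"), "d1"),
    "absent")
})

test_that("similarity gates correlation magnitude by significance", {
  a <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  g <- similarity_matrix(make_expr(list(
    x = a, y = 2 * a + 3, z = -a + 20)))
  expect_equal(g$r["x", "y"], 1)
  expect_lt(g$p["x", "y"], 0.05)
  expect_equal(g$sim["x", "y"], 1)
  expect_equal(g$dist["x", "y"], 0.5)
  # anti-correlation has the same similarity magnitude
  expect_equal(g$r["x", "z"], -1)
  expect_equal(g$sim["x", "z"], 1)
  # zero-variance row: flagged, similarity 0
  g2 <- similarity_matrix(make_expr(list(x = a, flat = rep(3, 10))))
  expect_true(g2$degenerate["flat"])
  expect_equal(g2$sim["x", "flat"], 0)
  expect_equal(g2$dist["x", "flat"], 1)
})

test_that("independent rows are significant at ~5% and p matches cor.test", {
  set.seed(5)
  expr <- matrix(rnorm(46 * 30), nrow = 46,
                 dimnames = list(paste0("r", 1:46), paste0("d", 1:30)))
  g <- similarity_matrix(expr)
  up <- upper.tri(g$p)
  frac <- mean(g$p[up] < 0.05)
  n_pairs <- sum(up)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n_pairs))
  # p-value formula agrees with R's cor.test
  ct <- cor.test(expr[1, ], expr[2, ])
  expect_equal(g$p[1, 2], ct$p.value, tolerance = 1e-12)
  # missing entries fall back to pairwise-complete donors
  expr[1, 1:5] <- NA
  g3 <- similarity_matrix(expr)
  ct2 <- cor.test(expr[1, 6:30], expr[2, 6:30])
  expect_equal(g3$p[1, 2], ct2$p.value, tolerance = 1e-12)
})

test_that("distance is the prescribed decreasing map of similarity", {
  sim <- seq(0, 1, by = 0.25)
  d <- 1 / (1 + sim)
  expect_equal(d[1], 1)          # sim 0 -> dist 1
  expect_equal(d[length(d)], 0.5)  # sim 1 -> dist 0.5
  expect_true(all(diff(d) < 0))
})

test_that("clean planted blocks become exactly the retained subclusters", {
  a <- rep(c(1, -1), 5)
  b <- rep(c(1, 1, -1, -1), length.out = 10)  # orthogonal to a
  rows <- c(lapply(1:5, function(i) a * i + i),
            lapply(1:5, function(i) b * i - i))
  names(rows) <- c(paste0("A", 1:5), paste0("B", 1:5))
  g <- similarity_matrix(make_expr(rows))
  sc <- cluster_and_split(g)
  expect_equal(sum(sc$table$retained), 2)
  expect_equal(sc$table$mean_sim[sc$table$retained], c(1, 1))
  got <- split(names(sc$assignment), sc$assignment)
  expect_true(any(vapply(got, setequal, TRUE, paste0("A", 1:5))))
  expect_true(any(vapply(got, setequal, TRUE, paste0("B", 1:5))))
  # naming convention C<cluster>S<subcluster>
  expect_true(all(grepl("^C[0-9]+S[0-9]+$", sc$table$name)))
})

test_that("a uniformly weak block is produced but not retained", {
  set.seed(11)
  # latent factor with modest loading over many donors: pairwise r ~ 0.3,
  # significant at n = 100, hence sim ~ 0.3
  f <- rnorm(100)
  rows <- lapply(1:6, function(i) f * 0.655 + rnorm(100))
  names(rows) <- paste0("w", 1:6)
  g <- similarity_matrix(make_expr(rows))
  sims <- g$sim[upper.tri(g$sim)]
  expect_gt(mean(sims), 0.1)
  expect_lt(mean(sims), 0.6)
  sc <- cluster_and_split(g)
  expect_false(any(sc$table$retained))
  # singleton input: flagged, never retained
  g1 <- similarity_matrix(make_expr(list(x = rnorm(10), y = rnorm(10))))
  sc1 <- cluster_and_split(g1)
  expect_true(all(!sc1$table$retained[sc1$table$n == 1]))
})

test_that("a 12-DEG 3-block instance matches the planted partition and survives relabeling", {
  a <- rep(c(1, -1), 6)
  b <- rep(c(1, 1, -1, -1), 3)
  cvec <- rep(c(1, 1, 1, -1, -1, -1), 2)
  base <- list(a, b, cvec)
  rows <- unlist(lapply(1:3, function(k) {
    lapply(1:4, function(i) base[[k]] * (i + k) + i)
  }), recursive = FALSE)
  names(rows) <- paste0(rep(c("X", "Y", "Z"), each = 4), 1:4)
  g <- similarity_matrix(make_expr(rows))
  sc <- cluster_and_split(g)
  truth <- rep(1:3, each = 4)
  expect_equal(ari(truth, sc$assignment[names(rows)]), 1)
  # shuffled input order: memberships unchanged up to names
  perm <- c(7, 2, 11, 4, 1, 9, 3, 12, 5, 8, 10, 6)
  g2 <- similarity_matrix(make_expr(rows[perm]))
  sc2 <- cluster_and_split(g2)
  expect_equal(ari(sc$assignment[names(rows)],
                   sc2$assignment[names(rows)]), 1)
  # subclusters partition their parent clusters
  expect_equal(sort(unlist(sc$members, use.names = FALSE)),
               sort(names(rows)))
})
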