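test_that("HVG ranking scores constant genes at zero and finds planted overdispersion", {
  set.seed(7)
  n <- 300
  x <- matrix(rpois(n * 30, 1), nrow = n)
  x[, 5] <- rnbinom(n, mu = 1, size = 1 / 3)   # strongly overdispersed
  x <- cbind(x, 2L)                            # constant gene
  colnames(x) <- c(sprintf("g%02d", 1:30), "const")
  rk <- rank_hvgs(Matrix::Matrix(x, sparse = TRUE))
  expect_equal(rk$gene[1], "g05")
  expect_equal(rk$score[rk$gene == "const"], 0)
  expect_equal(rk$rank[rk$gene == "const"], 31)
})

test_that("HVG scores are invariant to nucleus permutation and shared by duplicated genes", {
  set.seed(8)
  x <- matrix(rpois(200 * 20, 1.5), nrow = 200)
  x[, 2] <- x[sample(200), 1]   # gene 2 = gene 1 under a nucleus permutation
  colnames(x) <- sprintf("g%02d", 1:20)
  rk <- rank_hvgs(Matrix::Matrix(x, sparse = TRUE))
  expect_equal(rk$score[rk$gene == "g01"], rk$score[rk$gene == "g02"],
               tolerance = 1e-12)
  rk2 <- rank_hvgs(Matrix::Matrix(x[sample(200), ], sparse = TRUE))
  expect_equal(setNames(rk$score, rk$gene)[sort(colnames(x))],
               setNames(rk2$score, rk2$gene)[sort(colnames(x))],
               tolerance = 1e-12)
})

test_that("marker retention curve is monotone and saturates at full retention", {
  co <- four_type_cohort(3, n_nuclei = 50, n_genes = 150)
  rk <- rank_hvgs(co$counts)
  mrc <- marker_retention_curve(rk, co$marker_db)
  ret <- mrc$curve$n_markers_retained
  expect_true(all(diff(ret) >= 0))
  expect_equal(ret[length(ret)], mrc$n_markers)
  expect_equal(mrc$n_markers,
               length(unique(unlist(lapply(co$marker_db, `[[`, "positive")))))
  # elbow retention is at least the retention at 10% of genes
  expect_gte(ret[mrc$elbow], ret[ceiling(0.1 * nrow(rk))])
  expect_error(marker_retention_curve(rk, list()), "empty")
})

test_that("truncated PCA matches a dense eigendecomposition oracle", {
  set.seed(11)
  x <- matrix(rpois(5 * 4, 5), nrow = 5,
              dimnames = list(paste0("n", 1:5), paste0("g", 1:4)))
  p <- scale_and_pca(x, colnames(x), n_components = 2)
  z <- scale(x)[, , drop = TRUE]
  ev <- eigen(crossprod(z))
  for (j in 1:2) {
    expect_equal(abs(sum(p$transform$loadings[, j] * ev$vectors[, j])), 1,
                 tolerance = 1e-8)
  }
  expect_equal(colSums(p$embedding^2), ev$values[1:2], tolerance = 1e-8)
  # orthonormal loadings
  expect_equal(crossprod(p$transform$loadings), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("embedding variances are non-increasing and full rank reconstructs exactly", {
  co <- four_type_cohort(5, n_nuclei = 40, n_genes = 120)
  rk <- rank_hvgs(co$counts)
  hv <- rk$gene[1:60]
  p <- scale_and_pca(co$counts, hv, n_components = 20)
  v <- apply(p$embedding, 2L, var)
  expect_true(all(diff(v) <= 1e-10))
  full <- scale_and_pca(co$counts, hv,
                        n_components = length(p$transform$genes))
  z <- scale(as.matrix(co$counts[, full$transform$genes]))[, , drop = TRUE]
  recon <- full$embedding %*% t(full$transform$loadings)
  expect_lt(max(abs(recon - z)), 1e-6)
})

test_that("zero-variance HVGs are excluded from scaling with a warning", {
  x <- cbind(matrix(rpois(80, 2), nrow = 20), 3L)
  colnames(x) <- c(paste0("g", 1:4), "flat")
  expect_warning(p <- scale_and_pca(x, colnames(x), n_components = 2),
                 "zero-variance")
  expect_false("flat" %in% p$transform$genes)
})

test_that("batch-correction hooks honor their contracts", {
  set.seed(13)
  emb <- matrix(rnorm(60), nrow = 20)
  batch <- rep(c("a", "b"), each = 10)
  expect_identical(apply_batch_correction(emb, batch, "identity"), emb)
  shifted <- emb
  shifted[batch == "b", ] <- shifted[batch == "b", ] + 5
  cc <- apply_batch_correction(shifted, batch, "center")
  expect_equal(colMeans(cc[batch == "a", ]), colMeans(cc[batch == "b", ]),
               tolerance = 1e-9)
  # single batch: centering hook changes nothing
  expect_equal(apply_batch_correction(emb, rep("a", 20), "center"), emb,
               tolerance = 1e-12)
  expect_error(apply_batch_correction(emb, batch[1:5]), "length")
  hook <- function(e, b) e * 0
  expect_equal(apply_batch_correction(emb, batch, hook), emb * 0)
})

test_that("back-projection follows the staged dense oracle on a truncated toy case", {
  cfg <- single_type_config(19, n_nuclei = 50, n_genes = 80)
  co <- simulate_cohort(cfg)
  rk <- rank_hvgs(co$counts)
  hv <- rk$gene[1:30]
  p <- scale_and_pca(co$counts, hv, n_components = 2)
  got <- backproject_counts(p$embedding, p$transform, co$counts)
  # independent staged computation
  tr <- p$transform
  y <- p$embedding %*% t(tr$loadings)
  orig <- as.matrix(co$counts[, tr$genes, drop = FALSE])
  expected <- as.matrix(co$counts)
  for (k in seq_along(tr$genes)) {
    col <- y[, k]
    q1 <- quantile(col, 0.01, type = 7, names = FALSE)
    col[col <= q1] <- (0 - tr$means[k]) / tr$sds[k]
    col <- col + ((min(orig[, k]) - tr$means[k]) / tr$sds[k] - min(col))
    xv <- col * tr$sds[k] + tr$means[k]
    xv[xv < 0] <- 0
    expected[, tr$genes[k]] <- trunc(xv + 1e-6)
  }
  expect_identical(as.matrix(got), expected)
  expect_true(all(got@x >= 0))
  expect_true(all(got@x %% 1 == 0))
})

test_that("full-rank identity back-projection recovers counts and keeps zero genes zero", {
  cfg <- single_type_config(23, n_nuclei = 200, n_genes = 100)
  co <- simulate_cohort(cfg)
  counts <- co$counts
  counts[, "G00010"] <- 0   # an all-zero gene stays all-zero
  rk <- rank_hvgs(counts)
  hv <- rk$gene[rk$score > 0]
  p <- scale_and_pca(counts, hv, n_components = length(hv))
  emb <- apply_batch_correction(p$embedding, co$nuclei$library, "identity")
  bp <- backproject_counts(emb, p$transform, counts)
  expect_identical(as.matrix(bp), as.matrix(counts))
  expect_equal(sum(bp[, "G00010"]), 0)
})
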