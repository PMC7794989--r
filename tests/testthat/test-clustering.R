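# Normalization, phenotype clustering, PCA, phases, and the Ward cross-check.

test_that("gene-wise normalization matches its defining identities", {
  set.seed(8)
  ref <- data.frame(A = 2^rnorm(500, mean = 3, sd = 1.5),
                    B = 2^rnorm(500, mean = -1, sd = 0.5))
  st <- normalization_stats(ref, c("A", "B"))
  # a level at the reference geometric mean maps to z = 0
  probe <- data.frame(A = 2^st$mean[["A"]], B = 2^(st$mean[["B"]] + st$sd[["B"]]))
  z <- normalize_solutions(probe, st)
  expect_equal(z$A, 0)
  expect_equal(z$B, 1)
  # self-normalization: mean 0, sd 1 per node to machine precision
  zref <- normalize_solutions(ref, ref)
  expect_equal(mean(zref$A), 0, tolerance = 1e-10)
  expect_equal(sd(zref$A), 1, tolerance = 1e-10)
  # zero-variance reference is rejected, naming the node
  const <- data.frame(A = rep(4, 10), B = 2^rnorm(10))
  expect_error(normalization_stats(const, c("A", "B")), "node A")
  expect_error(normalize_solutions(data.frame(A = c(1, -1)), st), "node A")
})

test_that("k-means recovers well-separated blobs and orders labels by ZEB", {
  tbl <- blob_table()
  asg <- kmeans_phenotypes(tbl, k = 4, restarts = 10, seed = 7)
  expect_equal(as.character(asg$labels), tbl$truth)
  # labels sorted by ascending cluster-median ZEB
  med <- tapply(tbl$ZEB, asg$labels, median)
  expect_true(all(diff(med[c("e", "he", "hm", "m")]) > 0))
  # determinism under a fixed seed
  asg2 <- kmeans_phenotypes(tbl, k = 4, restarts = 10, seed = 7)
  expect_identical(asg$labels, asg2$labels)
  # label order is invariant to row permutation (relabeling test)
  perm <- sample(nrow(tbl))
  asg3 <- kmeans_phenotypes(tbl[perm, ], k = 4, restarts = 10, seed = 7)
  expect_equal(as.character(asg3$labels), tbl$truth[perm])
  expect_error(kmeans_phenotypes(tbl[1:3, ], k = 5), "exceeds")
  expect_error(kmeans_phenotypes(tbl[, -2], k = 4), "missing core node")
})

test_that("cluster quality metrics behave as their definitions require", {
  tbl <- blob_table(n_per = 40)
  q <- cluster_quality_sweep(tbl, k_range = 2:6, restarts = 5, seed = 3)
  expect_true(all(diff(q$inertia) <= 1e-8))          # non-increasing in k
  expect_true(all(q$silhouette >= -1 & q$silhouette <= 1))
  # four crisp blobs: every metric prefers k = 4
  expect_equal(q$k[which.max(q$silhouette)], 4)
  expect_equal(q$k[which.max(q$calinski_harabasz)], 4)
  expect_equal(q$k[which.min(q$davies_bouldin)], 4)
})

test_that("PCA summary is orthonormal with the ZEB-negative orientation", {
  tbl <- blob_table(n_per = 60)
  tbl$SNAIL <- rnorm(nrow(tbl), sd = 0.05)
  tbl$NFkB <- rnorm(nrow(tbl), sd = 0.05)
  p <- pca_summary(tbl)
  expect_equal(sum(p$variance_fraction), 1)
  L <- p$loadings
  expect_equal(crossprod(L), diag(ncol(L)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lt(L["ZEB", 1], 0)
  # 1-D data embedded in 6-D: PC1 explains everything
  t1 <- seq(-1, 1, length.out = 50)
  one <- data.frame(miR200 = t1, ZEB = -2 * t1, SNAIL = 0.5 * t1,
                    LIN28 = t1, let7 = -t1, NFkB = 0 * t1)
  expect_warning(p1 <- pca_summary(one), "constant")
  expect_equal(unname(p1$variance_fraction[1]), 1, tolerance = 1e-12)
})

test_that("phase labels aggregate states per parameter set", {
  labels <- c("e", "m", "m", "he", "e", "hm", "m")
  model_id <- c(1, 1, 2, 3, 3, 3, 4)
  n_states <- c(2, 2, 1, 3, 3, 3, 1)
  ph <- label_phases(labels, model_id, n_states)
  expect_equal(ph$phases$phase, c("{e,m}", "{m}", "{e,he,hm}", "{m}"))
  fr <- ph$frequencies
  for (cl in unique(fr$class)) {
    expect_equal(sum(fr$freq[fr$class == cl]), 1)
  }
  expect_error(label_phases(labels[-1], model_id[-1], n_states[-1]),
               "missing labeled")
})

test_that("Ward linkage agrees with k-means on separable data", {
  tbl <- blob_table(n_per = 40)
  wd <- ward_dendrogram(tbl, max_rows = 1000, groups = 4)
  expect_false(wd$subsampled)
  asg <- kmeans_phenotypes(tbl, k = 4, seed = 7)
  agree <- partition_agreement(as.character(asg$labels), wd$cut)
  expect_equal(agree, 1)
  # duplicated single point: merges at zero height
  one <- data.frame(miR200 = rep(1, 6), ZEB = 1, LIN28 = 1, let7 = 1)
  wd0 <- ward_dendrogram(one, groups = 2)
  expect_true(all(wd0$hclust$height < 1e-12))
})

test_that("partition agreement maximizes over label permutations", {
  a <- c("x", "x", "y", "y", "z", "z")
  b <- c(3, 3, 1, 1, 2, 2) # same partition, different labels
  expect_equal(partition_agreement(a, b), 1)
  expect_equal(partition_agreement(a, c(3, 1, 1, 1, 2, 2)), 5 / 6)
})
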