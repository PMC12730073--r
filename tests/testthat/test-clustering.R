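test_that("perfectly separated blocks are recovered under every linkage", {
  d <- two_block_dist(c(4, 4))
  truth <- rep(1:2, each = 4)
  for (lk in c("ward.D2", "average", "complete", "single", "centroid")) {
    part <- cut_partition(hclust_features(d, lk), 2)
    expect_equal(adjusted_rand_index(unclass(part), truth), 1,
                 info = lk)
  }
})

test_that("single linkage chains along a path while an outlier stays apart", {
  # features on a line at consecutive distance 1, plus one far outlier
  x <- c(0, 1, 2, 3, 4, 100)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("f", 1:6), paste0("f", 1:6))
  part <- cut_partition(hclust_features(d, "single"), 2)
  expect_equal(as.integer(part), c(1L, 1L, 1L, 1L, 1L, 2L))
})

test_that("merge sequences equal the naive agglomeration oracle for all linkages", {
  set.seed(301)
  for (rep in 1:20) {
    n <- sample(6:9, 1)
    cfg <- random_point_config(n)
    for (lk in c("ward.D2", "average", "complete", "single", "centroid")) {
      hc <- hclust_features(cfg$d, lk)
      oracle <- oracle_agglomerate(cfg$d, lk, coords = cfg$coords)
      expect_identical(merge_sets(hc), oracle$merges,
                       info = paste(lk, "rep", rep))
      if (lk != "ward.D2") {
        expect_equal(hc$height, oracle$heights, tolerance = 1e-9,
                     info = paste(lk, "heights"))
      }
    }
  }
})

test_that("ward.D2 heights match the centroid-based merge cost", {
  set.seed(302)
  cfg <- random_point_config(8)
  hc <- hclust_features(cfg$d, "ward.D2")
  oracle <- oracle_agglomerate(cfg$d, "ward.D2", coords = cfg$coords)
  expect_equal(hc$height, oracle$heights, tolerance = 1e-9)
  # and agrees with stats::hclust on the same input
  ref <- hclust(as.dist(cfg$d), method = "ward.D2")
  expect_equal(hc$height, ref$height, tolerance = 1e-9)
})

test_that("partition is invariant to feature input order", {
  set.seed(303)
  cfg <- random_point_config(9)
  part <- cut_partition(hclust_features(cfg$d, "average"), 3)
  perm <- sample(9)
  dp <- cfg$d[perm, perm]
  part2 <- cut_partition(hclust_features(dp, "average"), 3)
  expect_equal(adjusted_rand_index(part, part2), 1)
})

test_that("cutting at k then k-1 merges exactly two clusters", {
  set.seed(304)
  cfg <- random_point_config(10)
  for (lk in c("ward.D2", "single", "centroid")) {
    hc <- hclust_features(cfg$d, lk)
    for (k in 3:8) {
      pk <- cut_partition(hc, k)
      pk1 <- cut_partition(hc, k - 1)
      # every k-1 cluster is a union of k-clusters; exactly one union of two
      tab <- table(unclass(pk), unclass(pk1))
      expect_equal(sum(colSums(tab > 0) == 2), 1)
      expect_equal(sum(colSums(tab > 0) == 1), k - 2)
    }
  }
})

test_that("hclust input validation and linkage compatibility warnings", {
  expect_error(hclust_features(matrix(0, 1, 1)), "singleton")
  expect_error(hclust_features(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  set.seed(305)
  X <- matrix(rnorm(40), 8, 5, dimnames = list(NULL, paste0("f", 1:5)))
  fd <- feature_distance(X, "manhattan")
  expect_warning(hclust_features(fd, "ward.D2"), "Euclidean-compatible")
  expect_warning(hclust_features(fd, "centroid"), "Euclidean-compatible")
  fdp <- feature_distance(X, "pearson")
  expect_no_warning(hclust_features(fdp, "ward.D2"))   # sqrt(2(1-r)) embeds
  hc <- suppressWarnings(hclust_features(fd, "ward.D2"))
  expect_error(cut_partition(hc, 9), "out of range")
})

test_that("internal indices behave on constructed geometries", {
  d <- two_block_dist(c(5, 5), within = 0.1, between = 2)
  part <- cut_partition(hclust_features(d, "average"), 2)
  idx <- internal_indices(part, d)
  expect_gt(idx$silhouette, 0.9)
  expect_gt(idx$dunn, 1)
  expect_gt(idx$ch, 100)
  expect_true(abs(idx$silhouette) <= 1)

  # near-uniform distances, one giant cluster + singleton: silhouette ~ 0
  set.seed(306)
  n <- 8
  du <- matrix(1, n, n) + matrix(runif(n * n, -0.01, 0.01), n)
  du <- (du + t(du)) / 2
  diag(du) <- 0
  dimnames(du) <- list(paste0("f", 1:n), paste0("f", 1:n))
  lab <- structure(c(rep(1L, n - 1), 2L), names = rownames(du), class = "partition")
  idx2 <- internal_indices(lab, du)
  expect_lt(abs(idx2$silhouette), 0.05)
  expect_true(is_degenerate_partition(lab))
})

test_that("silhouette agrees with the cluster-package reference", {
  set.seed(307)
  cfg <- random_point_config(12)
  for (k in 2:4) {
    part <- cut_partition(hclust_features(cfg$d, "complete"), k)
    ref <- cluster::silhouette(as.integer(part), dmatrix = cfg$d)
    expect_equal(internal_indices(part, cfg$d)$silhouette,
                 mean(ref[, "sil_width"]), tolerance = 1e-12)
  }
})

test_that("consensus k finds planted block counts with full support", {
  set.seed(308)
  X <- block_feature_matrix(n = 60, block_sizes = c(6, 6, 6), w = 0.95)
  d <- feature_distance(X, "pearson")
  ks <- select_k_consensus(d, "average")
  expect_equal(ks$consensus_k, 3)
  expect_equal(ks$support, 1)

  X2 <- block_feature_matrix(n = 60, block_sizes = c(8, 8), w = 0.95)
  ks2 <- select_k_consensus(feature_distance(X2, "pearson"), "ward.D2")
  expect_equal(ks2$consensus_k, 2)
})

test_that("early stop halts the scan under persistent disagreement and is reported", {
  set.seed(309)
  # structureless distances: indices disagree, majority support stays low
  n <- 25
  du <- matrix(runif(n * n, 0.9, 1.1), n)
  du <- (du + t(du)) / 2
  diag(du) <- 0
  dimnames(du) <- list(paste0("f", 1:n), paste0("f", 1:n))
  ks <- select_k_consensus(du, "average", k_range = 2:20,
                           early_stop = list(threshold = 0.9, patience = 2))
  full <- select_k_consensus(du, "average", k_range = 2:20,
                             early_stop = list(threshold = 0, patience = 3))
  expect_true(is.na(full$stopped_early_at))
  expect_equal(length(full$scanned_k), 19)
  if (!is.na(ks$stopped_early_at)) {
    expect_lt(length(ks$scanned_k), 19)
    expect_equal(max(ks$scanned_k), ks$stopped_early_at)
  }
  # consensus ties break toward smaller k: constructed two-index tie
  expect_error(select_k_consensus(du, "average", k_range = 30:40), "no valid k")
})
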