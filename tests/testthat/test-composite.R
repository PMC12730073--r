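test_that("KS statistic anchors and exhaustive-sweep oracle", {
  set.seed(501)
  a <- rnorm(15)
  expect_equal(ks_statistic(a, a), 0)
  expect_equal(ks_statistic(1:5, 11:15), 1)       # disjoint supports
  expect_equal(ks_statistic(c(1, 2, 3, 4), c(2, 3, 4, 5)),
               oracle_ks_sweep(c(1, 2, 3, 4), c(2, 3, 4, 5)))
  expect_equal(oracle_ks_sweep(c(1, 2, 3, 4), c(2, 3, 4, 5)), 0.25)
  for (rep in 1:20) {
    x <- rnorm(sample(5:30, 1)); y <- rnorm(sample(5:30, 1), mean = runif(1, 0, 2))
    expect_equal(ks_statistic(x, y), oracle_ks_sweep(x, y), tolerance = 1e-12)
    # agreement with the stats reference
    expect_equal(ks_statistic(x, y),
                 unname(suppressWarnings(ks.test(x, y))$statistic),
                 tolerance = 1e-12)
  }
  expect_error(ks_statistic(numeric(), 1:3), "empty")
})

test_that("mean fractional ratio: zero at equal means, log-ratio otherwise", {
  a <- c(1, 2, 3); b <- c(3, 2, 1)                 # equal means
  expect_equal(mean_fractional_ratio(a, b), 0)
  expect_equal(mean_fractional_ratio(c(2, 2), c(1, 1), epsilon = 0), log(2))
  expect_equal(mean_fractional_ratio(c(1, 1), c(2, 2), epsilon = 0,
                                     signed = TRUE), -log(2))
  set.seed(502)
  x <- rnorm(10)
  for (eps in c(0, 1e-6, 1e-2)) {
    expect_equal(mean_fractional_ratio(x, x, epsilon = eps), 0)
  }
  # epsilon keeps a zero-mean comparison defined
  expect_true(is.finite(mean_fractional_ratio(c(-1, 1), c(2, 2))))
})

test_that("robust z-score: median maps to zero, MAD scaling, fallbacks", {
  v <- c(1, 2, 3, 4, 100)
  z <- robust_z(v)
  expect_equal(z[which(v == median(v))], 0)
  # hand arithmetic: median 3, MAD = 1.4826 * median(|x - 3|) = 1.4826
  expect_equal(z[5], (100 - 3) / (1.4826 * 1), tolerance = 1e-12)
  expect_equal(robust_z(rep(7, 5)), rep(0, 5))     # constant -> all zeros
  # MAD = 0 but IQR > 0 engages the fallback scale
  v2 <- c(1, 5, 5, 5, 5, 5, 9, 9, 9)
  expect_true(stats::mad(v2) == 0 && stats::IQR(v2) > 0)
  expect_false(all(robust_z(v2) == 0))
  expect_error(robust_z(1), "length >= 2")
})

test_that("identical tables give the flagged degenerate all-zero CI", {
  set.seed(503)
  X <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, paste0("f", 1:10)))
  rec <- composite_index(make_pair(X))
  expect_equal(rec$r, rep(1, 10))
  expect_true(all(rec$ks == 0))
  expect_true(all(rec$mfr == 0))
  expect_true(all(rec$ci == 0))
  expect_true(attr(rec, "degenerate"))
})

test_that("a single high-fidelity feature strictly tops the CI ranking", {
  set.seed(504)
  n <- 60
  A <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, sprintf("f%02d", 1:10)))
  B <- A
  B[, 1] <- A[, 1] + rnorm(n, sd = 0.05)                 # near-perfect copy
  for (j in 2:10) B[, j] <- 3 * A[, j]^3 + rnorm(n, sd = 2)  # corrupted: r low, KS/MFR high
  rec <- composite_index(make_pair(A, B))
  expect_equal(rec$feature[which.max(rec$ci)], "f01")
  expect_gt(sort(rec$ci, decreasing = TRUE)[1] - sort(rec$ci, decreasing = TRUE)[2], 0)
  # invariant check on components
  expect_gt(rec$r[1], 0.99)
  expect_true(all(rec$ks[-1] >= 0.2))
})

test_that("CI is invariant under a common positive rescaling of one feature", {
  set.seed(505)
  X <- matrix(rnorm(50 * 8), 50, 8, dimnames = list(NULL, paste0("f", 1:8)))
  Y <- X + matrix(rnorm(400, sd = 0.2), 50)
  X2 <- X; Y2 <- Y
  X2[, 3] <- 10 * X[, 3]; Y2[, 3] <- 10 * Y[, 3]
  # exact with epsilon = 0 (the stabilizer breaks pure scale invariance by
  # a term of order epsilon/|mean|)
  base <- composite_index(make_pair(X, Y), epsilon = 0)
  mod <- composite_index(make_pair(X2, Y2), epsilon = 0)
  expect_equal(mod$r, base$r, tolerance = 1e-12)
  expect_equal(mod$ks, base$ks, tolerance = 1e-12)
  expect_equal(mod$mfr, base$mfr, tolerance = 1e-9)
  expect_equal(mod$ci, base$ci, tolerance = 1e-9)
  # and near-exact at the default epsilon
  expect_equal(composite_index(make_pair(X2, Y2))$ci,
               composite_index(make_pair(X, Y))$ci, tolerance = 1e-4)
})

test_that("composite_index validates its inputs", {
  set.seed(506)
  X <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("f1", "f2", "f3")))
  pair <- make_pair(X)
  expect_error(composite_index(pair, features = c("f1", "f2")), ">= 3 features")
  expect_error(composite_index(pair, features = c("f1", "f2", "zz")),
               "not in the aligned pair")
})

test_that("winner selection: argmax, near-winner delta, tie and floor rules", {
  part <- structure(c(a = 1L, b = 1L, c = 1L, d = 2L, e = 2L), class = "partition")
  rec <- data.frame(feature = c("a", "b", "c", "d", "e"),
                    r = 1, ci = c(2.0, 1.9, 0.2, 1.0, 1.0))
  sel <- select_winners(part, rec, delta = 0.3)
  s1 <- sel$selected[sel$selected$cluster == 1, ]
  expect_equal(s1$feature[s1$role == "winner"], "a")
  expect_equal(s1$feature[s1$role == "near_winner"], "b")
  expect_false("c" %in% s1$feature)
  # exact tie in cluster 2: lexicographic winner, other is co-winner
  s2 <- sel$selected[sel$selected$cluster == 2, ]
  expect_equal(s2$feature[s2$role == "winner"], "d")
  expect_equal(s2$feature[s2$role == "co_winner"], "e")
  expect_setequal(winners(sel), c("a", "d", "e"))
  expect_equal(winners(sel, include_co_winners = FALSE), c("a", "d"))
  # absolute floor drops cluster 1's best? no - drops clusters whose best < floor
  sel2 <- select_winners(part, rec, delta = 0.3, ci_floor = 1.5)
  expect_equal(unique(sel2$selected$cluster), 1)
  expect_equal(sel2$skipped_clusters$cluster, 2)
  # clusters with no scored feature are reported, skipped
  sel3 <- select_winners(part, rec[rec$feature != "d" & rec$feature != "e", ],
                         delta = 0.3)
  expect_equal(sel3$skipped_clusters$cluster, 2)
})

test_that("number of winners equals k for fully scored partitions", {
  set.seed(507)
  X <- block_feature_matrix(n = 50, block_sizes = c(5, 5, 5), w = 0.9)
  Y <- X + matrix(rnorm(length(X), sd = 0.1), nrow(X))
  pair <- make_pair(X, Y)
  rec <- composite_index(pair)
  part <- cut_partition(hclust_features(feature_distance(pair$table_a, "pearson"),
                                        "ward.D2"), 3)
  sel <- select_winners(part, rec)
  expect_equal(sum(sel$selected$role == "winner"), 3)
})

test_that("qc_filter drops weak correlations and redundant near-winners", {
  part <- structure(c(a = 1L, b = 1L, c = 2L), class = "partition")
  rec <- data.frame(feature = c("a", "b", "c"),
                    r = c(0.95, 0.92, 0.3), ci = c(2, 1.8, 1))
  sel <- select_winners(part, rec, delta = 0.5)
  fcor <- matrix(c(1, 0.99, 0, 0.99, 1, 0, 0, 0, 1), 3, 3,
                 dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  out <- qc_filter(sel, rec, fcor, min_corr = 0.5, redundancy_cutoff = 0.9)
  expect_equal(out$final_set, "a")                 # b redundant with a; c weak r
  expect_setequal(out$dropped$feature, c("b", "c"))
  expect_match(out$dropped$reason[out$dropped$feature == "b"], "redundant")
  expect_match(out$dropped$reason[out$dropped$feature == "c"], "inter-platform r")
})

test_that("final set never contains a redundant within-cluster pair", {
  set.seed(508)
  for (rep in 1:5) {
    X <- block_feature_matrix(n = 40, block_sizes = c(6, 6), w = 0.95)
    Y <- X + matrix(rnorm(length(X), sd = 0.1), nrow(X))
    pair <- make_pair(X, Y)
    rec <- composite_index(pair)
    part <- cut_partition(hclust_features(feature_distance(pair$table_a, "pearson"),
                                          "average"), 2)
    sel <- select_winners(part, rec, delta = 10)   # large delta: many survivors
    fcor <- feature_cor_matrix(pair)
    cutoff <- 0.9
    out <- qc_filter(sel, rec, fcor, min_corr = 0, redundancy_cutoff = cutoff)
    kept <- out$final_set
    expect_gt(length(kept), 0)
    for (cl in unique(part)) {
      mates <- intersect(kept, names(part)[part == cl])
      if (length(mates) > 1) {
        cc <- abs(fcor[mates, mates])
        expect_lte(max(cc[upper.tri(cc)]), cutoff)
      }
    }
  }
})

test_that("winner frequencies count winners and near-winners per solution", {
  mk_sel <- function(winner, near = character()) {
    structure(list(selected = data.frame(
      feature = c(winner, near), cluster = 1L,
      ci = seq(2, by = -0.1, length.out = length(winner) + length(near)),
      role = c(rep("winner", length(winner)), rep("near_winner", length(near)))),
      skipped_clusters = data.frame(), delta = 0.5, ci_floor = -Inf, k = 1L),
      class = "selection_result")
  }
  sols <- list(mk_sel("x"), mk_sel("x"), mk_sel("x"))
  freq <- aggregate_winner_frequencies(sols)
  expect_equal(freq$n_winner[freq$feature == "x"], 3)
  sols2 <- list(mk_sel("x"), mk_sel("x", near = "y"),
                mk_sel("y", near = "x"))
  freq2 <- aggregate_winner_frequencies(sols2)
  expect_equal(freq2$n_winner[freq2$feature == "x"], 2)
  expect_equal(freq2$n_winner_or_near[freq2$feature == "x"], 3)
  expect_equal(freq2$n_winner[freq2$feature == "y"], 1)
  expect_equal(freq2$n_winner_or_near[freq2$feature == "y"], 2)
  expect_error(aggregate_winner_frequencies(list()), "at least one")
})
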