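# Fixture builders shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a small feature CSV and return its path.
write_feature_csv <- function(values, lesion_ids = rownames(values),
                              path = tempfile(fileext = ".csv")) {
  df <- data.frame(lesion_id = lesion_ids, values, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# A distance matrix with two well-separated blocks of features.
two_block_dist <- function(sizes = c(4, 4), within = 0.1, between = 2.0) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  d <- matrix(between, n, n)
  for (b in seq_along(sizes)) d[lab == b, lab == b] <- within
  diag(d) <- 0
  dimnames(d) <- list(paste0("f", 1:n), paste0("f", 1:n))
  d
}

# Random feature points in Euclidean space plus their distance matrix
# (Euclidean-compatible by construction, for ward.D2/centroid oracles).
random_point_config <- function(n, m = 3) {
  coords <- matrix(rnorm(n * m), n, m)
  d <- as.matrix(dist(coords))
  dimnames(d) <- list(paste0("f", 1:n), paste0("f", 1:n))
  list(coords = coords, d = d)
}

# Aligned pair built directly from two value matrices over shared lesions.
make_pair <- function(A, B = A) {
  align_platforms(feature_table(A, platform_id = "a"),
                  feature_table(B, platform_id = "b"))
}

# A single stability-grid record row (for select_stable_configs tests).
grid_rec <- function(metric, linkage, ari, sil) {
  data.frame(metric = metric, linkage = linkage, k_a = 3L, k_b = 3L,
             ari = ari, silhouette_a = sil, silhouette_b = sil,
             dunn_a = 1, dunn_b = 1, degenerate_a = FALSE,
             degenerate_b = FALSE, error = NA_character_, stable = NA)
}

# Block-structured lesion-by-feature matrix with named features.
block_feature_matrix <- function(n = 40, block_sizes = c(5, 5, 5), w = 0.9) {
  p <- sum(block_sizes)
  lab <- rep(seq_along(block_sizes), block_sizes)
  Z <- matrix(rnorm(n * length(block_sizes)), n)
  X <- sqrt(w) * Z[, lab] + sqrt(1 - w) * matrix(rnorm(n * p), n)
  colnames(X) <- paste0("f", seq_len(p))
  rownames(X) <- paste0("lesion", seq_len(n))
  attr(X, "block") <- lab
  X
}
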