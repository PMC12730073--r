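# Independent oracles used across the suite. Each takes a deliberately
# different computational route from the package implementation.

# ICC(A,1) via stats::aov two-way ANOVA mean squares.
oracle_icc_aov <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   subject = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- anova(stats::aov(y ~ subject + rater, data = df))$`Mean Sq`
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Naive double-loop pairwise distances between feature columns.
oracle_dist_loop <- function(X, metric) {
  p <- ncol(X)
  d <- matrix(0, p, p, dimnames = list(colnames(X), colnames(X)))
  for (j in seq_len(p)) for (k in seq_len(p)) {
    a <- X[, j]; b <- X[, k]
    d[j, k] <- switch(metric,
      euclidean = sqrt(sum((a - b)^2)),
      manhattan = sum(abs(a - b)),
      cosine = 1 - sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2))),
      pearson = sqrt(2 * (1 - stats::cor(a, b))),
      spearman = sqrt(2 * (1 - stats::cor(a, b, method = "spearman"))))
  }
  diag(d) <- 0   # self-distance is 0 by definition; avoids sqrt round-off
  d
}

# Exhaustive pair-counting ARI: loop over all unordered item pairs.
oracle_ari_pairs <- function(p, q) {
  n <- length(p)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_p <- p[i] == p[j]
    same_q <- q[i] == q[j]
    if (same_p && same_q) s11 <- s11 + 1
    else if (!same_p && !same_q) s00 <- s00 + 1
    else if (same_p) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  tot <- s11 + s00 + s10 + s01
  exp_idx <- (s11 + s10) * (s11 + s01) / tot
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (abs(max_idx - exp_idx) < 1e-12) {
    return(if (s10 + s01 == 0) 1 else 0)
  }
  (s11 - exp_idx) / (max_idx - exp_idx)
}

# All set partitions of 1..n as label vectors (restricted growth strings).
enumerate_partitions <- function(n) {
  out <- list()
  rec <- function(labels, next_max) {
    i <- length(labels) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- labels; return() }
    for (v in seq_len(next_max + 1L)) {
      rec(c(labels, v), max(next_max, v))
    }
  }
  rec(integer(), 0L)
  out
}

# Naive O(n^3) agglomeration from first principles. Clusters are member
# sets; inter-cluster distances are recomputed each step by definition:
# single/complete/average from the pairwise matrix, ward.D2/centroid from
# the coordinates that generated it. Returns the merge sequence as a list
# of sorted member vectors, plus merge heights.
oracle_agglomerate <- function(d, linkage, coords = NULL) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  merges <- list()
  heights <- numeric()
  cluster_dist <- function(ci, cj) {
    cross <- d[ci, cj, drop = FALSE]
    switch(linkage,
      single = min(cross),
      complete = max(cross),
      average = mean(cross),
      ward.D2 = {
        ca <- colMeans(coords[ci, , drop = FALSE])
        cb <- colMeans(coords[cj, , drop = FALSE])
        sqrt(2 * length(ci) * length(cj) / (length(ci) + length(cj)) *
               sum((ca - cb)^2))
      },
      centroid = {
        ca <- colMeans(coords[ci, , drop = FALSE])
        cb <- colMeans(coords[cj, , drop = FALSE])
        sqrt(sum((ca - cb)^2))
      })
  }
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestv <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      v <- cluster_dist(clusters[[i]], clusters[[j]])
      if (v < bestv) { bestv <- v; best <- c(i, j) }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1L]] <- merged
    heights <- c(heights, bestv)
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
  }
  list(merges = merges, heights = heights)
}

# Merge sequence of a feature_hclust tree as sorted member-index sets.
merge_sets <- function(hc) {
  n <- length(hc$labels)
  members <- vector("list", n - 1L)
  lapply(seq_len(n - 1L), function(s) {
    get <- function(v) if (v < 0) -v else members[[v]]
    members[[s]] <<- sort(c(get(hc$merge[s, 1]), get(hc$merge[s, 2])))
    members[[s]]
  })
}

# Exhaustive ECDF sweep for the two-sample KS statistic.
oracle_ks_sweep <- function(a, b) {
  breaks <- sort(c(a, b))
  max(vapply(breaks, function(t) abs(mean(a <= t) - mean(b <= t)), 0))
}
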