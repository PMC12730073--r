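## Agglomerative hierarchical clustering of features with deterministic
## tie-breaking, merge-order dendrogram cuts, internal validity indices and
## majority-rule consensus selection of k.

LINKAGES <- c("ward.D2", "average", "complete", "single", "centroid")

#' Agglomerative hierarchical clustering of features
#'
#' Iteratively merges the closest pair of clusters under the chosen linkage,
#' starting from singleton features, using the Lance-Williams recurrence:
#'
#' * `single` — minimum distance between members of the two clusters;
#' * `complete` — maximum pairwise distance;
#' * `average` — mean distance over all cross-cluster pairs (UPGMA);
#' * `ward.D2` — merge minimizing the increase in total within-cluster
#'   variance (recurrence applied to squared distances, heights reported on
#'   the original distance scale);
#' * `centroid` — distance between cluster centroids (squared-distance
#'   recurrence; heights may invert, which is inherent to this linkage).
#'
#' ward.D2 and centroid are geometrically meaningful only for distances with
#' a Euclidean embedding; the correlation distance sqrt(2(1-r)) is such an
#' embedding, but manhattan/cosine inputs are not, so those combinations are
#' accepted with a warning.
#'
#' Ties in the minimum are broken deterministically toward the lowest
#' (column, row) cluster-slot pair in column-major scan order, so the merge
#' sequence is invariant across platforms and (given identical distances)
#' across feature input orderings.
#'
#' @param d a [feature_distance()] result, or a symmetric distance matrix.
#' @param linkage one of `"ward.D2"`, `"average"`, `"complete"`,
#'   `"single"`, `"centroid"`.
#' @return an object of classes `feature_hclust` and `hclust` with the
#'   usual `merge`, `height`, `order`, `labels`, `method` components.
#' @export
hclust_features <- function(d, linkage = LINKAGES) {
  linkage <- match.arg(linkage)
  metric <- NULL
  if (inherits(d, "feature_dist")) {
    metric <- d$metric
    d <- d$d
  }
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("empty or singleton distance matrix")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)) || any(diag(d) != 0))
    stop("d must be symmetric with zero diagonal")
  if (linkage %in% c("ward.D2", "centroid") &&
      !is.null(metric) && metric %in% c("manhattan", "cosine")) {
    warning(linkage, " linkage assumes a Euclidean-compatible distance; '",
            metric, "' is not -- results are exploratory")
  }
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("f", seq_len(n))

  squared <- linkage %in% c("ward.D2", "centroid")
  D <- if (squared) d^2 else d
  diag(D) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  slot_id <- -seq_len(n)            # hclust encoding: negatives = singletons
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (s in seq_len(n - 1L)) {
    idx <- which.min(D)             # column-major => deterministic tie-break
    j <- (idx - 1L) %/% n + 1L
    i <- idx - (j - 1L) * n
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    v <- D[i, j]
    height[s] <- if (squared) sqrt(v) else v
    merge[s, ] <- sort(c(slot_id[i], slot_id[j]))

    ni <- size[i]; nj <- size[j]; nk <- size
    new <- switch(linkage,
      single   = pmin(D[i, ], D[j, ]),
      complete = pmax(D[i, ], D[j, ]),
      average  = (ni * D[i, ] + nj * D[j, ]) / (ni + nj),
      ward.D2  = ((ni + nk) * D[i, ] + (nj + nk) * D[j, ] - nk * v) /
                 (ni + nj + nk),
      centroid = (ni * D[i, ] + nj * D[j, ] - (ni * nj / (ni + nj)) * v) /
                 (ni + nj)
    )
    D[i, ] <- new
    D[, i] <- new
    D[i, i] <- Inf
    D[j, ] <- Inf
    D[, j] <- Inf
    active[j] <- FALSE
    size[i] <- ni + nj
    slot_id[i] <- s
  }

  hc <- structure(
    list(merge = merge, height = height, order = dendrogram_order(merge),
         labels = labels, method = linkage,
         dist.method = metric %||% "unknown", call = match.call()),
    class = c("feature_hclust", "hclust"))
  hc
}

# Leaf ordering by iterative traversal of the merge tree (plot support only).
dendrogram_order <- function(merge) {
  n <- nrow(merge) + 1L
  members <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    left <- merge[s, 1]
    right <- merge[s, 2]
    lv <- if (left < 0) -left else members[[left]]
    rv <- if (right < 0) -right else members[[right]]
    members[[s]] <- c(lv, rv)
  }
  as.integer(members[[n - 1L]])
}

#' Cut a feature dendrogram into k clusters
#'
#' Cuts by merge order (the first `n - k` merges are applied), which remains
#' well defined when centroid linkage produces height inversions. Cluster
#' ids are relabeled 1..k in order of first appearance along the feature
#' ordering, so the labeling is deterministic.
#'
#' @param hc a [hclust_features()] tree.
#' @param k number of clusters, `2 <= k <= n`.
#' @return object of class `partition`: named integer vector (feature ->
#'   cluster id in 1..k) with the configuration in attributes.
#' @export
cut_partition <- function(hc, k) {
  n <- length(hc$labels)
  if (k < 1 || k > n) stop("k out of range [1, ", n, "]")
  grp <- -seq_len(n)                # current group id in merge encoding
  if (k < n) {
    for (s in seq_len(n - k)) {
      grp[grp %in% hc$merge[s, ]] <- s
    }
  }
  lab <- match(grp, unique(grp))    # 1..k in order of first appearance
  stopifnot(length(unique(lab)) == k)
  structure(stats::setNames(as.integer(lab), hc$labels),
            class = "partition",
            k = as.integer(k), linkage = hc$method, metric = hc$dist.method)
}

#' @export
print.partition <- function(x, ...) {
  cat("<partition> k =", attr(x, "k"),
      "| metric:", attr(x, "metric") %||% "?",
      "| linkage:", attr(x, "linkage") %||% "?", "\n")
  print(table(cluster = unclass(x)))
  invisible(x)
}

#' Internal cluster validity indices from a distance matrix
#'
#' * **silhouette** — mean over features of `(b - a) / max(a, b)` where `a`
#'   is the mean distance to the feature's own cluster and `b` the smallest
#'   mean distance to another cluster; singletons score 0 by convention.
#' * **dunn** — minimum between-cluster distance divided by the maximum
#'   within-cluster diameter (`Inf` when every cluster is a single point).
#' * **ch** — Calinski-Harabasz ratio `(B/(k-1)) / (W/(n-k))` with between-
#'   and within-cluster dispersion obtained from squared pairwise distances
#'   via the Euclidean sum-of-squares identity
#'   `SS(cluster) = sum_{i<j in cluster} d_ij^2 / n_cluster`, so the index
#'   is computable from the distance matrix alone.
#'
#' @param partition a [cut_partition()] labeling.
#' @param d the `feature_dist` (or matrix) the partition was built from.
#' @return named list: `silhouette` in \[-1, 1\], `dunn` >= 0, `ch` >= 0.
#' @export
internal_indices <- function(partition, d) {
  if (inherits(d, "feature_dist")) d <- d$d
  d <- as.matrix(d)
  lab <- as.integer(partition)
  nm <- names(partition)
  if (!is.null(nm) && !is.null(rownames(d))) {
    if (!setequal(nm, rownames(d))) stop("partition and d feature sets differ")
    d <- d[nm, nm, drop = FALSE]
  }
  n <- length(lab)
  stopifnot(nrow(d) == n)
  k <- length(unique(lab))
  if (k < 2 || k >= n + 1) stop("need 2 <= k <= n non-empty clusters")
  sizes <- tabulate(lab, k)

  # silhouette
  cl_sum <- rowsum_by_cluster(d, lab, k)   # n x k: sum of distances to each cluster
  sil <- numeric(n)
  for (i in seq_len(n)) {
    ci <- lab[i]
    if (sizes[ci] == 1) { sil[i] <- 0; next }
    a <- cl_sum[i, ci] / (sizes[ci] - 1)
    b <- min(cl_sum[i, -ci] / sizes[-ci])
    sil[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }

  # dunn
  inter <- Inf
  diam <- 0
  for (c1 in seq_len(k)) {
    in1 <- lab == c1
    dd <- d[in1, in1, drop = FALSE]
    if (sum(in1) > 1) diam <- max(diam, max(dd))
    for (c2 in seq_len(k)) {
      if (c2 <= c1) next
      inter <- min(inter, min(d[in1, lab == c2, drop = FALSE]))
    }
  }
  dunn <- if (diam > 0) inter / diam else Inf

  # Calinski-Harabasz via sum-of-squares identity on d^2
  d2 <- d^2
  tot <- sum(d2[upper.tri(d2)]) / n
  within <- 0
  for (c1 in seq_len(k)) {
    in1 <- lab == c1
    if (sizes[c1] > 1) {
      dd <- d2[in1, in1, drop = FALSE]
      within <- within + sum(dd[upper.tri(dd)]) / sizes[c1]
    }
  }
  between <- max(tot - within, 0)
  ch <- if (within > 0 && n > k) (between / (k - 1)) / (within / (n - k)) else Inf

  list(silhouette = mean(sil), dunn = dunn, ch = ch)
}

rowsum_by_cluster <- function(d, lab, k) {
  out <- matrix(0, nrow(d), k)
  for (c1 in seq_len(k)) out[, c1] <- rowSums(d[, lab == c1, drop = FALSE])
  out
}

#' Flag degenerate partitions
#'
#' A partition is degenerate when one giant cluster holds all features
#' except singletons (the classic single-linkage failure mode: internally
#' very compact, yet uninformative).
#'
#' @param partition a [cut_partition()] labeling.
#' @return logical.
#' @export
is_degenerate_partition <- function(partition) {
  sizes <- tabulate(as.integer(partition))
  k <- length(sizes)
  k > 1 && max(sizes) == length(partition) - (k - 1)
}

#' Consensus selection of the number of clusters
#'
#' Scans `k_range`, computing each internal index for each k; each index
#' votes the k at which it is maximal, and the consensus k is the modal
#' vote (majority rule), ties broken toward smaller k (parsimony). An
#' early-stop mechanism limits the scan: after each evaluated k the running
#' votes are tallied, and if the majority support (fraction of indices
#' agreeing on the modal running vote) stays below `threshold` for
#' `patience` consecutive values of k, the scan halts.
#'
#' @param d a `feature_dist` or distance matrix.
#' @param linkage linkage rule passed to [hclust_features()].
#' @param k_range integer vector of candidate k (default 2:10, clipped to
#'   `n - 1`).
#' @param indices subset of `c("silhouette", "dunn", "ch")`.
#' @param early_stop list with `threshold` (majority-support fraction,
#'   default 0.5) and `patience` (consecutive low-support k values before
#'   halting, default 3).
#' @return object of class `k_selection`: list with `votes` (per-index
#'   best k), `scores` (index x k matrix), `consensus_k`, `support`,
#'   `stopped_early_at` (NA if the full range was scanned) and the echoed
#'   configuration.
#' @export
select_k_consensus <- function(d, linkage = LINKAGES, k_range = 2:10,
                               indices = c("silhouette", "dunn", "ch"),
                               early_stop = list(threshold = 0.5, patience = 3)) {
  linkage <- match.arg(linkage)
  indices <- match.arg(indices, several.ok = TRUE)
  dm <- if (inherits(d, "feature_dist")) d$d else as.matrix(d)
  n <- nrow(dm)
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) stop("no valid k in range [2, ", n - 1, "]")
  hc <- hclust_features(d, linkage)

  scores <- matrix(NA_real_, length(indices), length(k_range),
                   dimnames = list(indices, k_range))
  low_streak <- 0L
  stopped_at <- NA_integer_
  scanned <- 0L
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    part <- cut_partition(hc, k)
    vals <- internal_indices(part, dm)
    scores[, ki] <- unlist(vals)[indices]
    scanned <- ki
    votes_now <- apply(scores[, seq_len(ki), drop = FALSE], 1, best_k_vote,
                       ks = k_range[seq_len(ki)])
    support_now <- max(tabulate(match(votes_now, unique(votes_now)))) / length(indices)
    if (support_now < early_stop$threshold) {
      low_streak <- low_streak + 1L
      if (low_streak >= early_stop$patience) { stopped_at <- k; break }
    } else low_streak <- 0L
  }
  scores <- scores[, seq_len(scanned), drop = FALSE]
  ks <- k_range[seq_len(scanned)]
  votes <- apply(scores, 1, best_k_vote, ks = ks)
  tab <- table(votes)
  win <- as.integer(names(tab)[tab == max(tab)])
  consensus_k <- min(win)                       # ties -> smaller k
  structure(
    list(votes = votes, scores = scores, consensus_k = consensus_k,
         support = max(tab) / length(votes),
         stopped_early_at = stopped_at,
         scanned_k = ks, linkage = linkage,
         early_stop = early_stop),
    class = "k_selection")
}

best_k_vote <- function(v, ks) {
  v[!is.finite(v)] <- -Inf
  if (all(v == -Inf)) return(NA_integer_)
  ks[which.max(v)]                              # first max -> smaller k on ties
}

#' @export
print.k_selection <- function(x, ...) {
  cat("<k_selection> consensus k =", x$consensus_k,
      sprintf("(support %.2f, linkage %s)\n", x$support, x$linkage))
  cat("  votes:", paste(names(x$votes), x$votes, sep = "=", collapse = ", "), "\n")
  if (!is.na(x$stopped_early_at))
    cat("  early stop at k =", x$stopped_early_at, "\n")
  invisible(x)
}

#' Write a partition and its dendrogram merge table
#'
#' @param partition a [cut_partition()] result.
#' @param hc the tree it came from (optional; adds the merge table).
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return written paths, invisibly.
#' @export
write_partition <- function(partition, hc = NULL, dir, prefix = "clusters") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, paste0(prefix, "_partition.csv"))
  data.table::fwrite(data.frame(feature = names(partition),
                                cluster = as.integer(partition)), p1)
  out <- p1
  if (!is.null(hc)) {
    p2 <- file.path(dir, paste0(prefix, "_merges.csv"))
    data.table::fwrite(data.frame(step = seq_along(hc$height),
                                  left = hc$merge[, 1], right = hc$merge[, 2],
                                  height = hc$height), p2)
    out <- c(out, p2)
  }
  invisible(out)
}
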