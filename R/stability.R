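## Cross-platform partition stability: Adjusted Rand Index over the
## (metric x linkage) grid, with the ARI >= 0.8 stability gate.

#' Adjusted Rand Index between two feature partitions
#'
#' Hubert-Arabie chance-corrected Rand index computed from the contingency
#' table of the two labelings: 1 for identical partitions (up to cluster
#' relabeling), expectation approximately 0 for independent random
#' labelings. Both partitions must label the identical feature set; named
#' labelings are aligned by name.
#'
#' @param p,q partitions: named integer/factor vectors (e.g. from
#'   [cut_partition()]).
#' @return numeric scalar in \[-1, 1\].
#' @export
#' @examples
#' adjusted_rand_index(c(a = 1, b = 1, c = 2), c(a = 2, b = 2, c = 1)) # 1
adjusted_rand_index <- function(p, q) {
  if (!is.null(names(p)) && !is.null(names(q))) {
    if (!setequal(names(p), names(q))) {
      stop("partitions label different feature sets; symmetric difference: ",
           paste(c(setdiff(names(p), names(q)), setdiff(names(q), names(p))),
                 collapse = ", "))
    }
    q <- q[names(p)]
  } else if (length(p) != length(q)) {
    stop("partitions have different lengths (", length(p), " vs ", length(q), ")")
  }
  ct <- table(as.integer(factor(p)), as.integer(factor(q)))
  n <- sum(ct)
  sum_ij <- sum(choose(ct, 2))
  sum_a <- sum(choose(rowSums(ct), 2))
  sum_b <- sum(choose(colSums(ct), 2))
  tot <- choose(n, 2)
  expected <- sum_a * sum_b / tot
  maxidx <- (sum_a + sum_b) / 2
  if (abs(maxidx - expected) < .Machine$double.eps * max(1, tot)) {
    # degenerate margins (e.g. both one cluster, or both all singletons)
    return(if (sum_ij == maxidx) 1 else 0)
  }
  (sum_ij - expected) / (maxidx - expected)
}

#' Evaluate the cross-platform stability grid
#'
#' For each (metric, linkage) configuration, clusters the two platforms'
#' aligned feature tables independently, compares the partitions by ARI and
#' records internal validity on both sides — the fields of the standard
#' stability-versus-quality scatter (ARI against silhouette with the Dunn
#' index as a third channel).
#'
#' The number of clusters per side follows `k_policy`:
#' `"per_platform"` (default) gives each platform its own consensus k (ARI
#' between different-k partitions is well defined); `"common"` forces
#' platform A's consensus k on both sides; `"fixed"` uses `k_fixed`.
#'
#' Per-cell failures (e.g. a metric undefined for some features) are
#' recorded in the `error` column, not fatal.
#'
#' @param pair an [align_platforms()] result (post-ICC feature set).
#' @param metrics subset of the five distance metrics.
#' @param linkages subset of the five linkage rules.
#' @param k_policy `"per_platform"`, `"common"` or `"fixed"`.
#' @param k_fixed integer, used when `k_policy = "fixed"`.
#' @param k_range,early_stop,indices passed to [select_k_consensus()].
#' @param standardize passed to [feature_distance()] (NULL = per-metric
#'   default).
#' @param ari_threshold stability gate on ARI (default 0.8, boundary
#'   inclusive).
#' @return object of class `stability_grid`: data.frame `records` with one
#'   row per configuration (metric, linkage, k_a, k_b, ari, silhouette_a/b,
#'   dunn_a/b, degenerate_a/b, stable, error) plus a `partitions` list (per
#'   configuration, the A and B labelings) for downstream winner selection.
#' @export
evaluate_grid <- function(pair,
                          metrics = DISTANCE_METRICS,
                          linkages = LINKAGES,
                          k_policy = c("per_platform", "common", "fixed"),
                          k_fixed = NULL,
                          k_range = 2:10,
                          early_stop = list(threshold = 0.5, patience = 3),
                          indices = c("silhouette", "dunn", "ch"),
                          standardize = NULL,
                          ari_threshold = 0.8) {
  stopifnot(inherits(pair, "aligned_pair"))
  k_policy <- match.arg(k_policy)
  if (k_policy == "fixed" && is.null(k_fixed)) stop("k_policy = 'fixed' needs k_fixed")
  metrics <- match.arg(metrics, DISTANCE_METRICS, several.ok = TRUE)
  linkages <- match.arg(linkages, LINKAGES, several.ok = TRUE)

  rows <- list()
  partitions <- list()
  for (metric in metrics) {
    cell <- tryCatch({
      da <- feature_distance(pair$table_a, metric, standardize = standardize)
      db <- feature_distance(pair$table_b, metric, standardize = standardize)
      common <- intersect(rownames(da$d), rownames(db$d))
      if (length(common) < 3) stop("fewer than 3 usable features under ", metric)
      da$d <- da$d[common, common]
      db$d <- db$d[common, common]
      list(da = da, db = db)
    }, error = function(e) e)
    for (linkage in linkages) {
      key <- paste(metric, linkage, sep = ":")
      if (inherits(cell, "error")) {
        rows[[key]] <- grid_row(metric, linkage, error = conditionMessage(cell))
        next
      }
      notes <- character()
      rows[[key]] <- tryCatch(withCallingHandlers({
        ksel_a <- select_k_consensus(cell$da, linkage, k_range, indices, early_stop)
        k_a <- switch(k_policy,
                      per_platform = ksel_a$consensus_k,
                      common = ksel_a$consensus_k,
                      fixed = as.integer(k_fixed))
        k_b <- switch(k_policy,
                      per_platform = select_k_consensus(cell$db, linkage, k_range,
                                                        indices, early_stop)$consensus_k,
                      common = k_a,
                      fixed = as.integer(k_fixed))
        hc_a <- hclust_features(cell$da, linkage)
        hc_b <- hclust_features(cell$db, linkage)
        pa <- cut_partition(hc_a, k_a)
        pb <- cut_partition(hc_b, k_b)
        ia <- internal_indices(pa, cell$da$d)
        ib <- internal_indices(pb, cell$db$d)
        partitions[[key]] <- list(a = pa, b = pb)
        grid_row(metric, linkage, k_a = k_a, k_b = k_b,
                 ari = adjusted_rand_index(pa, pb),
                 silhouette_a = ia$silhouette, silhouette_b = ib$silhouette,
                 dunn_a = ia$dunn, dunn_b = ib$dunn,
                 degenerate_a = is_degenerate_partition(pa),
                 degenerate_b = is_degenerate_partition(pb),
                 note = if (length(notes)) paste(unique(notes), collapse = "; ")
                        else NA_character_)
      }, warning = function(w) {
        # compatibility warnings (e.g. ward.D2 on manhattan) become per-cell
        # notes rather than repeated console warnings
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      }), error = function(e) grid_row(metric, linkage,
                                       error = conditionMessage(e)))
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  records$stable <- !is.na(records$ari) & records$ari >= ari_threshold
  structure(list(records = records, partitions = partitions,
                 ari_threshold = ari_threshold, k_policy = k_policy),
            class = "stability_grid")
}

grid_row <- function(metric, linkage, k_a = NA_integer_, k_b = NA_integer_,
                     ari = NA_real_, silhouette_a = NA_real_,
                     silhouette_b = NA_real_, dunn_a = NA_real_,
                     dunn_b = NA_real_, degenerate_a = NA, degenerate_b = NA,
                     note = NA_character_, error = NA_character_) {
  data.frame(metric = metric, linkage = linkage, k_a = k_a, k_b = k_b,
             ari = ari, silhouette_a = silhouette_a, silhouette_b = silhouette_b,
             dunn_a = dunn_a, dunn_b = dunn_b,
             degenerate_a = degenerate_a, degenerate_b = degenerate_b,
             note = note, error = error, stringsAsFactors = FALSE)
}

#' @export
print.stability_grid <- function(x, ...) {
  r <- x$records
  cat("<stability_grid>", nrow(r), "configurations |",
      sum(r$stable), "stable at ARI >=", x$ari_threshold,
      "| k policy:", x$k_policy, "\n")
  print(r[, c("metric", "linkage", "k_a", "k_b", "ari",
              "silhouette_a", "silhouette_b", "stable")], digits = 3)
  invisible(x)
}

#' Select stable configurations
#'
#' Configurations whose ARI reaches the threshold (boundary inclusive),
#' sorted by descending ARI and, among ties, descending platform-A
#' silhouette; the order is fully deterministic (metric, linkage as final
#' keys). An empty result is allowed and flagged with a warning.
#'
#' @param grid an [evaluate_grid()] result (or its `records` data.frame).
#' @param ari_threshold stability gate, default 0.8.
#' @return data.frame of stable configuration rows.
#' @export
select_stable_configs <- function(grid, ari_threshold = 0.8) {
  records <- if (inherits(grid, "stability_grid")) grid$records else grid
  ok <- records[!is.na(records$ari) & records$ari >= ari_threshold, , drop = FALSE]
  if (!nrow(ok)) {
    warning("no configuration reaches ARI >= ", ari_threshold)
    return(ok)
  }
  ok[order(-ok$ari, -ok$silhouette_a, ok$metric, ok$linkage), , drop = FALSE]
}

#' Stability-versus-quality scatter
#'
#' ARI (y) against silhouette (x), Dunn index as color and linkage as
#' shape, one panel per platform side for the silhouette/Dunn values.
#'
#' @param grid an [evaluate_grid()] result.
#' @param side `"a"` or `"b"`: which platform's internal indices to plot.
#' @return a ggplot object.
#' @export
plot_stability_grid <- function(grid, side = c("a", "b")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_stability_grid needs the ggplot2 package")
  }
  side <- match.arg(side)
  r <- grid$records
  r <- r[!is.na(r$ari), , drop = FALSE]
  r$silhouette <- r[[paste0("silhouette_", side)]]
  r$dunn <- pmin(r[[paste0("dunn_", side)]], 10) # cap Inf/huge for the color scale
  ggplot2::ggplot(r, ggplot2::aes(x = .data$silhouette, y = .data$ari,
                                  color = .data$dunn, shape = .data$linkage)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_hline(yintercept = grid$ari_threshold, linetype = "dashed") +
    ggplot2::labs(x = "Silhouette score", y = "Adjusted Rand Index (ARI)",
                  color = "Dunn index", shape = "Linkage",
                  title = sprintf("Clustering stability vs internal quality (platform %s)",
                                  toupper(side))) +
    ggplot2::theme_minimal()
}
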