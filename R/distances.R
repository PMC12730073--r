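## Feature-feature dissimilarity matrices.
##
## Five metrics operate on the columns (features) of a lesions-by-features
## matrix: correlation-derived distances sqrt(2(1 - r)) for Pearson and
## Spearman, and the Euclidean, Manhattan and cosine geometric distances
## between feature vectors across lesions.

DISTANCE_METRICS <- c("pearson", "spearman", "euclidean", "manhattan", "cosine")

#' Feature-feature distance matrix
#'
#' Dispatcher over the five supported metrics. Correlation metrics use
#' `d[j,k] = sqrt(2 (1 - r[j,k]))` which embeds the correlation structure
#' as an equivalent Euclidean distance (d = 0 at r = 1, sqrt(2) at r = 0,
#' 2 at r = -1). Geometric metrics compare feature columns over lesions;
#' because raw radiomic features span orders of magnitude they are z-scored
#' across lesions first by default (`standardize = TRUE`), a recorded
#' configuration field since it changes the resulting partitions.
#'
#' Features for which a metric is undefined (constant columns under
#' correlation or standardization; all-zero columns under cosine) are
#' excluded from the matrix and listed in `$excluded`, not imputed.
#'
#' @param X lesions-by-features numeric matrix or [feature_table()].
#' @param metric one of `"pearson"`, `"spearman"`, `"euclidean"`,
#'   `"manhattan"`, `"cosine"`.
#' @param standardize z-score feature columns across lesions before the
#'   geometric metrics; default TRUE for euclidean/manhattan/cosine and
#'   (vacuously) FALSE for the correlation metrics.
#' @return object of class `feature_dist`: list with `metric`,
#'   `standardize`, `d` (symmetric matrix with zero diagonal, dimnames =
#'   feature names) and `excluded` (named character vector of reasons).
#' @export
#' @examples
#' X <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
#' feature_distance(X, "pearson")$d
feature_distance <- function(X, metric = DISTANCE_METRICS, standardize = NULL) {
  metric <- match.arg(metric)
  if (inherits(X, "feature_table")) X <- X$values
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  geo <- metric %in% c("euclidean", "manhattan", "cosine")
  if (is.null(standardize)) standardize <- geo
  if (metric %in% c("pearson", "spearman")) {
    if (nrow(X) < 3) stop("correlation distances need >= 3 lesions")
    correlation_distance(X, rank = metric == "spearman")
  } else {
    if (nrow(X) < 2) stop("geometric distances need >= 2 lesions")
    geometric_distance(X, metric, standardize = standardize)
  }
}

#' Correlation-derived distance
#'
#' `d[j,k] = sqrt(2 (1 - r[j,k]))` with r the Pearson (or, for
#' `rank = TRUE`, Spearman with average ranks) correlation between feature
#' columns. Constant features have undefined correlation and are excluded
#' with a report entry.
#'
#' @param X lesions-by-features matrix.
#' @param rank use Spearman rank correlation instead of Pearson.
#' @return `feature_dist` object.
#' @export
correlation_distance <- function(X, rank = FALSE) {
  X <- as.matrix(X)
  const <- apply(X, 2, function(v) stats::sd(v) == 0)
  excluded <- stats::setNames(rep("constant feature (correlation undefined)",
                                  sum(const)), colnames(X)[const])
  Xo <- X[, !const, drop = FALSE]
  if (ncol(Xo) < 2) stop("fewer than 2 non-constant features")
  r <- stats::cor(Xo, method = if (rank) "spearman" else "pearson")
  r[r > 1] <- 1
  r[r < -1] <- -1
  d <- sqrt(2 * (1 - r))
  diag(d) <- 0
  d <- (d + t(d)) / 2
  new_feature_dist(if (rank) "spearman" else "pearson", d,
                   standardize = FALSE, excluded = excluded)
}

#' Geometric distance between feature vectors
#'
#' Euclidean: `sqrt(sum_i (x_ij - x_ik)^2)`; Manhattan:
#' `sum_i |x_ij - x_ik|`; cosine: one minus the cosine similarity of the
#' two columns, in \[0, 2\] (0 proportional, 1 orthogonal, 2 antiparallel).
#' Sums run over lesions i = 1..N.
#'
#' @param X lesions-by-features matrix.
#' @param metric `"euclidean"`, `"manhattan"` or `"cosine"`.
#' @param standardize z-score columns across lesions first.
#' @return `feature_dist` object.
#' @export
geometric_distance <- function(X, metric = c("euclidean", "manhattan", "cosine"),
                               standardize = TRUE) {
  metric <- match.arg(metric)
  X <- as.matrix(X)
  excluded <- character(0)
  if (standardize) {
    const <- apply(X, 2, function(v) stats::sd(v) == 0)
    excluded <- c(excluded, stats::setNames(
      rep("constant feature (standardization undefined)", sum(const)),
      colnames(X)[const]))
    X <- X[, !const, drop = FALSE]
    X <- scale(X)
    attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
  }
  if (metric == "cosine") {
    nrm <- sqrt(colSums(X^2))
    zero <- nrm == 0
    excluded <- c(excluded, stats::setNames(
      rep("all-zero vector (cosine undefined)", sum(zero)), colnames(X)[zero]))
    X <- X[, !zero, drop = FALSE]
    nrm <- nrm[!zero]
    if (ncol(X) < 2) stop("fewer than 2 usable features")
    s <- crossprod(sweep(X, 2, nrm, "/"))
    s[s > 1] <- 1
    s[s < -1] <- -1
    d <- 1 - s
  } else {
    if (ncol(X) < 2) stop("fewer than 2 usable features")
    d <- as.matrix(stats::dist(t(X), method = metric))
  }
  diag(d) <- 0
  d <- (d + t(d)) / 2
  new_feature_dist(metric, d, standardize = standardize,
                   excluded = stats::setNames(as.character(excluded), names(excluded)))
}

new_feature_dist <- function(metric, d, standardize, excluded = character()) {
  structure(list(metric = metric, standardize = standardize,
                 d = d, excluded = excluded),
            class = "feature_dist")
}

#' @export
print.feature_dist <- function(x, ...) {
  cat("<feature_dist>", x$metric,
      if (x$standardize) "(standardized)" else "(raw)",
      "|", nrow(x$d), "features")
  if (length(x$excluded)) cat(" |", length(x$excluded), "excluded")
  cat("\n")
  invisible(x)
}

#' Write a distance matrix with a sidecar metadata file
#'
#' @param fd a `feature_dist`.
#' @param path CSV path for the square matrix; the metric, standardization
#'   flag and exclusions go to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_feature_dist <- function(fd, path) {
  df <- data.frame(feature = rownames(fd$d), fd$d,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path)
  jsonlite::write_json(
    list(metric = fd$metric, standardize = fd$standardize,
         excluded = as.list(fd$excluded)),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
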