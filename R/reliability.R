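## Intra-software repeatability: ICC(A,1) on repeated segmentations.

#' ICC(A,1): two-way model, single measurement, absolute agreement
#'
#' Quantifies repeatability of one feature measured on `n` subjects
#' (lesions) in `k` repeated segmentations. From the two-way ANOVA
#' decomposition with subjects as random rows and repetitions as columns,
#'
#' \deqn{ICC(A,1) = \frac{MSR - MSE}{MSR + (k-1)\,MSE + k\,(MSC - MSE)/n}}
#'
#' where MSR is the mean square between subjects, MSC the mean square
#' between measurements and MSE the residual mean square. Absolute
#' agreement charges systematic differences between repetitions (MSC) as
#' disagreement.
#'
#' @param measurements numeric matrix, subjects in rows, repetitions in
#'   columns; must be complete.
#' @return list of class `icc_result` with `icc` (NA with
#'   `undefined = TRUE` when the matrix has zero total variance), `MSR`,
#'   `MSC`, `MSE`, `n`, `k`.
#' @export
#' @examples
#' m <- cbind(c(1, 5, 9), c(1.1, 5.2, 8.9), c(0.9, 4.8, 9.2))
#' compute_icc_a1(m)$icc
compute_icc_a1 <- function(measurements) {
  m <- as.matrix(measurements)
  storage.mode(m) <- "double"
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2) stop("need at least 2 subjects, got ", n)
  if (k < 2) stop("need at least 2 repetitions, got ", k)
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("incomplete measurement matrix: subject ", bad[1, 1],
         ", repetition ", bad[1, 2], " is missing/non-finite")
  }
  grand <- mean(m)
  rowm <- rowMeans(m)
  colm <- colMeans(m)
  sst <- sum((m - grand)^2)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  mse <- max(mse, 0) # guard tiny negative round-off
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  scale2 <- max(mean(m^2), 1)
  undefined <- sst <= 1e-12 * scale2 * n * k || abs(denom) <= 1e-14 * scale2
  icc <- if (undefined) NA_real_ else (msr - mse) / denom
  structure(list(icc = icc, MSR = msr, MSC = msc, MSE = mse,
                 n = n, k = k, undefined = undefined),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat("ICC(A,1) =", if (x$undefined) "undefined (zero variance)"
      else format(x$icc, digits = 4),
      sprintf("[n = %d subjects, k = %d repetitions]\n", x$n, x$k))
  invisible(x)
}

#' Classify an ICC value into conventional reliability bands
#'
#' Intervals are closed on the left so the bands align with the `>= 0.75`
#' retention rule: poor below 0.50, moderate in \[0.50, 0.75), good in
#' \[0.75, 0.90), excellent at 0.90 and above. Undefined ICC (zero-variance
#' feature) maps to `"undefined"`.
#'
#' @param icc numeric vector of ICC values (NA allowed).
#' @return character vector of categories.
#' @export
classify_reliability <- function(icc) {
  out <- rep("undefined", length(icc))
  ok <- !is.na(icc)
  out[ok & icc < 0.50] <- "poor"
  out[ok & icc >= 0.50 & icc < 0.75] <- "moderate"
  out[ok & icc >= 0.75 & icc < 0.90] <- "good"
  out[ok & icc >= 0.90] <- "excellent"
  out
}

#' Per-feature ICC screen over a repeated-measures stack
#'
#' @param rm repeated measures: a 3-d array (subjects x repetitions x
#'   features, dimnames used for feature names) or a named list of
#'   subjects-by-repetitions matrices.
#' @param threshold retention threshold on ICC(A,1); the conventional gate
#'   is 0.75 (boundary inclusive).
#' @return data.frame of class `icc_screen`: `feature`, `icc`, `category`,
#'   `retained`. Undefined ICCs are never retained (a constant feature
#'   carries no information).
#' @export
icc_screen <- function(rm, threshold = 0.75) {
  mats <- repeated_measures_list(rm)
  res <- lapply(mats, compute_icc_a1)
  icc <- vapply(res, `[[`, 0, "icc")
  out <- data.frame(
    feature = names(mats),
    icc = unname(icc),
    category = classify_reliability(icc),
    retained = !is.na(icc) & icc >= threshold,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "threshold") <- threshold
  class(out) <- c("icc_screen", "data.frame")
  out
}

repeated_measures_list <- function(rm) {
  if (is.array(rm) && length(dim(rm)) == 3) {
    fn <- dimnames(rm)[[3]]
    if (is.null(fn)) fn <- paste0("f", seq_len(dim(rm)[3]))
    mats <- lapply(seq_len(dim(rm)[3]), function(j) rm[, , j])
    names(mats) <- fn
    mats
  } else if (is.list(rm)) {
    if (is.null(names(rm))) names(rm) <- paste0("f", seq_along(rm))
    rm
  } else if (is.matrix(rm)) {
    list(f1 = rm)
  } else {
    stop("rm must be a 3-d array, a list of matrices, or a matrix")
  }
}

#' Retained feature set from an ICC screen
#'
#' @param results an [icc_screen()] data.frame (one platform).
#' @param threshold optional re-threshold; defaults to the screen's own.
#' @param allow_empty if FALSE (default), an empty retained set is an error
#'   directing the user to the override; if TRUE it is returned with a
#'   warning and the pipeline may proceed with all features.
#' @return character vector of retained feature names.
#' @export
filter_robust <- function(results, threshold = NULL, allow_empty = FALSE) {
  stopifnot(is.data.frame(results), all(c("feature", "icc") %in% names(results)))
  if (is.null(threshold)) threshold <- attr(results, "threshold") %||% 0.75
  keep <- results$feature[!is.na(results$icc) & results$icc >= threshold]
  if (!length(keep)) {
    msg <- sprintf("no feature reaches ICC(A,1) >= %.3g", threshold)
    if (!allow_empty) stop(msg, " (set allow_empty = TRUE to proceed regardless)")
    warning(msg, "; proceeding with an empty retained set")
  }
  keep
}

#' Combine per-platform retained sets
#'
#' The cross-platform stage consumes, by default, the intersection of the
#' two platforms' retained sets; union and single-platform modes are
#' offered because the gating policy is a study design choice.
#'
#' @param retained_a,retained_b character vectors of retained features
#'   (harmonized names).
#' @param mode one of "intersection" (default), "union", "a_only", "b_only".
#' @return character vector.
#' @export
combine_retained <- function(retained_a, retained_b,
                             mode = c("intersection", "union", "a_only", "b_only")) {
  mode <- match.arg(mode)
  switch(mode,
         intersection = intersect(retained_a, retained_b),
         union = union(retained_a, retained_b),
         a_only = retained_a,
         b_only = retained_b)
}

#' Read a long-format repeated-measures table
#'
#' Expected columns: a subject id (`lesion_id`), a repetition label
#' (`repetition`), then one numeric column per feature. Each feature is
#' reshaped into a complete subjects-by-repetitions matrix.
#'
#' @param x path to a delimited file, or a data.frame already in memory.
#' @param id_col,rep_col column names for subject and repetition.
#' @return named list of subjects-by-repetitions matrices.
#' @export
read_repeated_long <- function(x, id_col = "lesion_id", rep_col = "repetition") {
  df <- if (is.character(x)) data.table::fread(x, data.table = FALSE) else as.data.frame(x)
  for (cn in c(id_col, rep_col)) {
    if (!cn %in% names(df)) stop("missing column '", cn, "'")
  }
  ids <- sort(unique(as.character(df[[id_col]])))
  reps <- sort(unique(as.character(df[[rep_col]])))
  feats <- setdiff(names(df), c(id_col, rep_col))
  if (!length(feats)) stop("no feature columns")
  ri <- match(as.character(df[[id_col]]), ids)
  ci <- match(as.character(df[[rep_col]]), reps)
  lapply(stats::setNames(feats, feats), function(f) {
    m <- matrix(NA_real_, length(ids), length(reps), dimnames = list(ids, reps))
    m[cbind(ri, ci)] <- as.numeric(df[[f]])
    m
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
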