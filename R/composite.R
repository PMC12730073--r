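## Composite Index: per-feature cross-platform robustness score and the
## winner / near-winner / QC selection stages.

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Sup-norm distance between the empirical CDFs of the two samples,
#' evaluated over the pooled support: 0 for identical samples, 1 for
#' disjoint supports.
#'
#' @param a,b numeric vectors (length >= 1; the Composite Index requires
#'   >= 2 per sample).
#' @return numeric scalar in \[0, 1\].
#' @export
#' @examples
#' ks_statistic(1:4, 2:5)
ks_statistic <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty vector")
  x <- sort(unique(c(a, b)))
  fa <- vapply(x, function(t) mean(a <= t), 0)
  fb <- vapply(x, function(t) mean(b <= t), 0)
  max(abs(fa - fb))
}

#' Mean fractional ratio: stabilized log-ratio of means
#'
#' `MFR = |log((|mean(a)| + eps) / (|mean(b)| + eps))|`; 0 indicates no
#' scale bias between platforms, and `eps` keeps the ratio defined when a
#' mean is near zero. The signed value (direction of the bias) is available
#' via `signed = TRUE`.
#'
#' @param a,b numeric vectors.
#' @param epsilon stabilizer added to both absolute means (default 1e-6).
#' @param signed return the signed log-ratio instead of its magnitude.
#' @return numeric scalar (>= 0 unless `signed`).
#' @export
mean_fractional_ratio <- function(a, b, epsilon = 1e-6, signed = FALSE) {
  if (!length(a) || !length(b)) stop("empty vector")
  v <- log((abs(mean(a)) + epsilon) / (abs(mean(b)) + epsilon))
  if (signed) v else abs(v)
}

#' Robust z-score
#'
#' `z_i = (x_i - median(x)) / (1.4826 * MAD)`. When the MAD is zero the
#' scale falls back to the normalized IQR (`IQR / 1.349`), and when that is
#' also zero every z is 0 (a constant vector carries no ranking
#' information).
#'
#' @param values numeric vector, length >= 2.
#' @return numeric vector of the same length.
#' @export
robust_z <- function(values) {
  if (length(values) < 2) stop("robust_z needs length >= 2")
  med <- stats::median(values)
  s <- stats::mad(values, center = med)        # 1.4826 * median |x - med|
  if (s <= 0) s <- stats::IQR(values) / 1.349
  if (s <= 0) return(rep(0, length(values)))
  (values - med) / s
}

#' Composite Index of cross-platform feature robustness
#'
#' For each feature f measured on the same lesions by two platforms:
#' * `r_f` — Pearson (optionally Spearman) correlation between the two
#'   platforms' values across lesions (shape consistency);
#' * `D_f` — two-sample KS statistic between the two value distributions
#'   (distributional similarity);
#' * `MFR_f` — stabilized absolute log-ratio of mean values (scale bias).
#'
#' Each of the three statistics is standardized by a robust z-score across
#' the feature population entering this stage, and
#' `CI_f = z_corr,f - z_KS,f - z_MFR,f`, so high correlation, low
#' distributional divergence and low scale bias give a high CI.
#'
#' When all three statistic vectors are constant across features (e.g. the
#' two tables are identical copies) every CI is 0; the result is flagged
#' `degenerate`.
#'
#' @param pair an [align_platforms()] result.
#' @param features optional subset of features to score (default: all
#'   common features; at least 3 required, since the z-scores need a
#'   population).
#' @param epsilon stabilizer for [mean_fractional_ratio()].
#' @param method correlation type for `r_f`: `"pearson"` (default) or
#'   `"spearman"`.
#' @return data.frame of class `robustness_records`: feature, r, ks, mfr,
#'   mfr_signed, z_corr, z_ks, z_mfr, ci; `attr(, "degenerate")` flags the
#'   all-constant case.
#' @export
composite_index <- function(pair, features = NULL, epsilon = 1e-6,
                            method = c("pearson", "spearman")) {
  stopifnot(inherits(pair, "aligned_pair"))
  method <- match.arg(method)
  feats <- features %||% pair$common_features
  missing <- setdiff(feats, pair$common_features)
  if (length(missing)) stop("features not in the aligned pair: ",
                            paste(missing, collapse = ", "))
  if (length(feats) < 3) stop("composite_index needs >= 3 features")
  A <- pair$table_a$values[, feats, drop = FALSE]
  B <- pair$table_b$values[, feats, drop = FALSE]

  r <- vapply(feats, function(f) {
    if (stats::sd(A[, f]) == 0 || stats::sd(B[, f]) == 0) return(NA_real_)
    stats::cor(A[, f], B[, f], method = method)
  }, 0)
  ks <- vapply(feats, function(f) ks_statistic(A[, f], B[, f]), 0)
  mfr_s <- vapply(feats, function(f)
    mean_fractional_ratio(A[, f], B[, f], epsilon, signed = TRUE), 0)
  mfr <- abs(mfr_s)

  r_z <- ifelse(is.na(r), -1, r)     # undefined correlation ranks worst
  z_corr <- robust_z(r_z)
  z_ks <- robust_z(ks)
  z_mfr <- robust_z(mfr)
  ci <- z_corr - z_ks - z_mfr

  out <- data.frame(feature = feats, r = unname(r), ks = unname(ks),
                    mfr = unname(mfr), mfr_signed = unname(mfr_s),
                    z_corr = unname(z_corr), z_ks = unname(z_ks),
                    z_mfr = unname(z_mfr), ci = unname(ci),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "degenerate") <- all(ci == 0)
  attr(out, "epsilon") <- epsilon
  attr(out, "method") <- method
  class(out) <- c("robustness_records", "data.frame")
  out
}

#' Per-cluster winner and near-winner selection
#'
#' Within each cluster of `partition`, the feature with the maximal CI is
#' the winner (exact ties are broken toward the lexicographically smallest
#' feature name, with all tied features reported as co-winners);
#' near-winners trail the winner's CI by at most `delta`. An optional
#' absolute floor drops clusters whose best CI falls below `ci_floor`
#' (reported in `skipped_clusters`), as are clusters containing no scored
#' feature.
#'
#' @param partition a [cut_partition()] labeling of the scored features.
#' @param records a [composite_index()] data.frame.
#' @param delta near-winner tolerance in robust-z units (default 0.5).
#' @param ci_floor optional absolute CI threshold for winners (default
#'   `-Inf`: pure argmax rule).
#' @return object of class `selection_result`: data.frame `selected`
#'   (feature, cluster, ci, role in winner/co_winner/near_winner) plus
#'   `skipped_clusters`, and the echoed parameters.
#' @export
select_winners <- function(partition, records, delta = 0.5, ci_floor = -Inf) {
  stopifnot(inherits(records, "data.frame"),
            all(c("feature", "ci") %in% names(records)))
  lab <- as.integer(partition)
  feats <- names(partition)
  if (is.null(feats)) stop("partition must be named by feature")
  rows <- list()
  skipped <- data.frame(cluster = integer(), reason = character(),
                        stringsAsFactors = FALSE)
  for (cl in sort(unique(lab))) {
    members <- feats[lab == cl]
    rec <- records[records$feature %in% members, , drop = FALSE]
    if (!nrow(rec)) {
      skipped <- rbind(skipped, data.frame(cluster = cl, reason = "no scored feature"))
      next
    }
    rec <- rec[order(-rec$ci, rec$feature), , drop = FALSE]
    best <- rec$ci[1]
    if (best < ci_floor) {
      skipped <- rbind(skipped, data.frame(cluster = cl,
                                           reason = sprintf("best CI %.3g < floor %.3g",
                                                            best, ci_floor)))
      next
    }
    role <- ifelse(rec$ci == best, "co_winner", "near_winner")
    role[1] <- "winner"
    keep <- rec$ci >= best - delta
    rows[[as.character(cl)]] <- data.frame(
      feature = rec$feature[keep], cluster = cl, ci = rec$ci[keep],
      role = role[keep], stringsAsFactors = FALSE)
  }
  selected <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature = character(), cluster = integer(), ci = numeric(),
               role = character(), stringsAsFactors = FALSE)
  rownames(selected) <- NULL
  structure(list(selected = selected, skipped_clusters = skipped,
                 delta = delta, ci_floor = ci_floor,
                 k = length(unique(lab))),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>", sum(x$selected$role == "winner"), "winner(s),",
      sum(x$selected$role == "co_winner"), "co-winner(s),",
      sum(x$selected$role == "near_winner"), "near-winner(s)",
      sprintf("across %d clusters (delta = %g)\n", x$k, x$delta))
  if (nrow(x$skipped_clusters)) {
    cat("  skipped clusters:", nrow(x$skipped_clusters), "\n")
  }
  invisible(x)
}

#' Winners of a selection
#'
#' @param selection a [select_winners()] result.
#' @param include_co_winners include exact-tie co-winners (default TRUE).
#' @return character vector of feature names.
#' @export
winners <- function(selection, include_co_winners = TRUE) {
  roles <- if (include_co_winners) c("winner", "co_winner") else "winner"
  selection$selected$feature[selection$selected$role %in% roles]
}

#' Quality-control filter on the selected features
#'
#' Two filters applied to the winner + near-winner pool: (i) features whose
#' inter-platform correlation `r_f` falls below `min_corr` are dropped;
#' (ii) a greedy intra-cluster redundancy filter scans the survivors in
#' descending CI order and drops any feature whose absolute within-cluster
#' correlation with an already-kept feature exceeds `redundancy_cutoff`.
#'
#' @param selection a [select_winners()] result.
#' @param records the [composite_index()] records.
#' @param feature_cor feature-by-feature correlation matrix used for the
#'   redundancy filter (see [feature_cor_matrix()]).
#' @param min_corr minimum acceptable inter-platform Pearson correlation
#'   (default 0.6).
#' @param redundancy_cutoff maximum allowed absolute within-cluster
#'   correlation among kept features (default 0.9).
#' @return list with `final_set` (character vector) and `dropped`
#'   (data.frame feature/cluster/reason).
#' @export
qc_filter <- function(selection, records, feature_cor,
                      min_corr = 0.6, redundancy_cutoff = 0.9) {
  sel <- selection$selected
  sel <- sel[order(-sel$ci, sel$feature), , drop = FALSE]
  rmap <- stats::setNames(records$r, records$feature)
  kept <- character()
  kept_cluster <- integer()
  dropped <- data.frame(feature = character(), cluster = integer(),
                        reason = character(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(sel))) {
    f <- sel$feature[i]
    cl <- sel$cluster[i]
    rf <- rmap[[f]]
    if (is.na(rf) || rf < min_corr) {
      dropped <- rbind(dropped, data.frame(
        feature = f, cluster = cl,
        reason = sprintf("inter-platform r = %.3g < %.3g", rf, min_corr)))
      next
    }
    mates <- kept[kept_cluster == cl]
    if (length(mates) && f %in% rownames(feature_cor)) {
      cc <- abs(feature_cor[f, mates])
      if (any(cc > redundancy_cutoff, na.rm = TRUE)) {
        dropped <- rbind(dropped, data.frame(
          feature = f, cluster = cl,
          reason = sprintf("redundant with %s (|r| = %.3g > %.3g)",
                           mates[which.max(cc)], max(cc), redundancy_cutoff)))
        next
      }
    }
    kept <- c(kept, f)
    kept_cluster <- c(kept_cluster, cl)
  }
  list(final_set = kept, dropped = dropped)
}

#' Within-platform feature correlation matrix
#'
#' Helper for [qc_filter()]: absolute-value-ready Pearson correlations
#' between feature columns, computed on platform A of an aligned pair (the
#' two platforms are near-interchangeable once the ARI gate has passed).
#'
#' @param pair an [align_platforms()] result.
#' @param method correlation method (default `"pearson"`).
#' @return square correlation matrix.
#' @export
feature_cor_matrix <- function(pair, method = "pearson") {
  stats::cor(pair$table_a$values, method = method)
}

#' Aggregate winner frequencies across stable solutions
#'
#' Counts, per feature, (i) the number of solutions in which it is a winner
#' (co-winners included) and (ii) the number in which it is a winner or a
#' near-winner, sorted by descending winner count then winner-or-near
#' count then name.
#'
#' @param solutions list of [select_winners()] results (one per stable
#'   clustering solution).
#' @return data.frame: feature, n_winner, n_winner_or_near.
#' @export
aggregate_winner_frequencies <- function(solutions) {
  if (!length(solutions)) stop("need at least one solution")
  wtab <- table(unlist(lapply(solutions, winners)))
  atab <- table(unlist(lapply(solutions, function(s) unique(s$selected$feature))))
  feats <- sort(unique(c(names(wtab), names(atab))))
  out <- data.frame(
    feature = feats,
    n_winner = as.integer(wtab[feats]),
    n_winner_or_near = as.integer(atab[feats]),
    stringsAsFactors = FALSE)
  out$n_winner[is.na(out$n_winner)] <- 0L
  out$n_winner_or_near[is.na(out$n_winner_or_near)] <- 0L
  out[order(-out$n_winner, -out$n_winner_or_near, out$feature), , drop = FALSE]
}
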