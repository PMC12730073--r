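## Synthetic paired platform tables and repeated-segmentation stacks with
## known ground truth. Features live in correlated blocks driven by latent
## factors; platform B re-measures platform A with per-feature scale bias,
## noise, and (for non-robust features) targeted corruptions, each of which
## degrades exactly one Composite Index component.

#' Simulation configuration
#'
#' Defaults state the validation world used throughout the package's tests:
#' 100 lesions, 60 features in 6 equally sized blocks sharing a latent
#' factor at within-block correlation 0.8, one planted robust feature per
#' block, competitor features biased by a scale factor from \[0.5, 2\] and
#' all corrupted, relative measurement noise 5%, and repeated-segmentation
#' stacks of 60 subjects x 3 repetitions at a true ICC of 0.95 for robust
#' and 0.85 for other features.
#'
#' @param n_lesions,n_features,n_blocks dimensions of the tables.
#' @param within_block_corr latent-factor loading: expected Pearson
#'   correlation between two features of the same block, in (0, 1).
#' @param robust_per_block planted high-fidelity features per block.
#' @param scale_bias_range range of the uniform per-feature scale factor
#'   applied to non-robust features on platform B.
#' @param corruption_fraction fraction of non-robust features receiving a
#'   monotone-nonlinear or noise corruption on platform B (never applied to
#'   planted robust features).
#' @param noise_sd platform-B measurement noise, as a fraction of each
#'   feature's scale.
#' @param robust_jitter half-width of the scale factor U(1 - j, 1 + j) for
#'   robust features (0 gives exact copies when noise_sd is also 0).
#' @param icc_true per-feature true ICC in (0, 1) for the repeated-measures
#'   stack: scalar, length-2 vector (robust, non-robust) or length
#'   `n_features`.
#' @param n_subjects,k_reps repeated-measures stack dimensions.
#' @param seed integer random seed; the full output is a deterministic
#'   function of the configuration.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_lesions = 100, n_features = 60, n_blocks = 6,
                       within_block_corr = 0.8, robust_per_block = 1,
                       scale_bias_range = c(0.5, 2), corruption_fraction = 1,
                       noise_sd = 0.05, robust_jitter = 0.02,
                       icc_true = c(0.95, 0.85),
                       n_subjects = 60, k_reps = 3, seed = 1L) {
  cfg <- list(n_lesions = n_lesions, n_features = n_features,
              n_blocks = n_blocks, within_block_corr = within_block_corr,
              robust_per_block = robust_per_block,
              scale_bias_range = scale_bias_range,
              corruption_fraction = corruption_fraction,
              noise_sd = noise_sd, robust_jitter = robust_jitter,
              icc_true = icc_true, n_subjects = n_subjects,
              k_reps = k_reps, seed = as.integer(seed))
  stopifnot(n_lesions >= 3, n_features >= 2, n_blocks >= 1,
            within_block_corr > 0, within_block_corr < 1,
            robust_per_block * n_blocks <= n_features,
            corruption_fraction >= 0, corruption_fraction <= 1,
            noise_sd >= 0, robust_jitter >= 0,
            all(icc_true > 0), all(icc_true < 1),
            n_subjects >= 2, k_reps >= 2)
  structure(cfg, class = "sim_config")
}

CORRUPTION_MENU <- c("cube", "squash", "heavy_noise", "mega_scale")

sim_feature_names <- function(cfg) {
  # realistic extractor-style names: <filter>_<family>_<name>
  filters <- c("original", paste0("wavelet_", WAVELET_SUBBANDS))
  families <- c("firstorder", "glcm", "glrlm", "glszm", "gldm", "ngtdm")
  sprintf("%s_%s_sim%03d",
          filters[(seq_len(cfg$n_features) - 1L) %% length(filters) + 1L],
          families[(seq_len(cfg$n_features) - 1L) %% length(families) + 1L],
          seq_len(cfg$n_features))
}

#' Generate a paired pair of platform feature tables with ground truth
#'
#' Platform A is drawn from a latent-factor block model: feature f in block
#' b is `sqrt(w) z_b + sqrt(1 - w) eps_f` (so two features of a block
#' correlate at `w = within_block_corr`), then shifted/scaled per feature
#' over several orders of magnitude to emulate heterogeneous radiomic
#' scales. Platform B re-measures A: planted robust features get a scale
#' factor within `1 +/- robust_jitter` plus `noise_sd`-relative noise;
#' non-robust features get a scale bias drawn from `scale_bias_range` and,
#' for a `corruption_fraction` of them, one corruption cycled from the menu
#' (`cube` — monotone nonlinearity distorting shape and distribution;
#' `squash` — rank-preserving saturation; `heavy_noise` — correlation
#' destroyed; `mega_scale` — 10x scale bias).
#'
#' @param cfg a [sim_config()].
#' @return list with `table_a`, `table_b` ([feature_table()]s over the same
#'   lesions and features) and `truth` (data.frame: feature, block, robust,
#'   scale_bias, corruption).
#' @export
simulate_platform_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_lesions
  p <- cfg$n_features
  w <- cfg$within_block_corr

  block_of <- rep(seq_len(cfg$n_blocks), length.out = p)
  block_of <- sort(block_of)
  robust <- logical(p)
  for (b in seq_len(cfg$n_blocks)) {
    robust[which(block_of == b)[seq_len(cfg$robust_per_block)]] <- TRUE
  }
  feats <- sim_feature_names(cfg)
  lesions <- sprintf("lesion%03d", seq_len(n))

  Z <- matrix(stats::rnorm(n * cfg$n_blocks), n, cfg$n_blocks)
  E <- matrix(stats::rnorm(n * p), n, p)
  core <- sqrt(w) * Z[, block_of, drop = FALSE] + sqrt(1 - w) * E

  sigma <- 10^stats::runif(p, -1, 2)        # heterogeneous feature scales
  mu <- stats::rnorm(p, 0, 2) * sigma
  A <- sweep(sweep(core, 2, sigma, "*"), 2, mu, "+")

  scale_bias <- ifelse(robust,
                       stats::runif(p, 1 - cfg$robust_jitter, 1 + cfg$robust_jitter),
                       stats::runif(p, cfg$scale_bias_range[1], cfg$scale_bias_range[2]))
  corruption <- rep("none", p)
  nonrob <- which(!robust)
  n_corrupt <- round(cfg$corruption_fraction * length(nonrob))
  if (n_corrupt > 0) {
    victims <- sample(nonrob, n_corrupt)
    corruption[victims] <- CORRUPTION_MENU[(seq_len(n_corrupt) - 1L) %%
                                             length(CORRUPTION_MENU) + 1L]
  }

  B <- matrix(0, n, p)
  for (f in seq_len(p)) {
    x <- A[, f]
    y <- scale_bias[f] * x
    cs <- (x - mu[f]) / sigma[f]            # latent-scale copy for shape edits
    y <- switch(corruption[f],
      none = y,
      cube = mu[f] + sigma[f] * cs^3,       # monotone, shape-distorting
      squash = mu[f] + sigma[f] * tanh(cs),
      heavy_noise = y + 1.5 * sigma[f] * stats::rnorm(n),
      mega_scale = 10 * x
    )
    if (cfg$noise_sd > 0) y <- y + cfg$noise_sd * sigma[f] * stats::rnorm(n)
    B[, f] <- y
  }

  dimnames(A) <- dimnames(B) <- list(lesions, feats)
  truth <- data.frame(feature = feats, block = block_of, robust = robust,
                      scale_bias = scale_bias, corruption = corruption,
                      stringsAsFactors = FALSE)
  list(table_a = feature_table(A, platform_id = "platform_a"),
       table_b = feature_table(B, platform_id = "platform_b"),
       truth = truth)
}

#' Generate repeated-segmentation measurements with controlled reliability
#'
#' Per feature, measurement j of subject i is
#' `subject_i + e_ij` with `Var(subject) = icc` and `Var(e) = 1 - icc`, so
#' the population ICC(A,1) equals `icc_true` (no systematic repetition
#' effect). Values are then shifted/scaled per feature like the platform
#' tables.
#'
#' @param cfg a [sim_config()]; `icc_true` may be a scalar, a (robust,
#'   non-robust) pair, or one value per feature.
#' @param truth optional ground-truth data.frame from
#'   [simulate_platform_pair()] (used to map the (robust, non-robust) pair
#'   onto features); regenerated from `cfg` if missing.
#' @return list with `measurements` (3-d array subjects x repetitions x
#'   features) and `icc_true` (per-feature vector).
#' @export
simulate_repeated_measures <- function(cfg, truth = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(truth)) truth <- simulate_platform_pair(cfg)$truth
  p <- cfg$n_features
  icc <- cfg$icc_true
  icc_vec <- if (length(icc) == 1) rep(icc, p)
    else if (length(icc) == 2) ifelse(truth$robust, icc[1], icc[2])
    else if (length(icc) == p) icc
    else stop("icc_true must have length 1, 2 or n_features")

  set.seed(cfg$seed + 1L)
  n <- cfg$n_subjects
  k <- cfg$k_reps
  arr <- array(NA_real_, c(n, k, p),
               dimnames = list(sprintf("subject%03d", seq_len(n)),
                               sprintf("rep%d", seq_len(k)),
                               truth$feature))
  sigma <- 10^stats::runif(p, -1, 2)
  mu <- stats::rnorm(p, 0, 2) * sigma
  for (f in seq_len(p)) {
    subj <- stats::rnorm(n, 0, sqrt(icc_vec[f]))
    e <- matrix(stats::rnorm(n * k, 0, sqrt(1 - icc_vec[f])), n, k)
    arr[, , f] <- mu[f] + sigma[f] * (subj + e)
  }
  list(measurements = arr, icc_true = stats::setNames(icc_vec, truth$feature))
}

#' Write a simulated dataset to disk
#'
#' Platform tables, repeated measures (long format) and ground truth as
#' CSV, plus a manifest echoing the configuration.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory.
#' @return written paths, invisibly.
#' @export
write_simulation <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pair <- simulate_platform_pair(cfg)
  rm_ <- simulate_repeated_measures(cfg, pair$truth)
  pa <- file.path(dir, "platform_a.csv")
  pb <- file.path(dir, "platform_b.csv")
  write_feature_table(pair$table_a, pa)
  write_feature_table(pair$table_b, pb)
  pt <- file.path(dir, "ground_truth.csv")
  data.table::fwrite(pair$truth, pt)
  long <- do.call(rbind, lapply(seq_len(cfg$k_reps), function(j) {
    data.frame(lesion_id = dimnames(rm_$measurements)[[1]],
               repetition = j,
               rm_$measurements[, j, ], check.names = FALSE)
  }))
  pr <- file.path(dir, "repeated_measures.csv")
  data.table::fwrite(long, pr)
  pm <- file.path(dir, "simulation_manifest.json")
  jsonlite::write_json(unclass(cfg), pm, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(pa, pb, pt, pr, pm))
}
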