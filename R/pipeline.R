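## End-to-end workflow driver: ICC gate -> distances -> clustering with
## consensus k -> cross-platform ARI grid -> stable configurations ->
## Composite Index, winners, QC -> winner-frequency aggregation. Every
## threshold and default is echoed verbatim into the run manifest, and the
## whole run is a deterministic function of (config, seed).

#' Pipeline configuration
#'
#' Collects every tunable of the workflow with its default, so the run
#' manifest can echo the exact configuration. Inputs are either file paths
#' (`platform_a`, `platform_b`, optional `repeated_a`/`repeated_b`
#' long-format CSVs) or a [sim_config()] in `simulate`.
#'
#' @param platform_a,platform_b paths to platform feature tables (CSV).
#' @param repeated_a,repeated_b paths to long-format repeated-measures
#'   tables for the ICC stage (optional; the stage is skipped with a
#'   manifest note when absent).
#' @param simulate a [sim_config()]; when given, inputs are generated
#'   in-memory and the path arguments are ignored.
#' @param icc_threshold retention gate on ICC(A,1).
#' @param icc_mode how the two platforms' retained sets combine
#'   ("intersection", "union", "a_only", "b_only").
#' @param allow_empty_retained proceed with all features when the ICC gate
#'   retains none (explicit override; default FALSE halts at the gate).
#' @param metrics,linkages grid axes.
#' @param k_policy,k_fixed,k_range,early_stop see [evaluate_grid()].
#' @param standardize geometric-distance standardization override (NULL =
#'   per-metric default: on for euclidean/manhattan/cosine).
#' @param ari_threshold stability gate.
#' @param epsilon,delta,min_corr,redundancy_cutoff,ci_floor Composite Index
#'   stage parameters.
#' @param seed integer seed for any stochastic input generation.
#' @param make_plot write the stability scatter as PNG (needs ggplot2).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(platform_a = NULL, platform_b = NULL,
                            repeated_a = NULL, repeated_b = NULL,
                            simulate = NULL,
                            icc_threshold = 0.75,
                            icc_mode = "intersection",
                            allow_empty_retained = FALSE,
                            metrics = DISTANCE_METRICS,
                            linkages = LINKAGES,
                            k_policy = "per_platform", k_fixed = NULL,
                            k_range = 2:10,
                            early_stop = list(threshold = 0.5, patience = 3),
                            standardize = NULL,
                            ari_threshold = 0.8,
                            epsilon = 1e-6, delta = 0.5,
                            min_corr = 0.6, redundancy_cutoff = 0.9,
                            ci_floor = -Inf,
                            seed = 1L, make_plot = FALSE) {
  structure(list(
    platform_a = platform_a, platform_b = platform_b,
    repeated_a = repeated_a, repeated_b = repeated_b,
    simulate = simulate,
    icc_threshold = icc_threshold, icc_mode = icc_mode,
    allow_empty_retained = allow_empty_retained,
    metrics = metrics, linkages = linkages,
    k_policy = k_policy, k_fixed = k_fixed, k_range = k_range,
    early_stop = early_stop, standardize = standardize,
    ari_threshold = ari_threshold,
    epsilon = epsilon, delta = delta,
    min_corr = min_corr, redundancy_cutoff = redundancy_cutoff,
    ci_floor = ci_floor, seed = as.integer(seed), make_plot = make_plot
  ), class = "pipeline_config")
}

#' Run the full cross-platform robustness pipeline
#'
#' Stage order: input/simulation -> per-platform ICC(A,1) gate ->
#' platform alignment -> (metric x linkage) clustering grid with consensus
#' k -> ARI stability gate -> Composite Index -> per-solution winners and
#' QC filter -> winner-frequency aggregation. All intermediates are written
#' under `outdir` and a `manifest.json` records the configuration, stage
#' counts and md5 hashes of every text artifact (timestamps and absolute
#' paths are deliberately excluded so reruns are byte-identical).
#'
#' A stage failure aborts with the stage name after writing the partial
#' manifest.
#'
#' @param config a [pipeline_config()].
#' @param outdir run directory (created; contents overwritten).
#' @return invisibly, a list with the in-memory stage results and
#'   `manifest`.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    tool = "radrobust",
    version = as.character(utils::packageVersion("radrobust")),
    config = serializable_config(config),
    stages = list()
  )
  stage <- "inputs"
  result <- list()
  on.exit({
    manifest$failed_stage <- stage
    write_manifest(manifest, outdir)
  })

  ## ---- inputs ----
  if (!is.null(config$simulate)) {
    cfg <- config$simulate
    if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, cfg)
    pairgen <- simulate_platform_pair(cfg)
    ta <- pairgen$table_a
    tb <- pairgen$table_b
    rep_a <- rep_b <- simulate_repeated_measures(cfg, pairgen$truth)$measurements
    data.table::fwrite(pairgen$truth, file.path(outdir, "ground_truth.csv"))
    result$truth <- pairgen$truth
  } else {
    if (is.null(config$platform_a) || is.null(config$platform_b))
      stop("stage inputs: need platform_a and platform_b paths (or a simulate config)")
    ta <- read_feature_table(config$platform_a, "platform_a")
    tb <- read_feature_table(config$platform_b, "platform_b")
    rep_a <- if (!is.null(config$repeated_a)) read_repeated_long(config$repeated_a)
    rep_b <- if (!is.null(config$repeated_b)) read_repeated_long(config$repeated_b)
  }
  manifest$stages$inputs <- list(
    n_lesions_a = nrow(ta$values), n_features_a = ncol(ta$values),
    n_lesions_b = nrow(tb$values), n_features_b = ncol(tb$values))

  ## ---- ICC gate ----
  stage <- "icc"
  if (!is.null(rep_a) && !is.null(rep_b)) {
    scr_a <- icc_screen(rep_a, config$icc_threshold)
    scr_b <- icc_screen(rep_b, config$icc_threshold)
    data.table::fwrite(scr_a, file.path(outdir, "icc_platform_a.csv"))
    data.table::fwrite(scr_b, file.path(outdir, "icc_platform_b.csv"))
    ra <- filter_robust(scr_a, allow_empty = config$allow_empty_retained)
    rb <- filter_robust(scr_b, allow_empty = config$allow_empty_retained)
    retained <- combine_retained(harmonize_feature_names(ra),
                                 harmonize_feature_names(rb),
                                 config$icc_mode)
    if (!length(retained)) {
      if (!config$allow_empty_retained)
        stop("stage icc: empty retained set after combining platforms")
      retained <- NULL
    }
    result$icc <- list(a = scr_a, b = scr_b)
    manifest$stages$icc <- list(
      threshold = config$icc_threshold, mode = config$icc_mode,
      retained_a = sum(scr_a$retained), retained_b = sum(scr_b$retained),
      retained_combined = length(retained %||% character()))
  } else {
    retained <- NULL
    manifest$stages$icc <- list(skipped = "no repeated-measures input")
  }

  ## ---- alignment ----
  stage <- "align"
  pair <- align_platforms(ta, tb)
  if (!is.null(retained)) {
    keep <- intersect(pair$common_features, retained)
    if (length(keep) < 3) stop("stage align: fewer than 3 features survive the ICC gate")
    pair <- align_platforms(
      feature_table(pair$table_a$values[, keep, drop = FALSE],
                    platform_id = ta$platform_id),
      feature_table(pair$table_b$values[, keep, drop = FALSE],
                    platform_id = tb$platform_id))
  }
  write_aligned_pair(pair, outdir)
  manifest$stages$align <- list(
    n_lesions = pair$report$n_shared_lesions,
    n_common_features = length(pair$common_features))

  ## ---- stability grid ----
  stage <- "grid"
  grid <- evaluate_grid(pair,
                        metrics = config$metrics, linkages = config$linkages,
                        k_policy = config$k_policy, k_fixed = config$k_fixed,
                        k_range = config$k_range, early_stop = config$early_stop,
                        standardize = config$standardize,
                        ari_threshold = config$ari_threshold)
  data.table::fwrite(grid$records, file.path(outdir, "stability_grid.csv"))
  stable <- select_stable_configs(grid, config$ari_threshold)
  data.table::fwrite(stable, file.path(outdir, "stable_configs.csv"))
  result$grid <- grid
  result$stable <- stable
  manifest$stages$grid <- list(
    n_configs = nrow(grid$records), n_stable = nrow(stable),
    ari_threshold = config$ari_threshold, k_policy = config$k_policy)
  if (config$make_plot && requireNamespace("ggplot2", quietly = TRUE)) {
    for (side in c("a", "b")) {
      f <- file.path(outdir, sprintf("stability_scatter_%s.png", side))
      grDevices::png(f, width = 900, height = 700, res = 120)
      print(plot_stability_grid(grid, side))
      grDevices::dev.off()
    }
  }

  ## ---- composite index + winners ----
  stage <- "composite"
  records <- composite_index(pair, epsilon = config$epsilon)
  data.table::fwrite(records, file.path(outdir, "feature_robustness.csv"))
  result$records <- records
  if (isTRUE(attr(records, "degenerate")))
    manifest$stages$composite <- list(degenerate = TRUE)

  stage <- "select"
  fcor <- feature_cor_matrix(pair)
  solutions <- list()
  final_sets <- list()
  sel_rows <- list()
  for (i in seq_len(nrow(stable))) {
    key <- paste(stable$metric[i], stable$linkage[i], sep = ":")
    part <- grid$partitions[[key]]$a   # platform A partition hosts the winners
    sel <- select_winners(part, records, delta = config$delta,
                          ci_floor = config$ci_floor)
    qc <- qc_filter(sel, records, fcor,
                    min_corr = config$min_corr,
                    redundancy_cutoff = config$redundancy_cutoff)
    solutions[[key]] <- sel
    final_sets[[key]] <- qc$final_set
    if (nrow(sel$selected)) {
      sel_rows[[key]] <- data.frame(metric = stable$metric[i],
                                    linkage = stable$linkage[i],
                                    sel$selected,
                                    qc_pass = sel$selected$feature %in% qc$final_set,
                                    stringsAsFactors = FALSE)
    }
  }
  sel_df <- if (length(sel_rows)) do.call(rbind, sel_rows) else
    data.frame(metric = character(), linkage = character(), feature = character(),
               cluster = integer(), ci = numeric(), role = character(),
               qc_pass = logical())
  rownames(sel_df) <- NULL
  data.table::fwrite(sel_df, file.path(outdir, "winners.csv"))
  result$solutions <- solutions
  result$final_sets <- final_sets
  manifest$stages$select <- list(
    n_solutions = length(solutions),
    delta = config$delta, min_corr = config$min_corr,
    redundancy_cutoff = config$redundancy_cutoff,
    union_final_set = sort(unique(unlist(final_sets))))

  ## ---- aggregation ----
  stage <- "aggregate"
  if (length(solutions)) {
    freq <- aggregate_winner_frequencies(solutions)
    data.table::fwrite(freq, file.path(outdir, "winner_frequencies.csv"))
    result$frequencies <- freq
    manifest$stages$aggregate <- list(
      n_features_ever_winner = sum(freq$n_winner > 0),
      top = freq$feature[seq_len(min(5, nrow(freq)))])
  } else {
    manifest$stages$aggregate <- list(skipped = "no stable solution")
  }

  stage <- "done"
  on.exit()
  manifest$failed_stage <- NULL
  manifest <- write_manifest(manifest, outdir)
  result$manifest <- manifest
  invisible(result)
}

serializable_config <- function(config) {
  cfg <- unclass(config)
  cfg$simulate <- if (!is.null(cfg$simulate)) unclass(cfg$simulate)
  cfg$ci_floor <- if (is.finite(cfg$ci_floor)) cfg$ci_floor else NULL
  cfg
}

write_manifest <- function(manifest, outdir) {
  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  text <- files[grepl("\\.(csv|json)$", files)]
  hashes <- tools::md5sum(file.path(outdir, text))
  manifest$files <- as.list(stats::setNames(unname(hashes), text))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  manifest
}
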