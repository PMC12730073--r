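## Feature-table input, validation, name harmonization and platform alignment.

WAVELET_SUBBANDS <- c("lll", "llh", "lhl", "lhh", "hll", "hlh", "hhl", "hhh")
FEATURE_FAMILIES <- c("firstorder", "shape", "glcm", "glrlm", "glszm", "gldm", "ngtdm")

#' Harmonize radiomic feature names
#'
#' Case-folds names, normalizes `-`, `.` and whitespace separators to `_`,
#' collapses repeated underscores and optionally strips platform-specific
#' prefixes. The two supported extractor dialects share a PyRadiomics naming
#' core (`<filter>_<family>_<featurename>`), so harmonized names are the
#' matching key used by [align_platforms()].
#'
#' @param x character vector of feature names.
#' @param strip_prefixes character vector of regular expressions; a match at
#'   the start of a harmonized name (followed by `_`) is removed.
#' @return character vector of harmonized names.
#' @export
#' @examples
#' harmonize_feature_names(c("Wavelet-LHL_firstorder.Mean", "ORIGINAL_GLCM_ClusterShade"))
harmonize_feature_names <- function(x, strip_prefixes = character()) {
  y <- tolower(trimws(as.character(x)))
  y <- gsub("[-.[:space:]]+", "_", y)
  y <- gsub("_+", "_", y)
  y <- gsub("^_|_$", "", y)
  for (p in strip_prefixes) {
    y <- sub(paste0("^(?:", p, ")_"), "", y, perl = TRUE)
  }
  y
}

#' Parse filter and family metadata from feature names
#'
#' Feature names follow the extractor convention
#' `<filter>_<family>_<featurename>` where `<filter>` is `original` or a
#' wavelet sub-band (`wavelet_lll` ... `wavelet_hhh`, the low/high-pass
#' decomposition along the three axes) and `<family>` is one of firstorder,
#' shape, glcm, glrlm, glszm, gldm, ngtdm. Unparseable names are flagged
#' (`parsed = FALSE`), never dropped.
#'
#' @param feature_names character vector (raw or harmonized names accepted).
#' @return data.frame with columns `feature`, `filter`, `family`, `parsed`.
#' @export
#' @examples
#' parse_feature_meta("wavelet_hlh_glcm_clustershade")
parse_feature_meta <- function(feature_names) {
  h <- harmonize_feature_names(feature_names)
  fam_alt <- paste(FEATURE_FAMILIES, collapse = "|")
  sub_alt <- paste(WAVELET_SUBBANDS, collapse = "|")
  pat <- paste0("^(original|wavelet_(?:", sub_alt, "))_(", fam_alt, ")_(.+)$")
  m <- regmatches(h, regexec(pat, h))
  filter <- vapply(m, function(g) if (length(g)) g[2] else NA_character_, "")
  family <- vapply(m, function(g) if (length(g)) g[3] else NA_character_, "")
  filter <- sub("^wavelet_", "wavelet-", filter)
  data.frame(
    feature = feature_names,
    filter = toupper_subband(filter),
    family = family,
    parsed = !is.na(family),
    stringsAsFactors = FALSE
  )
}

toupper_subband <- function(filter) {
  ifelse(grepl("^wavelet-", filter),
         paste0("wavelet-", toupper(sub("^wavelet-", "", filter))),
         filter)
}

#' Construct a feature table
#'
#' A feature table is a lesions-by-features numeric matrix tagged with a
#' platform label and per-feature metadata. Rows are lesions (each lesion is
#' a separate observational unit; no patient-level aggregation), columns are
#' features.
#'
#' @param values numeric matrix (lesions x features).
#' @param lesion_ids,feature_names identifiers; defaults taken from dimnames.
#' @param platform_id label of the extraction platform.
#' @return object of class `feature_table`.
#' @export
feature_table <- function(values, lesion_ids = rownames(values),
                          feature_names = colnames(values),
                          platform_id = "platform") {
  values <- as.matrix(values)
  if (is.null(lesion_ids)) lesion_ids <- as.character(seq_len(nrow(values)))
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(values)))
  lesion_ids <- as.character(lesion_ids)
  feature_names <- as.character(feature_names)
  if (anyDuplicated(lesion_ids)) {
    stop("duplicate lesion ids: ",
         paste(unique(lesion_ids[duplicated(lesion_ids)]), collapse = ", "))
  }
  if (anyDuplicated(feature_names)) {
    stop("duplicate feature names: ",
         paste(unique(feature_names[duplicated(feature_names)]), collapse = ", "))
  }
  stopifnot(nrow(values) == length(lesion_ids),
            ncol(values) == length(feature_names))
  storage.mode(values) <- "double"
  dimnames(values) <- list(lesion_ids, feature_names)
  structure(
    list(platform_id = platform_id,
         lesion_ids = lesion_ids,
         feature_names = feature_names,
         values = values,
         meta = parse_feature_meta(feature_names)),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> platform:", x$platform_id,
      "|", length(x$lesion_ids), "lesions x",
      length(x$feature_names), "features\n")
  nf <- sum(!x$meta$parsed)
  if (nf) cat("  ", nf, "feature name(s) not parseable as <filter>_<family>_<name>\n")
  nmiss <- sum(!is.finite(x$values))
  if (nmiss) cat("  ", nmiss, "non-finite value(s)\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Validate a feature table
#'
#' Reports (without dropping) every non-finite entry and every feature name
#' that does not parse as `<filter>_<family>_<featurename>`.
#'
#' @param ft a [feature_table()].
#' @return list with `n_lesions`, `n_features`, `non_finite` (data.frame of
#'   lesion/feature locations) and `unparsed_features`.
#' @export
validate_feature_table <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  bad <- which(!is.finite(ft$values), arr.ind = TRUE)
  list(
    n_lesions = nrow(ft$values),
    n_features = ncol(ft$values),
    non_finite = data.frame(
      lesion = ft$lesion_ids[bad[, 1]],
      feature = ft$feature_names[bad[, 2]],
      stringsAsFactors = FALSE
    ),
    unparsed_features = ft$meta$feature[!ft$meta$parsed]
  )
}

#' Read a platform feature table from delimited text
#'
#' Expects a header row, a lesion-id column (first column by default) and at
#' least one numeric feature column. Columns containing isolated non-numeric
#' cells are kept with those cells set to missing and are flagged in the
#' parse report; columns with no numeric content are dropped (also
#' reported).
#'
#' @param path CSV/TSV file path (delimiter sniffed by data.table).
#' @param platform_id label stored in the resulting table.
#' @param id_col name or index of the lesion-id column.
#' @return a [feature_table()]; the parse report is attached as
#'   `attr(, "report")` with elements `dropped_columns` and `flagged_cells`.
#' @export
read_feature_table <- function(path, platform_id, id_col = 1L) {
  df <- data.table::fread(path, data.table = FALSE, colClasses = "character")
  if (is.numeric(id_col)) {
    if (id_col > ncol(df)) stop("lesion-id column index out of range")
    id_name <- names(df)[id_col]
  } else {
    if (!id_col %in% names(df)) stop("missing lesion-id column '", id_col, "'")
    id_name <- id_col
  }
  ids <- df[[id_name]]
  if (anyDuplicated(ids)) {
    stop("duplicate lesion ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  feat <- df[setdiff(names(df), id_name)]
  dropped <- character()
  flagged <- list()
  cols <- lapply(names(feat), function(nm) {
    raw <- feat[[nm]]
    num <- suppressWarnings(as.numeric(raw))
    coerced <- which(is.na(num) & !is.na(raw) & nzchar(trimws(raw)) &
                       !toupper(trimws(raw)) %in% c("NA", "NAN"))
    if (all(is.na(num))) {
      dropped <<- c(dropped, nm)
      return(NULL)
    }
    if (length(coerced)) {
      flagged[[nm]] <<- data.frame(lesion = ids[coerced], value = raw[coerced],
                                   stringsAsFactors = FALSE)
    }
    num
  })
  names(cols) <- names(feat)
  cols <- cols[!vapply(cols, is.null, TRUE)]
  if (!length(cols)) stop("no numeric feature columns in ", path)
  values <- do.call(cbind, cols)
  rownames(values) <- ids
  ft <- feature_table(values, platform_id = platform_id)
  attr(ft, "report") <- list(dropped_columns = dropped, flagged_cells = flagged)
  ft
}

#' Write a feature table as CSV
#'
#' Inverse of [read_feature_table()]: first column `lesion_id`, one column
#' per feature. Values are written at full precision so that decimal text
#' that round-trips through `double` is reproduced bit-identically.
#'
#' @param ft a [feature_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  df <- data.frame(lesion_id = ft$lesion_ids, ft$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}

#' Align two platform feature tables
#'
#' Restricts both tables to their shared lesions and to the features whose
#' harmonized names (see [harmonize_feature_names()]) match, in identical
#' order. Features exclusive to one platform are listed in the report, as
#' are features excluded because they carry missing values (all downstream
#' distance and Composite Index formulas assume complete vectors).
#'
#' @param a,b [feature_table()] objects.
#' @param strip_prefixes passed to [harmonize_feature_names()].
#' @param drop_incomplete drop features with any non-finite value in either
#'   table (default TRUE).
#' @return object of class `aligned_pair`: list with `table_a`, `table_b`
#'   (restricted, columns renamed to harmonized names), `common_features`
#'   and `report`.
#' @export
align_platforms <- function(a, b, strip_prefixes = character(),
                            drop_incomplete = TRUE) {
  stopifnot(inherits(a, "feature_table"), inherits(b, "feature_table"))
  lesions <- intersect(a$lesion_ids, b$lesion_ids)
  if (length(lesions) < 2) stop("fewer than 2 shared lesion ids")

  ha <- harmonize_feature_names(a$feature_names, strip_prefixes)
  hb <- harmonize_feature_names(b$feature_names, strip_prefixes)
  dup_a <- a$feature_names[duplicated(ha)]
  dup_b <- b$feature_names[duplicated(hb)]
  keep_a <- !duplicated(ha)
  keep_b <- !duplicated(hb)
  common <- intersect(ha[keep_a], hb[keep_b])
  if (!length(common)) stop("zero shared features after name harmonization")

  ia <- match(common, ha)
  ib <- match(common, hb)
  va <- a$values[lesions, ia, drop = FALSE]
  vb <- b$values[lesions, ib, drop = FALSE]
  colnames(va) <- colnames(vb) <- common

  incomplete <- character()
  if (drop_incomplete) {
    bad <- !(apply(is.finite(va), 2, all) & apply(is.finite(vb), 2, all))
    incomplete <- common[bad]
    va <- va[, !bad, drop = FALSE]
    vb <- vb[, !bad, drop = FALSE]
    common <- common[!bad]
    if (!length(common)) stop("zero shared features with complete values")
  }

  report <- list(
    n_shared_lesions = length(lesions),
    only_in_a = sort(setdiff(ha[keep_a], hb[keep_b])),
    only_in_b = sort(setdiff(hb[keep_b], ha[keep_a])),
    duplicate_harmonized_a = dup_a,
    duplicate_harmonized_b = dup_b,
    incomplete_features = incomplete
  )
  structure(
    list(table_a = feature_table(va, platform_id = a$platform_id),
         table_b = feature_table(vb, platform_id = b$platform_id),
         common_features = common,
         report = report),
    class = "aligned_pair"
  )
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat("<aligned_pair>", x$table_a$platform_id, "vs", x$table_b$platform_id,
      "|", x$report$n_shared_lesions, "lesions x",
      length(x$common_features), "common features\n")
  r <- x$report
  cat("  exclusive to A:", length(r$only_in_a),
      "| exclusive to B:", length(r$only_in_b),
      "| incomplete dropped:", length(r$incomplete_features), "\n")
  invisible(x)
}

#' Write an aligned pair and its harmonization report
#'
#' @param pair an [align_platforms()] result.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_aligned_pair <- function(pair, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pa <- file.path(dir, "aligned_platform_a.csv")
  pb <- file.path(dir, "aligned_platform_b.csv")
  pr <- file.path(dir, "harmonization_report.json")
  write_feature_table(pair$table_a, pa)
  write_feature_table(pair$table_b, pb)
  jsonlite::write_json(pair$report, pr, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(pa, pb, pr))
}
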