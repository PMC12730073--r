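test_that("feature CSV round-trips through read_feature_table", {
  vals <- matrix(c(1.5, 2.25, -3, 0.125, 10, 7,
                   4, 5, 6, 0.5, -1.75, 2), nrow = 3,
                 dimnames = list(c("L1", "L2", "L3"),
                                 c("original_firstorder_mean",
                                   "original_glcm_contrast",
                                   "wavelet_lhl_firstorder_mean",
                                   "original_shape_volume")))
  path <- write_feature_csv(vals)
  ft <- read_feature_table(path, "platform_a")
  expect_s3_class(ft, "feature_table")
  expect_equal(dim(ft), c(3L, 4L))
  expect_identical(ft$values, vals)   # bit-identical for round-trippable text

  # write -> read round-trip is also exact
  out <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, out)
  expect_identical(read_feature_table(out, "platform_a")$values, vals)
})

test_that("feature metadata parses filter and family from names", {
  meta <- parse_feature_meta(c("wavelet_hlh_glcm_clustershade",
                               "original_firstorder_skewness",
                               "Wavelet-LHL_firstorder.Mean",
                               "diagnostics_versions_pyradiomics"))
  expect_equal(meta$filter[1:3], c("wavelet-HLH", "original", "wavelet-LHL"))
  expect_equal(meta$family[1:3], c("glcm", "firstorder", "firstorder"))
  expect_true(all(meta$parsed[1:3]))
  expect_false(meta$parsed[4])   # flagged, not dropped
})

test_that("non-numeric cells are flagged and set missing; empty columns dropped", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("lesion_id,original_firstorder_mean,original_glcm_contrast,notes",
               "L1,1.5,oops,freetext",
               "L2,2.5,3.5,more",
               "L3,9,4.5,text"), path)
  ft <- read_feature_table(path, "p")
  rep <- attr(ft, "report")
  expect_equal(rep$dropped_columns, "notes")
  expect_named(rep$flagged_cells, "original_glcm_contrast")
  expect_true(is.na(ft$values["L1", "original_glcm_contrast"]))
  expect_equal(ft$values["L2", "original_glcm_contrast"], 3.5)
})

test_that("read errors: duplicate ids, missing id column, no numeric columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("lesion_id,f_a", "L1,1", "L1,2"), path)
  expect_error(read_feature_table(path, "p"), "duplicate lesion ids")
  writeLines(c("lesion_id,f_a", "L1,x", "L2,y"), path)
  expect_error(read_feature_table(path, "p"), "no numeric feature")
  path2 <- write_feature_csv(matrix(1:4, 2, dimnames = list(c("a", "b"), c("x", "y"))))
  expect_error(read_feature_table(path2, "p", id_col = "missing"), "lesion-id column")
})

test_that("alignment harmonizes dialect differences in feature names", {
  set.seed(11)
  vals <- matrix(rnorm(30), 3, 10,
                 dimnames = list(paste0("L", 1:3),
                                 paste0("original_firstorder_f", 1:10)))
  a <- feature_table(vals, platform_id = "a")
  b_names <- toupper(gsub("_", "-", colnames(vals)))
  b <- feature_table(`colnames<-`(vals, b_names), platform_id = "b")

  # oracle: exact string matching finds nothing across the dialects
  expect_length(intersect(colnames(a$values), b_names), 0)
  pair <- align_platforms(a, b)
  expect_length(pair$common_features, 10)
  expect_equal(pair$table_a$values, pair$table_b$values)
})

test_that("alignment subsets to shared features and lesions and reports exclusives", {
  set.seed(12)
  base <- matrix(rnorm(40), 4, 10,
                 dimnames = list(paste0("L", 1:4),
                                 c(paste0("original_firstorder_f", 1:7),
                                   paste0("original_shape_s", 1:3))))
  a <- feature_table(base, platform_id = "a")
  # platform B misses the 3 shape features and one lesion (Table-1-style mismatch)
  b <- feature_table(base[1:3, 1:7], platform_id = "b")
  pair <- align_platforms(a, b)
  expect_equal(length(pair$common_features), 7)
  expect_equal(pair$report$only_in_a, sort(paste0("original_shape_s", 1:3)))
  expect_equal(pair$report$n_shared_lesions, 3)

  # identity alignment keeps everything
  pid <- align_platforms(a, a)
  expect_setequal(pid$common_features, colnames(base))

  # errors
  expect_error(align_platforms(a, feature_table(base[1, , drop = FALSE],
                                                platform_id = "b")),
               "fewer than 2 shared lesion")
  c_names <- paste0("other_family_x", 1:10)
  cc <- feature_table(`colnames<-`(base, c_names), platform_id = "c")
  expect_error(align_platforms(a, cc), "zero shared features")
})

test_that("align_platforms is idempotent and drops incomplete features with a report", {
  set.seed(13)
  A <- matrix(rnorm(24), 4, 6,
              dimnames = list(paste0("L", 1:4), paste0("original_glcm_f", 1:6)))
  B <- A + rnorm(24, sd = 0.01)
  B[2, 3] <- NA
  pair <- align_platforms(feature_table(A, platform_id = "a"),
                          feature_table(B, platform_id = "b"))
  expect_equal(pair$report$incomplete_features, "original_glcm_f3")
  expect_length(pair$common_features, 5)

  pair2 <- align_platforms(pair$table_a, pair$table_b)
  expect_identical(pair2$common_features, pair$common_features)
  expect_identical(pair2$table_a$values, pair$table_a$values)
  expect_identical(pair2$table_b$values, pair$table_b$values)
})

test_that("validation reports non-finite entries without dropping them", {
  A <- matrix(c(1, NA, 3, Inf), 2, 2,
              dimnames = list(c("L1", "L2"), c("original_glcm_a", "original_glcm_b")))
  v <- validate_feature_table(feature_table(A, platform_id = "p"))
  expect_equal(nrow(v$non_finite), 2)
  expect_setequal(v$non_finite$feature, c("original_glcm_a", "original_glcm_b"))
})
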