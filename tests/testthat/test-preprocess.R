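test_that("quartiles use linear interpolation over observed values only", {
  m <- matrix(7, 3, 4)
  expect_equal(unlist(compute_quartiles(make_features(m))),
               c(q1 = 7, q2 = 7, q3 = 7))

  m2 <- matrix(as.numeric(1:8), 2, 4)
  q <- compute_quartiles(make_features(m2))
  expect_equal(c(q$q1, q$q2, q$q3), c(2.75, 4.5, 6.25))

  # permutation invariance in sample columns
  m3 <- random_intensities(10, 6, seed = 5)
  m3[2, 3] <- NA
  q_a <- compute_quartiles(make_features(m3))
  q_b <- compute_quartiles(make_features(m3[, c(4, 2, 6, 1, 3, 5)]))
  expect_equal(q_a, q_b)

  expect_error(compute_quartiles(make_features(matrix(NA_real_, 2, 3))),
               "observed")
})

test_that("missing mask separates filtering and strict semantics", {
  m <- random_intensities(40, 6, seed = 9)
  feats <- make_features(m)
  expect_false(any(as.matrix(
    build_missing_mask(feats, 0, "filtering")[, -1])))

  q3 <- compute_quartiles(feats)$q3
  mk <- as.matrix(build_missing_mask(feats, q3, "filtering")[, -1])
  expect_equal(mean(mk), 0.75, tolerance = 0.01)

  m[5, 2] <- NA
  feats2 <- make_features(m)
  strict <- as.matrix(build_missing_mask(feats2, q3, "strict")[, -1])
  expect_equal(sum(strict), 1L)   # threshold ignored entirely
  expect_true(strict[5, 2])
})

test_that("prevalence filter applies the >= min_frac rule in every group", {
  # 2 groups of 4 samples; feature A observed 2/4 and 3/4 -> kept,
  # feature B observed 1/4 and 4/4 -> dropped
  m <- matrix(10, 2, 8, dimnames = list(c("A", "B"), paste0("s", 1:8)))
  m["A", c(1, 2)] <- NA
  m["B", c(1, 2, 3)] <- NA
  feats <- make_features(m)
  design <- make_design(paste0("s", 1:8), rep(c("g1", "g2"), each = 4))
  mask <- build_missing_mask(feats, 0, "filtering")
  kept <- filter_by_group_prevalence(feats, mask, design, min_frac = 0.5)
  expect_identical(kept$feature_id, "A")

  # all-observed: nothing dropped at any min_frac <= 1
  m2 <- random_intensities(15, 8, seed = 2)
  feats2 <- make_features(m2)
  mask2 <- build_missing_mask(feats2, 0, "filtering")
  expect_equal(nrow(filter_by_group_prevalence(feats2, mask2, design, 1.0)), 15L)

  # min_frac = 1 keeps only complete-in-every-group features
  m2[1, 1] <- NA
  feats3 <- make_features(m2)
  mask3 <- build_missing_mask(feats3, 0, "filtering")
  kept3 <- filter_by_group_prevalence(feats3, mask3, design, 1.0)
  expect_equal(nrow(kept3), 14L)
  expect_false("F1" %in% kept3$feature_id)
})

test_that("prevalence filter matches exhaustive counting on random masks", {
  set.seed(31)
  for (rep in 1:20) {
    m <- random_intensities(50, 24, seed = 100 + rep)
    m[matrix(runif(length(m)) < 0.3, nrow(m))] <- NA
    feats <- make_features(m)
    design <- make_design(colnames(m), rep(paste0("g", 1:4), each = 6))
    mask <- build_missing_mask(feats, 0, "filtering")
    kept <- filter_by_group_prevalence(feats, mask, design, 0.5)
    # independent brute-force oracle
    expect_kept <- vapply(seq_len(nrow(m)), function(i) {
      all(vapply(paste0("g", 1:4), function(g) {
        cols <- design$sample_id[design$condition == g]
        sum(!is.na(m[i, cols])) / length(cols) >= 0.5
      }, logical(1)))
    }, logical(1))
    expect_identical(kept$feature_id, rownames(m)[expect_kept])
  }
})

test_that("kNN imputation fills absences from nearest features", {
  # duplicate-neighbor case: a twin supplies the missing value exactly
  base <- c(5, 9, 13, 21, 40)
  m <- rbind(F1 = base, F2 = base, F3 = rev(base) * 3, F4 = base^1.3)
  colnames(m) <- paste0("s", 1:5)
  m["F1", 3] <- NA
  imp <- impute_knn(make_features(m), k = 1)
  expect_equal(feature_matrix(imp)["F1", "s3"], 13)

  # heavy missingness falls back to the feature's own observed mean
  m2 <- random_intensities(12, 10, seed = 77)
  m2[1, 1:6] <- NA  # 60% missing > rowmax 0.5
  imp2 <- impute_knn(make_features(m2), k = 3)
  expect_equal(unname(feature_matrix(imp2)[1, 1]), mean(m2[1, 7:10]))

  # identity on complete data
  feats3 <- make_features(random_intensities(8, 4, seed = 3))
  expect_equal(impute_knn(feats3), feats3)

  # colmax violation is a hard error naming the sample
  m4 <- random_intensities(10, 3, seed = 4)
  m4[1:10, 2] <- NA
  expect_error(impute_knn(make_features(m4)), "s2")
})

test_that("median-of-ratios normalization matches hand and oracle results", {
  m <- matrix(c(2, 8, 4, 16), 2, dimnames = list(c("F1", "F2"), c("a", "b")))
  norm <- normalize_median_ratio(make_features(m))
  sf <- attr(norm, "size_factors")$size_factor
  expect_equal(sf[2] / sf[1], 2)
  nm <- feature_matrix(norm)
  expect_equal(nm[, 1], nm[, 2])

  # single sample: reference equals the sample, size factor 1
  one <- make_features(matrix(c(3, 5, 11), 3, 1))
  norm1 <- normalize_median_ratio(one)
  expect_equal(attr(norm1, "size_factors")$size_factor, 1)
  expect_equal(feature_matrix(norm1), feature_matrix(one))

  # brute-force oracle on random positive matrices
  for (rep in 1:10) {
    m3 <- random_intensities(10, 6, seed = 200 + rep)
    out <- feature_matrix(normalize_median_ratio(make_features(m3)))
    oracle <- oracle_median_ratio(m3)
    expect_equal(out, oracle, tolerance = 1e-12)
  }

  expect_error(normalize_median_ratio(make_features(matrix(c(0, 1, 2, 3), 2))),
               "positive")
})

test_that("log2 transform is exact and monotone", {
  m <- matrix(c(8, 1, 2, 1024), 2, dimnames = list(c("F1", "F2"), c("a", "b")))
  lg <- feature_matrix(log2_transform(make_features(m)))
  expect_equal(lg, log2(m))
  expect_equal(lg["F1", "a"], 3)
  expect_equal(lg["F2", "a"], 0)
  m2 <- random_intensities(30, 1, seed = 8)
  lg2 <- feature_matrix(log2_transform(make_features(m2)))
  expect_equal(order(lg2[, 1]), order(m2[, 1]))
})

test_that("normalization removes a planted per-sample scalar", {
  m <- random_intensities(60, 1, seed = 12)
  scal <- c(1, 0.25, 2, 5.5, 0.8)
  full <- m[, rep(1, 5)] %*% diag(scal)
  dimnames(full) <- list(rownames(m), paste0("s", 1:5))
  norm <- feature_matrix(normalize_median_ratio(make_features(full)))
  for (j in 2:5) {
    expect_equal(norm[, j], norm[, 1], tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("preprocess_features runs the fixed stage order and reports", {
  sim <- simulate_screen(simulation_config(n_features = 300, n_modules = 4,
                                           module_size = 30, seed = 21))
  prep <- preprocess_features(sim$features, sim$design)
  m <- feature_matrix(prep$log2)
  expect_false(anyNA(m))
  expect_lt(prep$n_features_kept, prep$n_features_in)
  expect_equal(prep$threshold_used, prep$thresholds$q1)
  # censoring schemes use the harsher quartiles
  prep_h <- preprocess_features(sim$features, sim$design, censor = "high")
  expect_equal(prep_h$threshold_used, prep$thresholds$q3)
  expect_lte(prep_h$n_features_kept, prep$n_features_kept)
})
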