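test_that("condition distance matches a brute-force correlation oracle", {
  set.seed(15)
  r <- matrix(rnorm(10 * 6), 10, dimnames = list(paste0("M", 1:10),
                                                 paste0("c", 1:6)))
  d <- condition_distance(r)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(d[i, j], 1 - cor(r[, i], r[, j]), tolerance = 1e-12)
  }
  # identical and negated columns hit the extremes
  r2 <- cbind(a = r[, 1], b = r[, 1], c = -r[, 1])
  d2 <- condition_distance(r2)
  expect_equal(d2["a", "b"], 0)
  expect_equal(d2["a", "c"], 2)
})

test_that("average linkage reproduces hand agglomeration and ultrametrics", {
  d <- matrix(c(0, 0.1, 0.9, 0.1, 0, 0.9, 0.9, 0.9, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- average_linkage_tree(d)
  expect_equal(sort(hc$height), c(0.1, 0.9))

  # ultrametric input: heights reproduce the ultrametric exactly
  du <- matrix(c(0, .2, .6, .6, .2, 0, .6, .6, .6, .6, 0, .4, .6, .6, .4, 0), 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  hcu <- average_linkage_tree(du)
  expect_equal(as.matrix(cophenetic(hcu))[LETTERS[1:4], LETTERS[1:4]], du)

  # leaf order permutation leaves the topology unchanged
  p <- c(3, 1, 4, 2)
  hcp <- average_linkage_tree(du[p, p])
  expect_equal(as.matrix(cophenetic(hcp))[LETTERS[1:4], LETTERS[1:4]], du)
})

test_that("merge heights equal the brute-force mean pairwise distance", {
  set.seed(22)
  x <- matrix(rnorm(8 * 4), 8)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(letters[1:8], letters[1:8])
  hc <- average_linkage_tree(d)
  # oracle: recompute each merge height as the mean inter-group distance
  groups <- as.list(letters[1:8])
  names(groups) <- as.character(-(1:8))
  for (i in seq_len(nrow(hc$merge))) {
    g1 <- if (hc$merge[i, 1] < 0) letters[-hc$merge[i, 1]] else groups[[as.character(hc$merge[i, 1])]]
    g2 <- if (hc$merge[i, 2] < 0) letters[-hc$merge[i, 2]] else groups[[as.character(hc$merge[i, 2])]]
    expect_equal(hc$height[i], mean(d[g1, g2]), tolerance = 1e-12)
    groups[[as.character(i)]] <- c(g1, g2)
  }
})

test_that("silhouette cut finds planted leaf blocks", {
  blocks <- matrix(0.9, 6, 6)
  blocks[1:3, 1:3] <- 0.05
  blocks[4:6, 4:6] <- 0.05
  diag(blocks) <- 0
  dimnames(blocks) <- list(letters[1:6], letters[1:6])
  hc <- average_linkage_tree(blocks)
  cut <- cut_by_silhouette(hc, blocks)
  expect_equal(cut$chosen_k, 2L)
  expect_equal(length(unique(cut$labels[1:3])), 1L)
  expect_true(all(
    cut$silhouette_by_k$silhouette[cut$silhouette_by_k$k == 2] >=
      cut$silhouette_by_k$silhouette))
  # singleton range is forced
  cut3 <- cut_by_silhouette(hc, blocks, k_range = 3)
  expect_equal(cut3$chosen_k, 3L)
})

test_that("flat cut groups are unions of subtrees", {
  set.seed(30)
  r <- matrix(rnorm(12 * 8), 12)
  colnames(r) <- paste0("c", 1:8)
  d <- condition_distance(r)
  hc <- average_linkage_tree(d)
  cut <- cut_by_silhouette(hc, d)
  base <- cutree(hc, k = cut$chosen_k)
  expect_identical(unname(cut$labels), unname(base))
})

test_that("AU/BP support is deterministic and certain for clear splits", {
  # two condition blocks with separation far above resampling noise
  set.seed(41)
  r <- cbind(matrix(rnorm(12 * 3, 5, 0.1), 12), matrix(rnorm(12 * 3, -5, 0.1), 12))
  r[, 1:3] <- r[, 1:3] * rep(c(1, -1), 6)   # strong module signature
  colnames(r) <- paste0("c", 1:6)
  rownames(r) <- paste0("M", 1:12)
  prof <- structure(list(R = r, conditions = colnames(r),
                         modules = rownames(r)),
                    class = "ms1_correlation_profile")
  sup1 <- au_bootstrap(prof, n_boot = 200, seed = 5)
  sup2 <- au_bootstrap(prof, n_boot = 200, seed = 5)
  expect_identical(sup1, sup2)
  expect_true(all(sup1$bp >= 0 & sup1$bp <= 1))
  expect_true(all(sup1$au >= 0 & sup1$au <= 1, na.rm = TRUE))
  # the root (all leaves) is present in every resample
  root <- which.max(nchar(sup1$leaves))
  expect_equal(sup1$bp[root], 1)
  expect_equal(sup1$au[root], 1)

  expect_error(au_bootstrap(structure(list(R = r[1:3, ],
                                           conditions = colnames(r),
                                           modules = rownames(r)[1:3]),
                                      class = "ms1_correlation_profile")),
               "4 module rows")
})

test_that("condition_tree composes distance, cut and support", {
  set.seed(52)
  strong <- matrix(rnorm(12, 0, 1), 12, 1)
  r <- cbind(strong %*% t(c(1, 1, 1)) + rnorm(36, 0, 0.05),
             -strong %*% t(c(1, 1)) + rnorm(24, 0, 0.05))
  colnames(r) <- paste0("c", 1:5)
  rownames(r) <- paste0("M", 1:12)
  prof <- structure(list(R = r, conditions = colnames(r),
                         modules = rownames(r)),
                    class = "ms1_correlation_profile")
  tree <- condition_tree(prof, n_boot = 200, seed = 9)
  expect_s3_class(tree, "ms1_condition_tree")
  expect_equal(tree$chosen_k, 2L)
  expect_setequal(names(tree$cut_labels), colnames(r))
  td <- tidy(tree)
  expect_named(td, c("node", "leaves", "bp", "au", "height"))
  expect_equal(nrow(td), 4L)
  # heights non-decreasing toward the root
  expect_true(all(diff(tree$hclust$height) >= -1e-12))
})
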