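sim_marker_data <- function(n = 40, p = 9, effect = 3, seed = 1,
                            duplicate_first = FALSE) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rnorm(n * p), n)
  x[, 1] <- x[, 1] + effect * y
  if (duplicate_first) x <- cbind(x, x[, 1])
  colnames(x) <- paste0("F", seq_len(ncol(x)))
  list(x = x, y = y)
}

test_that("module selection takes the maximum absolute correlation", {
  r <- matrix(c(0.2, -0.9, 0.5), 3, 1,
              dimnames = list(paste0("M", 1:3), "UC"))
  prof <- structure(list(R = r, conditions = "UC", modules = rownames(r)),
                    class = "ms1_correlation_profile")
  expect_equal(select_marker_module(prof, "UC"), "M2")

  r2 <- matrix(0.4, 3, 1, dimnames = list(paste0("M", 1:3), "UC"))
  prof2 <- structure(list(R = r2, conditions = "UC", modules = rownames(r2)),
                     class = "ms1_correlation_profile")
  expect_message(m <- select_marker_module(prof2, "UC"), "tie")
  expect_equal(m, "M1")

  r3 <- r[1, , drop = FALSE]
  prof3 <- structure(list(R = r3, conditions = "UC", modules = "M1"),
                     class = "ms1_correlation_profile")
  expect_equal(select_marker_module(prof3, "UC"), "M1")
  expect_error(select_marker_module(prof, "CD"), "not in profile")
})

test_that("the L1 path is all-zero at lambda_max and decreasing", {
  dat <- sim_marker_data(seed = 3)
  model <- fit_lasso_loocv(dat$x, dat$y, seed = 1)
  expect_true(all(diff(model$lambda_path) < 0))
  fit <- glmnet::glmnet(dat$x, dat$y, family = "binomial", alpha = 1,
                        lambda = model$lambda_path)
  expect_equal(sum(abs(fit$beta[, 1])), 0)  # all-zero at the top of the path
  # nonzero count is non-increasing in lambda near the top of the path
  nz <- colSums(as.matrix(fit$beta) != 0)
  expect_equal(nz[[1]], 0)
  expect_true(all(nz[1:20] <= max(nz)))
  # lambda.1se is at least the deviance-minimizing lambda
  expect_gte(model$lambda_1se, model$lambda_min)
})

test_that("a perfectly separating feature reaches LOOCV AUC 1", {
  dat <- sim_marker_data(n = 24, p = 4, effect = 30, seed = 5)
  model <- fit_lasso_loocv(dat$x, dat$y, seed = 1)
  expect_true(model$kept || length(model$nonzero_features) >= 1)
  auc <- loocv_auc(model, dat$x, dat$y)
  expect_equal(auc, 1.0)
})

test_that("duplicated informative features share shrunken weight", {
  dat_single <- sim_marker_data(n = 40, p = 9, effect = 3, seed = 7)
  dat_dup <- sim_marker_data(n = 40, p = 9, effect = 3, seed = 7,
                             duplicate_first = TRUE)
  m_single <- fit_lasso_loocv(dat_single$x, dat_single$y, seed = 1)
  m_dup <- fit_lasso_loocv(dat_dup$x, dat_dup$y, seed = 1)
  expect_true(m_dup$kept)
  b_single <- abs(m_single$coefficients["F1"])
  b_dup <- abs(m_dup$coefficients[c("F1", "F10")])
  expect_true(all(b_dup <= b_single + 1e-8))
})

test_that("a one-feature model is discarded with a log entry", {
  set.seed(1)
  n <- 30
  y <- rep(c(0L, 1L), each = n / 2)
  x <- cbind(F1 = rnorm(n) + 3 * y, F2 = rnorm(n))
  expect_message(model <- fit_lasso_loocv(x, y, seed = 1), "discarded")
  expect_false(model$kept)
  expect_true(is.na(model$loocv_auc))
})

test_that("LOOCV AUC is rank-based and honest under the null", {
  dat <- sim_marker_data(n = 20, p = 3, effect = 10, seed = 2)
  model <- fit_lasso_loocv(dat$x, dat$y, seed = 1)
  # monotone transform of probabilities leaves the rank statistic unchanged
  set.seed(3)
  score <- runif(20)
  y <- rbinom(20, 1, 0.5); y[1:2] <- c(0L, 1L)
  a1 <- ms1screen:::rank_auc(score, y)
  a2 <- ms1screen:::rank_auc(qlogis(score), y)
  expect_equal(a1, a2)

  expect_error(fit_lasso_loocv(dat$x, rep(1L, 20)), "classes")
})

test_that("fit_marker_model wires profile, modules and annotations", {
  set.seed(13)
  n_feat <- 30
  m <- matrix(rnorm(n_feat * 24, 20, 1), n_feat,
              dimnames = list(paste0("F", 1:n_feat), paste0("s", 1:24)))
  y <- rep(c(0, 1), each = 12)
  m[1:10, ] <- m[1:10, ] + 3 * rep(y, each = 10)  # module 1 carries signal
  feats <- make_features(2^m, rt = runif(n_feat, 60, 600),
                         mz = runif(n_feat, 300, 900))
  lg <- log2_transform(feats)
  design <- make_design(paste0("s", 1:24), ifelse(y == 1, "case", "ctrl"))
  labels <- setNames(rep(1:3, each = 10), rownames(m))
  eig <- compute_eigenfeatures(lg, labels)
  prof <- correlate_eigenfeatures(eig, design)
  model <- fit_marker_model(lg, labels, prof, design, "case", seed = 1)
  expect_equal(model$module_id, "M1")
  expect_true(model$kept)
  expect_gte(model$loocv_auc, 0.9)
  td <- tidy(model)
  expect_true(all(c("coefficient", "rt", "mz") %in% names(td)))
  expect_true(all(td$feature_id %in% paste0("F", 1:10)))
})
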