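test_that("PCA-guided component count reflects the data rank", {
  # exact rank 1
  u <- rnorm(50); v <- rnorm(8)
  m <- outer(u, v)
  dimnames(m) <- list(paste0("F", 1:50), paste0("s", 1:8))
  f1 <- as_feature_table(abs(m) + 10, NULL)  # positivity for the table check
  expect_equal(select_n_components(make_features(abs(m) + 10)), 1L)

  # 3 orthogonal zero-mean sample profiles, equal block variances
  set.seed(4)
  blocks <- qr.Q(qr(cbind(1, matrix(rnorm(18), 6))))[, 2:4]
  s_true <- matrix(0, 90, 3)
  for (b in 1:3) s_true[(b - 1) * 30 + 1:30, b] <- 1
  m3 <- s_true %*% t(blocks)
  ev <- eigen(crossprod(m3 - rowMeans(m3)), symmetric = TRUE)$values
  expect_equal(sum(ev > 1e-10 * ev[1]), 3L)  # oracle confirms rank 3
  feats3 <- make_features(m3 - min(m3) + 1)
  # equal variance shares (1/3 each): 99% needs all 3 components
  expect_equal(select_n_components(feats3, 0.99), 3L)

  # var_target 1 -> full numerical rank (capped at samples - 1)
  m4 <- random_intensities(40, 6, seed = 6)
  expect_equal(select_n_components(make_features(m4), 1.0), 5L)

  expect_error(select_n_components(make_features(matrix(5, 4, 4))), "constant")
})

test_that("a single ICA run is deterministic and recovers Laplace sources", {
  src <- simulate_sources(200, 40, 2, distribution = "laplace",
                          noise_sd = 0, seed = 14)
  r1 <- ica_single_run(src$x, 2, seed = 99)
  r2 <- ica_single_run(src$x, 2, seed = 99)
  expect_identical(r1$S, r2$S)

  # match recovered to true sources by maximum |r|
  cors <- abs(cor(r1$S, src$S))
  expect_true(all(apply(cors, 2, max) >= 0.95))

  # rank-1 signal, one component: collinear with the signal direction
  sig <- outer(rexp(150) - rexp(150), rnorm(12))
  dimnames(sig) <- list(paste0("F", 1:150), paste0("s", 1:12))
  r3 <- ica_single_run(sig, 1, seed = 3)
  true_dir <- sig[, 1] - mean(sig[, 1])
  expect_gte(abs(cor(r3$S[, 1], true_dir)), 0.999)
})

test_that("consensus extracts exactly the reproducible components", {
  src <- simulate_sources(250, 30, 3, distribution = "laplace",
                          noise_sd = 0, seed = 8)
  runs <- lapply(1:20, function(i) ica_single_run(src$x, 3, seed = 1000 + i))
  cons <- consensus_components(runs, src$x)
  expect_equal(cons$n_robust, 3L)
  expect_equal(cons$cluster_sizes, rep(20L, 3))
  cors <- abs(cor(cons$S, src$S))
  expect_true(all(apply(cors, 2, max) >= 0.99))

  # sign-flipped copies of one run collapse to that run's components
  base <- runs[[1]]
  flipped <- base
  flipped$S <- -base$S
  cons2 <- consensus_components(list(base, flipped, base), src$x)
  expect_equal(cons2$n_robust, 3L)
  cors2 <- abs(cor(cons2$S, base$S))
  expect_true(all(apply(cors2, 2, max) > 1 - 1e-12))

  # min_support = 1 drops components absent from even one run
  deviant <- base
  set.seed(1); deviant$S <- matrix(rnorm(250 * 3), 250)
  deviant$S <- sweep(deviant$S, 2, sqrt(colSums(deviant$S^2)), "/")
  expect_error(
    consensus_components(c(runs[1:19], list(deviant)), src$x, min_support = 1),
    "support"
  )
})

test_that("robust_ica is reproducible and permutation-stable", {
  src <- simulate_sources(150, 24, 3, distribution = "laplace",
                          noise_sd = 0.05, seed = 55)
  feats <- make_features(src$x - min(src$x) + 1)
  d1 <- robust_ica(feats, n_runs = 10, n_comp = 3, seed = 7)
  d2 <- robust_ica(feats, n_runs = 10, n_comp = 3, seed = 7)
  expect_identical(d1$S, d2$S)
  expect_identical(d1$A, d2$A)

  # permuting sample columns: same components up to order, permuted A
  perm <- c(5, 1, 24, 3:4, 2, 6:23)
  feats_p <- feats[, c("feature_id", sample_ids(feats)[perm])]
  d3 <- robust_ica(feats_p, n_runs = 10, n_comp = 3, seed = 7)
  expect_equal(d3$n_robust, d1$n_robust)
  cors <- abs(cor(d1$S, d3$S))
  expect_true(all(apply(cors, 2, max) > 0.99))
})

test_that("reconstruction error is bounded by the PCA truncation error", {
  src <- simulate_sources(200, 30, 3, distribution = "laplace",
                          noise_sd = 0.05, seed = 20)
  feats <- make_features(src$x - min(src$x) + 1)
  dec <- robust_ica(feats, n_runs = 10, n_comp = 3, seed = 2)
  m <- feature_matrix(feats)
  xc <- m - rowMeans(m)
  xc <- sweep(xc, 2, colMeans(xc))
  resid_ica <- sum((xc - dec$S %*% dec$A)^2)
  sv <- svd(xc)
  resid_pca <- sum(sv$d[-(1:3)]^2)
  expect_lte(resid_ica, resid_pca * 1.05)
})
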