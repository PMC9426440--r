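# Small fixtures built in code.

make_features <- function(m, rt = NULL, mz = NULL) {
  if (is.null(rownames(m))) rownames(m) <- paste0("F", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  ann <- tibble::tibble(feature_id = rownames(m))
  if (!is.null(rt)) ann$rt <- rt
  if (!is.null(mz)) ann$mz <- mz
  as_feature_table(m, ann)
}

make_design <- function(sample_ids, condition, ...) {
  tibble::tibble(sample_id = sample_ids, condition = condition, ...)
}

# Random positive intensity matrix.
random_intensities <- function(nf, ns, seed = 1, log_mean = 20, log_sd = 1.5) {
  set.seed(seed)
  m <- matrix(2^rnorm(nf * ns, log_mean, log_sd), nf, ns)
  rownames(m) <- paste0("F", seq_len(nf))
  colnames(m) <- paste0("s", seq_len(ns))
  m
}

# Independent median-of-ratios oracle: explicit loops, no shared code path.
oracle_median_ratio <- function(m) {
  ref <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) ref[i] <- prod(m[i, ])^(1 / ncol(m))
  out <- m
  for (j in seq_len(ncol(m))) {
    ratios <- numeric(nrow(m))
    for (i in seq_len(nrow(m))) ratios[i] <- m[i, j] / ref[i]
    out[, j] <- m[, j] / median(ratios)
  }
  out
}

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
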