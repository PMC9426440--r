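# Dendrogram comparison: cophenetic correlation between two condition trees
# over the same leaves, with significance from a leaf-label permutation test.

#' Cophenetic correlation between two trees
#'
#' Pearson correlation of the cophenetic distances over all leaf pairs,
#' aligned by leaf label. Accepts `condition_tree`, `hclust` or `phylo`
#' (e.g. read from Newick) inputs.
#'
#' @param tree1,tree2 Trees over identical leaf label sets.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
cophenetic_correlation <- function(tree1, tree2) {
  d1 <- cophenetic_matrix(tree1)
  d2 <- cophenetic_matrix(tree2)
  check_same_leaves(rownames(d1), rownames(d2))
  d2 <- d2[rownames(d1), rownames(d1)]
  v1 <- d1[lower.tri(d1)]
  v2 <- d2[lower.tri(d2)]
  if (sd(v1) == 0 || sd(v2) == 0) {
    abort("cophenetic distances are constant; correlation undefined.")
  }
  cor(v1, v2)
}

cophenetic_matrix <- function(tree) {
  if (inherits(tree, "ms1_condition_tree")) tree <- tree$hclust
  if (inherits(tree, "hclust")) {
    m <- as.matrix(cophenetic(tree))
  } else if (inherits(tree, "phylo")) {
    m <- ape::cophenetic.phylo(tree)
  } else {
    abort("trees must be condition_tree, hclust or phylo objects.")
  }
  m[order(rownames(m)), order(rownames(m))]
}

check_same_leaves <- function(a, b) {
  extra1 <- setdiff(a, b); extra2 <- setdiff(b, a)
  if (length(extra1) || length(extra2)) {
    abort(paste0("leaf label sets differ. Only in tree1: ",
                 paste(extra1, collapse = ", "), "; only in tree2: ",
                 paste(extra2, collapse = ", ")))
  }
}

#' Permutation test for cophenetic correlation
#'
#' Shuffles the leaf labels of `tree2` uniformly `n_perm` times, recomputes
#' the cophenetic correlation, and counts permutations with
#' `|r_perm| >= |r_obs|`. The reported p-value uses the add-one correction
#' `p = (count + 1) / (n_perm + 1)`, so it is never exactly zero.
#'
#' @inheritParams cophenetic_correlation
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Integer seed.
#' @return An `ms1_tree_comparison`: `r_cophenetic`, `n_perm`, `count_ge`,
#'   `p_value`, `seed`.
#' @export
permutation_pvalue <- function(tree1, tree2, n_perm = 10000, seed = 1) {
  if (n_perm < 1) abort("`n_perm` must be >= 1.")
  d1 <- cophenetic_matrix(tree1)
  d2 <- cophenetic_matrix(tree2)
  check_same_leaves(rownames(d1), rownames(d2))
  if (nrow(d1) < 4) abort("need at least 4 leaves.")
  d2 <- d2[rownames(d1), rownames(d1)]
  lt <- lower.tri(d1)
  v1 <- d1[lt]
  # degenerate trees (all cophenetic distances equal) carry no linear
  # association: their correlation is taken as 0, making the test trivially
  # non-significant (p = 1)
  safe_cor <- function(a, b) if (sd(a) == 0 || sd(b) == 0) 0 else cor(a, b)
  r_obs <- safe_cor(v1, d2[lt])

  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- nrow(d1)
  count <- 0L
  for (i in seq_len(n_perm)) {
    p <- sample.int(n)
    r_perm <- safe_cor(v1, d2[p, p][lt])
    if (abs(r_perm) >= abs(r_obs) - 1e-15) count <- count + 1L
  }
  structure(list(
    r_cophenetic = r_obs, n_perm = as.integer(n_perm), count_ge = count,
    p_value = (count + 1) / (n_perm + 1), seed = as.integer(seed)
  ), class = "ms1_tree_comparison")
}

#' @export
print.ms1_tree_comparison <- function(x, ...) {
  cat("Cophenetic tree comparison\n")
  cat(sprintf("  r = %.4f; permutation p = %.4g (%d of %d permutations >= |r|)\n",
              x$r_cophenetic, x$p_value, x$count_ge, x$n_perm))
  invisible(x)
}
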