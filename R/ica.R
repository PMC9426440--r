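# Consensus ICA: the log2 matrix X (features x samples) is row-centered and
# decomposed as X ~ S %*% A with statistically independent columns of S
# (feature loadings) and mixing activities A (components x samples). ICA is
# run many times from random initializations; components that recur across
# runs are clustered and replaced by their centroids ("robust" components).

#' PCA-guided component count
#'
#' The smallest number of principal components whose cumulative explained
#' variance (of the feature-centered matrix) reaches `var_target`, capped at
#' `min(n_features, n_samples - 1)`. This sets the dimensionality for the
#' ICA runs.
#'
#' @inheritParams sample_ids
#' @param var_target Target cumulative explained-variance fraction
#'   (default 0.99).
#' @return Integer component count.
#' @export
select_n_components <- function(features, var_target = 0.99) {
  m <- feature_matrix(features)
  if (ncol(m) < 2) abort("need at least 2 samples.")
  xc <- m - rowMeans(m)
  d <- svd(xc, nu = 0, nv = 0)$d
  ev <- d^2
  if (sum(ev) <= 0) abort("constant matrix: no variance to decompose.")
  cum <- cumsum(ev) / sum(ev)
  cap <- min(nrow(m), ncol(m) - 1L)
  n <- which(cum >= var_target - 1e-12)[1]
  if (is.na(n)) n <- length(ev)
  as.integer(min(n, cap))
}

#' One fixed-point ICA run
#'
#' FastICA with the logcosh contrast and symmetric decorrelation on the
#' whitened, feature-centered matrix. Deterministic for a given seed (the
#' seed draws the initial unmixing matrix). A run that cannot reach `tol`
#' within `max_iter` iterations — or whose rotation magnitude stops
#' improving for 100 consecutive iterations, the signature of near-Gaussian
#' dimensions whose fixed point is weaker than its estimation noise — is
#' returned with `converged = FALSE`.
#'
#' @param x Numeric features x samples matrix (will be row-centered).
#' @param n_comp Number of components to extract.
#' @param seed Integer seed for the random initialization.
#' @param tol Fixed-point convergence tolerance (default 1e-6).
#' @param max_iter Iteration cap per run (default 1000).
#' @return List with `S` (features x n_comp, unit-norm columns), `A`
#'   (n_comp x samples), `converged`, and the iteration count.
#' @export
ica_single_run <- function(x, n_comp, seed, tol = 1e-6, max_iter = 1000) {
  stopifnot(is.matrix(x), n_comp >= 1)
  wh <- whiten_features(x, n_comp)
  ica_run_whitened(wh, n_comp, seed, tol, max_iter)
}

# Shared whitening: row-center (per feature), then remove the column means
# over features so the whitened signals have zero mean along the feature
# index the fixed-point expectations run over.
whiten_features <- function(x, n_comp) {
  xc <- x - rowMeans(x)
  xc <- sweep(xc, 2L, colMeans(xc), "-")
  nf <- nrow(xc)
  sv <- svd(xc, nu = 0, nv = n_comp)
  if (length(sv$d) < n_comp || sv$d[n_comp] < 1e-12 * sv$d[1]) {
    abort("requested more components than the numerical rank supports.")
  }
  z <- t(xc %*% sv$v)
  z <- z / (sv$d[seq_len(n_comp)] / sqrt(nf))
  list(z = z, xc = xc)
}

ica_run_whitened <- function(wh, n_comp, seed, tol, max_iter) {
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  w0 <- matrix(rnorm(n_comp * n_comp), n_comp)
  core <- .fastica_core(wh$z, w0, tol, as.integer(max_iter), 100L)
  s_hat <- t(core$W %*% wh$z)
  s_hat <- sweep(s_hat, 2L, sqrt(colSums(s_hat^2)), "/")
  a_hat <- ls_solve(s_hat, wh$xc)
  list(S = s_hat, A = a_hat, converged = core$converged,
       iters = core$iters, seed = as.integer(seed))
}

# Minimum-norm least squares via SVD pseudoinverse; tolerant of (near-)
# collinear consensus centroids.
ls_solve <- function(s, x) {
  sv <- svd(s)
  keep <- sv$d > max(sv$d) * 1e-10
  v <- sv$v[, keep, drop = FALSE]
  u <- sv$u[, keep, drop = FALSE]
  v %*% ((t(u) %*% x) / sv$d[keep])
}

get_rng_state <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Consensus (robust) components from repeated ICA runs
#'
#' Pools the components of all converged runs, groups them by single-linkage
#' clustering of the distance 1 - |Pearson r| between loading vectors at
#' `link_threshold`, keeps groups supported by at least `min_support` of the
#' runs, sign-aligns each group's members to the member closest to the group
#' mean, and returns the renormalized element-wise means as the robust
#' loadings. Activities are recomputed by least squares against the centered
#' data.
#'
#' @param runs List of run results from [ica_single_run()].
#' @param x The features x samples matrix the runs decomposed.
#' @param min_support Minimum fraction of runs a group must draw components
#'   from (default 0.5).
#' @param link_threshold Single-linkage cut height on 1 - |r| (default 0.1).
#' @return An object of class `ms1_decomposition`.
#' @export
consensus_components <- function(runs, x, min_support = 0.5,
                                 link_threshold = 0.1) {
  conv <- Filter(function(r) isTRUE(r$converged), runs)
  if (length(conv) >= 2) {
    runs <- conv
  } else if (length(runs) >= 2) {
    # In the near-Gaussian regime no run reaches the fixed-point tolerance,
    # but strongly non-Gaussian source directions still lock in early; the
    # consensus clustering itself filters for reproducibility, so all
    # completed runs are pooled.
    inform(paste0("fewer than 2 of ", length(runs), " runs converged; ",
                  "pooling all runs and relying on consensus filtering."))
  } else {
    abort("need at least 2 completed runs for consensus.")
  }
  n_runs <- length(runs)
  pool <- do.call(cbind, lapply(runs, `[[`, "S"))
  run_of <- rep(seq_along(runs), vapply(runs, function(r) ncol(r$S), integer(1)))

  r <- fast_cor(pool)
  d <- 1 - abs(r)
  d[d < 0] <- 0
  hc <- hclust(as.dist(d), method = "single")
  grp <- cutree(hc, h = link_threshold)

  xc <- x - rowMeans(x)
  cents <- list(); sizes <- integer(0)
  for (g in sort(unique(grp))) {
    idx <- which(grp == g)
    support <- length(unique(run_of[idx])) / n_runs
    if (support < min_support) next
    mem <- pool[, idx, drop = FALSE]
    # sign-align to the member closest to the (sign-resolved) group mean
    sgn <- sign(fast_cor(mem[, 1, drop = FALSE], mem))
    sgn[sgn == 0] <- 1
    mem <- sweep(mem, 2L, as.numeric(sgn), "*")
    mu <- rowMeans(mem)
    anchor <- which.max(abs(crossprod(mem, mu)))
    sgn2 <- sign(crossprod(mem, mem[, anchor]))
    sgn2[sgn2 == 0] <- 1
    mem <- sweep(mem, 2L, as.numeric(sgn2), "*")
    cent <- rowMeans(mem)
    cent <- cent / sqrt(sum(cent^2))
    cents[[length(cents) + 1L]] <- cent
    sizes <- c(sizes, length(idx))
  }
  if (length(cents) == 0) {
    abort("no component group met the support threshold; try fewer components.")
  }
  s_rob <- do.call(cbind, cents)
  a_rob <- ls_solve(s_rob, xc)
  ord <- order(apply(a_rob, 1, var), decreasing = TRUE)
  s_rob <- s_rob[, ord, drop = FALSE]
  a_rob <- a_rob[ord, , drop = FALSE]
  colnames(s_rob) <- rownames(a_rob) <- paste0("IC", seq_len(ncol(s_rob)))
  rownames(s_rob) <- rownames(x)
  colnames(a_rob) <- colnames(x)

  structure(list(
    S = s_rob, A = a_rob,
    n_requested = ncol(runs[[1]]$S),
    n_robust = ncol(s_rob),
    n_runs = n_runs,
    run_seeds = vapply(runs, `[[`, integer(1), "seed"),
    cluster_sizes = sizes[ord]
  ), class = "ms1_decomposition")
}

#' Robust consensus ICA of a log2 feature table
#'
#' Chooses the component count by [select_n_components()] (unless given),
#' repeats [ica_single_run()] `n_runs` times with seeds derived from
#' `seed`, and extracts consensus components with
#' [consensus_components()].
#'
#' @inheritParams sample_ids
#' @inheritParams consensus_components
#' @param n_runs Number of repeated ICA runs (default 100).
#' @param n_comp Component count; `NULL` (default) = PCA-guided choice.
#' @param var_target See [select_n_components()].
#' @param tol,max_iter Per-run fixed-point settings.
#' @param seed Master seed; per-run seeds are derived deterministically.
#' @return An `ms1_decomposition`: robust loadings `S` (unit-norm columns),
#'   activities `A`, run provenance and per-component run support.
#' @export
robust_ica <- function(features, n_runs = 100, n_comp = NULL,
                       var_target = 0.99, tol = 1e-6, max_iter = 1000,
                       min_support = 0.5, link_threshold = 0.1, seed = 1) {
  m <- feature_matrix(features)
  if (is.null(n_comp)) n_comp <- select_n_components(features, var_target)
  wh <- whiten_features(m, n_comp)
  runs <- lapply(seq_len(n_runs), function(i) {
    ica_run_whitened(wh, n_comp, seed = derive_seed(seed, i), tol = tol,
                     max_iter = max_iter)
  })
  n_fail <- sum(!vapply(runs, `[[`, logical(1), "converged"))
  if (n_fail > 0) {
    inform(paste0(n_fail, " of ", n_runs,
                  " ICA runs did not converge and were excluded."))
  }
  res <- consensus_components(runs, m, min_support = min_support,
                              link_threshold = link_threshold)
  res$n_runs_used <- res$n_runs
  res$n_runs <- n_runs
  res$var_target <- var_target
  res$master_seed <- as.integer(seed)
  res
}

#' @export
print.ms1_decomposition <- function(x, ...) {
  cat("Robust ICA decomposition\n")
  cat("  features:", nrow(x$S), " samples:", ncol(x$A), "\n")
  cat("  components:", x$n_robust, "robust of", x$n_requested,
      "requested over", x$n_runs, "runs\n")
  cat("  run support per component:",
      paste(x$cluster_sizes, collapse = " "), "\n")
  invisible(x)
}
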