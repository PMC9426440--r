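# Feature-module detection: rows of the robust loading matrix S are
# clustered with k-medoids under correlation distance; the cluster count is
# chosen by the maximum mean silhouette over a scanned k range.

#' Correlation distance between feature loading rows
#'
#' @param s Numeric matrix (features x components); rows must be
#'   non-constant.
#' @return Symmetric matrix of d(i, j) = 1 - Pearson r(row i, row j)
#'   (zero diagonal, range \[0, 2\]).
#' @export
correlation_distance_matrix <- function(s) {
  stopifnot(is.matrix(s))
  if (ncol(s) < 2) abort("need at least 2 components per feature row.")
  rv <- apply(s, 1, sd)
  if (any(rv == 0)) {
    abort(paste0("constant loading row(s): ",
                 paste(head(rownames(s)[rv == 0], 5), collapse = ", ")))
  }
  d <- 1 - fast_cor(t(s))
  d[d < 0] <- 0
  d[d > 2] <- 2
  diag(d) <- 0
  d
}

#' k-medoid clustering of a distance matrix
#'
#' k-medoids++ seeding (first medoid uniform; subsequent medoids drawn with
#' probability proportional to squared distance to the nearest chosen
#' medoid) followed by alternation: assign each point to its nearest medoid,
#' then move each medoid to the member minimizing the within-module total
#' distance, until no move lowers the cost. Deterministic given `seed`.
#'
#' @param d Symmetric distance matrix.
#' @param k Number of modules, `2 <= k < n`.
#' @param seed Integer seed (controls seeding only).
#' @return List with `labels` (integers 1..k), `medoids` (row indices) and
#'   `cost` (sum of distances to own medoid).
#' @export
kmedoids_cluster <- function(d, k, seed = 1) {
  n <- nrow(d)
  if (k < 2 || k >= n) abort("`k` must satisfy 2 <= k < n.")
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  medoids <- kmedoidspp_seed(d, k)
  cost <- Inf
  repeat {
    labels <- max.col(-d[, medoids, drop = FALSE], ties.method = "first")
    new_medoids <- medoids
    for (c in seq_len(k)) {
      idx <- which(labels == c)
      if (length(idx) == 0) { new_medoids[c] <- medoids[c]; next }
      within <- colSums(d[idx, idx, drop = FALSE])
      new_medoids[c] <- idx[which.min(within)]
    }
    new_cost <- sum(d[cbind(seq_len(n), new_medoids[labels])])
    if (new_cost < cost - 1e-12) {
      medoids <- new_medoids
      cost <- new_cost
    } else break
  }
  labels <- max.col(-d[, medoids, drop = FALSE], ties.method = "first")
  cost <- sum(d[cbind(seq_len(n), medoids[labels])])
  list(labels = labels, medoids = medoids, cost = cost)
}

kmedoidspp_seed <- function(d, k) {
  n <- nrow(d)
  medoids <- integer(k)
  medoids[1] <- sample.int(n, 1)
  if (k > 1) {
    nearest <- d[, medoids[1]]
    for (i in 2:k) {
      w <- nearest^2
      if (sum(w) <= 0) w <- rep(1, n)
      medoids[i] <- sample.int(n, 1, prob = w)
      nearest <- pmin(nearest, d[, medoids[i]])
    }
  }
  medoids
}

#' Mean silhouette width of a flat clustering
#'
#' Computed directly from the supplied distance matrix. Points in singleton
#' clusters contribute silhouette 0 (the usual convention).
#'
#' @param d Symmetric distance matrix.
#' @param labels Integer cluster labels.
#' @return Mean silhouette width in \[-1, 1\].
#' @export
mean_silhouette <- function(d, labels) {
  n <- nrow(d)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) abort("silhouette needs at least 2 clusters.")
  ind <- matrix(0, n, k)
  ind[cbind(seq_len(n), labels)] <- 1
  sums <- d %*% ind                       # point x cluster total distance
  sizes <- colSums(ind)
  own_size <- sizes[labels]
  a <- ifelse(own_size > 1,
              sums[cbind(seq_len(n), labels)] / (own_size - 1), 0)
  means <- sweep(sums, 2L, sizes, "/")
  means[cbind(seq_len(n), labels)] <- Inf
  b <- apply(means, 1, min)
  s <- ifelse(own_size > 1, (b - a) / pmax(a, b), 0)
  mean(s)
}

#' Choose the module count by maximum silhouette
#'
#' Runs [kmedoids_cluster()] for every k in `k_range` and keeps the k with
#' the highest mean silhouette (ties broken toward the smallest k).
#'
#' @inheritParams kmedoids_cluster
#' @param k_range Integer vector of candidate k values (default `10:50`).
#' @param restarts Seeded restarts per k; the lowest-cost solution wins
#'   (default 1).
#' @return An object of class `ms1_feature_clustering` with fields `labels`,
#'   `medoids`, `chosen_k`, `cost`, `silhouette_by_k` (tibble `k`,
#'   `silhouette`) and `feature_ids`.
#' @export
select_k <- function(d, k_range = 10:50, seed = 1, restarts = 1) {
  if (length(k_range) == 0) abort("`k_range` is empty.")
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) >= nrow(d)) abort("max(k_range) must be < number of rows.")
  fits <- vector("list", length(k_range))
  sil <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    best <- NULL
    for (r in seq_len(restarts)) {
      fit <- kmedoids_cluster(d, k_range[i],
                              seed = derive_seed(seed, i * 1000L + r))
      if (is.null(best) || fit$cost < best$cost) best <- fit
    }
    fits[[i]] <- best
    sil[i] <- mean_silhouette(d, best$labels)
  }
  pick <- which.max(sil)  # which.max takes the first (smallest k) on ties
  structure(list(
    labels = fits[[pick]]$labels,
    medoids = fits[[pick]]$medoids,
    chosen_k = k_range[pick],
    cost = fits[[pick]]$cost,
    silhouette_by_k = tibble::tibble(k = k_range, silhouette = sil),
    feature_ids = rownames(d)
  ), class = "ms1_feature_clustering")
}

#' Cluster features from a robust ICA decomposition
#'
#' Convenience wrapper: builds the correlation distance over the rows of the
#' robust loading matrix and selects k by silhouette.
#'
#' @param decomposition An `ms1_decomposition` from [robust_ica()], or a
#'   plain loadings matrix (features x components).
#' @inheritParams select_k
#' @return An `ms1_feature_clustering`; `tidy()` gives per-feature module
#'   assignments.
#' @export
cluster_features <- function(decomposition, k_range = 10:50, seed = 1,
                             restarts = 1) {
  s <- if (inherits(decomposition, "ms1_decomposition")) decomposition$S
       else decomposition
  d <- correlation_distance_matrix(s)
  rownames(d) <- colnames(d) <- rownames(s)
  select_k(d, k_range = k_range, seed = seed, restarts = restarts)
}

#' @export
print.ms1_feature_clustering <- function(x, ...) {
  cat("k-medoid feature modules\n")
  cat("  features:", length(x$labels), "\n")
  cat("  chosen k:", x$chosen_k, "(mean silhouette",
      sprintf("%.3f", max(x$silhouette_by_k$silhouette)), ")\n")
  cat("  module sizes:", paste(tabulate(x$labels), collapse = " "), "\n")
  invisible(x)
}
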