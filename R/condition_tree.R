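# Condition clustering: the module x condition correlation profile is turned
# into a condition distance (1 - Pearson r of profile columns), clustered by
# average linkage, cut by silhouette, and every node gets multiscale
# bootstrap support (BP = plain bootstrap proportion; AU = approximately
# unbiased probability from the multiscale extrapolation).

#' Condition distance from a correlation profile
#'
#' @param profile An `ms1_correlation_profile` (or a modules x conditions
#'   matrix).
#' @return Symmetric condition distance matrix, d = 1 - Pearson r between
#'   profile columns.
#' @export
condition_distance <- function(profile) {
  r <- profile_matrix(profile)
  if (nrow(r) < 2) abort("need at least 2 modules (rows).")
  d <- 1 - fast_cor(r)
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

profile_matrix <- function(profile) {
  if (inherits(profile, "ms1_correlation_profile")) profile$R
  else as.matrix(profile)
}

#' Average-linkage condition tree
#'
#' UPGMA agglomeration of the condition distance: each merge height is the
#' mean pairwise distance between the two merged groups.
#'
#' @param d Symmetric condition distance matrix with dimnames.
#' @return An `hclust` object.
#' @export
average_linkage_tree <- function(d) {
  if (nrow(d) < 2) abort("need at least 2 conditions.")
  hclust(as.dist(d), method = "average")
}

#' Cut a tree into the silhouette-best number of flat groups
#'
#' @param hc An `hclust` over conditions.
#' @param d The distance matrix the tree was built from.
#' @param k_range Candidate group counts (default `2:(n - 1)`).
#' @return List with `labels` (named integer vector), `chosen_k` and
#'   `silhouette_by_k`.
#' @export
cut_by_silhouette <- function(hc, d, k_range = NULL) {
  n <- length(hc$labels %||% hc$order)
  if (n == 2) {
    inform("only 2 leaves: forced cut into 2 groups, silhouette skipped.")
    labels <- setNames(1:2, hc$labels)
    return(list(labels = labels, chosen_k = 2L,
                silhouette_by_k = tibble::tibble(k = 2L, silhouette = NA_real_)))
  }
  if (is.null(k_range)) k_range <- 2:(n - 1)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2 | k_range > n)) abort("k_range must lie in [2, n].")
  sil <- vapply(k_range, function(k) {
    if (k == n) return(NA_real_)
    mean_silhouette(d, cutree(hc, k = k))
  }, numeric(1))
  pick <- which.max(sil)
  list(labels = cutree(hc, k = k_range[pick]), chosen_k = k_range[pick],
       silhouette_by_k = tibble::tibble(k = k_range, silhouette = sil))
}

# Leaf sets below each internal node, as canonical keys.
node_leafsets <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    kids <- hc$merge[i, ]
    get1 <- function(k) if (k < 0) hc$labels[-k] else sets[[k]]
    sets[[i]] <- sort(c(get1(kids[1]), get1(kids[2])))
  }
  vapply(sets, paste, character(1), collapse = "\r")
}

#' Multiscale bootstrap support (AU/BP) for condition-tree nodes
#'
#' Module rows of the correlation profile are resampled with replacement at
#' several relative sizes (`scales`); for each scale the condition tree is
#' rebuilt and, per observed node, the fraction of resampled trees containing
#' the same leaf set is recorded. BP is that fraction at scale 1. AU comes
#' from the multiscale fit: z(r) = qnorm(1 - BP(r)) is regressed on
#' \{sqrt(r), 1/sqrt(r)\} by weighted least squares giving (v, c), and
#' AU = 1 - pnorm(v - c). Nodes whose BP is degenerate (0 or 1) at all, or
#' all but one, scale cannot support the fit and get AU clamped to 0 or 1;
#' a mixed node with fewer than two usable scales yields `NA`.
#'
#' @param profile An `ms1_correlation_profile` (>= 4 module rows).
#' @param hc The observed condition `hclust` (rebuilt from `profile` when
#'   omitted).
#' @param n_boot Bootstrap resamples per scale (default 1000).
#' @param scales Relative resample sizes (default `seq(0.5, 1.4, by = 0.1)`).
#' @param seed Integer seed.
#' @return Tibble with one row per internal node: `node`, `leaves`, `bp`,
#'   `au`.
#' @export
au_bootstrap <- function(profile, hc = NULL, n_boot = 1000,
                         scales = seq(0.5, 1.4, by = 0.1), seed = 1) {
  r <- profile_matrix(profile)
  m <- nrow(r)
  if (m < 4) abort("need at least 4 module rows to resample.")
  scales <- round(sort(unique(c(scales, 1))), 10)
  if (is.null(hc)) hc <- average_linkage_tree(condition_distance(r))
  obs_sets <- node_leafsets(hc)
  n_nodes <- length(obs_sets)

  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  counts <- matrix(0L, n_nodes, length(scales))
  for (si in seq_along(scales)) {
    set.seed(derive_seed(seed, si))
    msub <- max(2L, as.integer(ceiling(scales[si] * m)))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(m, msub, replace = TRUE)
      db <- boot_condition_distance(r[idx, , drop = FALSE])
      hb <- hclust(as.dist(db), method = "average")
      counts[, si] <- counts[, si] +
        (obs_sets %in% node_leafsets(hb))
    }
  }
  bp_mat <- counts / n_boot
  bp1 <- bp_mat[, which(scales == 1)]

  au <- vapply(seq_len(n_nodes), function(i) {
    bp <- bp_mat[i, ]
    if (all(bp == 1)) return(1)
    if (all(bp == 0)) return(0)
    use <- bp > 0 & bp < 1
    if (sum(use) < 2) {
      # nearly degenerate: informative at under two scales; clamp like the
      # fully degenerate case when all proportions sit on one side
      if (all(bp >= 0.5)) return(1)
      if (all(bp <= 0.5)) return(0)
      inform(paste0("node ", i, ": too few informative scales, AU unavailable."))
      return(NA_real_)
    }
    z <- qnorm(1 - bp[use])
    x <- cbind(sqrt(scales[use]), 1 / sqrt(scales[use]))
    w <- n_boot * stats::dnorm(z)^2 / (bp[use] * (1 - bp[use]))
    fit <- tryCatch(stats::lm.wfit(x, z, w), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) {
      inform(paste0("node ", i, ": singular multiscale fit, AU unavailable."))
      return(NA_real_)
    }
    vc <- fit$coefficients
    min(1, max(0, 1 - pnorm(vc[1] - vc[2])))
  }, numeric(1))

  tibble::tibble(
    node = seq_len(n_nodes),
    leaves = gsub("\r", ",", obs_sets),
    bp = bp1,
    au = au
  )
}

# Resampled profiles can produce constant condition columns; their
# correlations are undefined and are set to 0 (distance 1) so the
# agglomeration can proceed.
boot_condition_distance <- function(rb) {
  cs <- sweep(rb, 2L, colMeans(rb), "-")
  s <- sqrt(colMeans(cs^2))
  ok <- s > 0
  cs[, ok] <- sweep(cs[, ok, drop = FALSE], 2L, s[ok], "/")
  cc <- crossprod(cs) / nrow(cs)
  cc[!ok, ] <- 0; cc[, !ok] <- 0
  d <- 1 - cc
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Cluster conditions from a correlation profile
#'
#' Builds the condition distance, the average-linkage tree, the
#' silhouette-chosen flat cut, and per-node AU/BP bootstrap support.
#'
#' @inheritParams au_bootstrap
#' @param k_range Candidate flat-cut sizes (default `2:(n - 1)` conditions).
#' @return An `ms1_condition_tree`: `hclust`, `distance`, `cut_labels`,
#'   `chosen_k`, `silhouette_by_k`, `support` (AU/BP tibble), `seed`.
#' @export
condition_tree <- function(profile, k_range = NULL, n_boot = 1000,
                           scales = seq(0.5, 1.4, by = 0.1), seed = 1) {
  d <- condition_distance(profile)
  hc <- average_linkage_tree(d)
  cut <- cut_by_silhouette(hc, d, k_range)
  if (nrow(profile_matrix(profile)) >= 4) {
    support <- au_bootstrap(profile, hc, n_boot = n_boot, scales = scales,
                            seed = seed)
  } else {
    inform("fewer than 4 modules: bootstrap support unavailable.")
    sets <- node_leafsets(hc)
    support <- tibble::tibble(node = seq_along(sets),
                              leaves = gsub("\r", ",", sets),
                              bp = NA_real_, au = NA_real_)
  }
  structure(list(
    hclust = hc, distance = d,
    cut_labels = cut$labels, chosen_k = cut$chosen_k,
    silhouette_by_k = cut$silhouette_by_k,
    support = support, n_boot = n_boot, seed = as.integer(seed)
  ), class = "ms1_condition_tree")
}

#' @export
print.ms1_condition_tree <- function(x, ...) {
  cat("Condition tree over", length(x$hclust$labels), "conditions\n")
  cat("  silhouette-chosen cut: k =", x$chosen_k, "\n")
  n_sig <- sum(x$support$au > 0.9, na.rm = TRUE)
  cat("  nodes with AU > 0.9:", n_sig, "of", nrow(x$support), "\n")
  invisible(x)
}
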