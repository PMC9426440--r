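# Eigenfeature summary: each feature module is reduced to one per-sample
# vector, the first right-singular direction of the module's standardized
# log2 sub-matrix (the eigengene construction applied to MS1 features).

#' Eigenfeatures of feature modules
#'
#' For every module: feature rows are standardized (centered, unit
#' variance), the sub-matrix is decomposed by SVD, and the first right
#' singular vector over samples becomes the module eigenfeature. Its sign is
#' fixed so that it correlates non-negatively with the module's mean
#' standardized profile; explained variance is the first squared singular
#' value over the total.
#'
#' @inheritParams sample_ids
#' @param clustering An `ms1_feature_clustering` (or an integer vector of
#'   module labels named by feature_id).
#' @return An `ms1_eigenfeatures` object: `E` (modules x samples, unit-norm
#'   rows), `explained_variance`, `module_sizes`, and `sign_anchor` (per
#'   module, whether the eigenfeature is aligned non-negatively with the
#'   mean standardized profile — always true by construction).
#' @export
compute_eigenfeatures <- function(features, clustering) {
  m <- feature_matrix(features)
  if (ncol(m) < 3) abort("need at least 3 samples.")
  labels <- clustering_labels(clustering, rownames(m))
  mods <- sort(unique(labels))
  e <- matrix(NA_real_, length(mods), ncol(m),
              dimnames = list(paste0("M", mods), colnames(m)))
  ev <- numeric(length(mods))
  sizes <- integer(length(mods))
  anchor <- logical(length(mods))
  for (i in seq_along(mods)) {
    xm <- m[labels == mods[i], , drop = FALSE]
    sizes[i] <- nrow(xm)
    mu <- rowMeans(xm)
    s <- apply(xm, 1, sd)
    if (any(s == 0)) {
      abort(paste0("zero-variance feature row in module ", mods[i]))
    }
    z <- (xm - mu) / s
    sv <- svd(z)
    vec <- sv$v[, 1]
    if (sum(vec * colMeans(z)) < 0) vec <- -vec
    e[i, ] <- vec
    ev[i] <- sv$d[1]^2 / sum(sv$d^2)
    anchor[i] <- sum(vec * colMeans(z)) >= 0
  }
  structure(list(E = e, explained_variance = setNames(ev, rownames(e)),
                 module_sizes = setNames(sizes, rownames(e)),
                 sign_anchor = setNames(anchor, rownames(e)),
                 module_ids = mods),
            class = "ms1_eigenfeatures")
}

clustering_labels <- function(clustering, feature_ids) {
  if (inherits(clustering, "ms1_feature_clustering")) {
    labels <- setNames(clustering$labels, clustering$feature_ids)
  } else labels <- clustering
  if (is.null(names(labels))) {
    if (length(labels) != length(feature_ids)) {
      abort("unnamed labels must match the feature table rows.")
    }
    names(labels) <- feature_ids
  }
  missing <- setdiff(feature_ids, names(labels))
  if (length(missing)) {
    abort(paste0("features without module label: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  labels[feature_ids]
}

#' One-hot condition indicator matrix
#'
#' @param design Design tibble with `sample_id` and `condition`.
#' @return Binary matrix (conditions x samples); rows are condition levels in
#'   order of first appearance, columns follow the design.
#' @export
condition_indicators <- function(design) {
  check_design(design)
  lev <- condition_levels(design)
  if (length(lev) < 2) abort("need at least 2 conditions.")
  ind <- outer(lev, as.character(design$condition), "==") * 1
  dimnames(ind) <- list(lev, design$sample_id)
  if (any(rowSums(ind) == ncol(ind))) {
    abort("a condition covering all samples has an undefined correlation.")
  }
  ind
}

#' Correlate eigenfeatures with condition indicators
#'
#' Pearson correlation of each module eigenfeature with each one-hot
#' condition indicator, over matched samples.
#'
#' @param eig An `ms1_eigenfeatures` object.
#' @param design Design tibble covering every sample in `eig`.
#' @return An `ms1_correlation_profile`: matrix `R` (modules x conditions)
#'   plus condition order.
#' @export
correlate_eigenfeatures <- function(eig, design) {
  check_design(design)
  ind <- condition_indicators(design)
  samples <- colnames(eig$E)
  missing <- setdiff(samples, colnames(ind))
  if (length(missing)) {
    abort(paste0("design misses sample(s): ", paste(missing, collapse = ", ")))
  }
  ind <- ind[, samples, drop = FALSE]
  r <- fast_cor(t(eig$E), t(ind))
  structure(list(R = r, conditions = rownames(ind),
                 modules = rownames(eig$E)),
            class = "ms1_correlation_profile")
}

#' @export
print.ms1_eigenfeatures <- function(x, ...) {
  cat("Eigenfeature set:", nrow(x$E), "modules x", ncol(x$E), "samples\n")
  cat("  explained variance:",
      paste(sprintf("%.2f", x$explained_variance), collapse = " "), "\n")
  invisible(x)
}

#' @export
print.ms1_correlation_profile <- function(x, ...) {
  cat("Module x condition correlation profile (",
      nrow(x$R), " modules, ", ncol(x$R), " conditions)\n", sep = "")
  print(round(x$R, 3))
  invisible(x)
}
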