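#' Intensity quartiles over observed values
#'
#' Quartile thresholds are computed on the raw intensity scale over all
#' observed (non-`NA`) entries of the table, using linear-interpolation
#' quantiles ([stats::quantile()] type 7). The first quartile is the default
#' missingness threshold of the screen: values below it are treated as
#' missing for prevalence filtering (but are kept for analysis if the
#' feature survives). The second and third quartiles reproduce the harsher
#' "high plus medium" and "high"-only censoring schemes.
#'
#' @inheritParams sample_ids
#' @return One-row tibble with `q1`, `q2`, `q3`.
#' @export
compute_quartiles <- function(features) {
  m <- feature_matrix(features)
  v <- m[!is.na(m)]
  if (length(v) < 4) abort("need at least 4 observed intensities.")
  q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
  tibble::tibble(q1 = q[1], q2 = q[2], q3 = q[3])
}

#' Missingness mask for filtering or imputation
#'
#' Two distinct notions of "missing" are used in the screen. For prevalence
#' *filtering*, absent entries and observed entries below an intensity
#' threshold both count as missing (`mode = "filtering"`). For *imputation*
#' only truly absent entries are missing (`mode = "strict"`): sub-threshold
#' observed values are retained as data.
#'
#' @inheritParams sample_ids
#' @param threshold Intensity threshold on the raw scale (ignored in strict
#'   mode). Typically `compute_quartiles(features)$q1`.
#' @param mode `"filtering"` or `"strict"`.
#' @return Tibble with `feature_id` and one logical column per sample
#'   (`TRUE` = treated as missing).
#' @export
build_missing_mask <- function(features, threshold = 0,
                               mode = c("filtering", "strict")) {
  mode <- match.arg(mode)
  if (threshold < 0) abort("`threshold` must be non-negative.")
  m <- feature_matrix(features)
  mask <- is.na(m)
  if (mode == "filtering") mask <- mask | (!is.na(m) & m < threshold)
  dplyr::bind_cols(tibble::tibble(feature_id = rownames(m)),
                   tibble::as_tibble(mask, .name_repair = "minimal"))
}

#' Per-condition prevalence filter
#'
#' A feature is retained only if, in *every* condition group, it is
#' non-missing (per `mask`) in at least `min_frac` of that group's samples.
#' Retained features keep all their observed values, including sub-threshold
#' ones: the mask governs filtering only, not the retained data.
#'
#' @inheritParams sample_ids
#' @param mask Output of [build_missing_mask()] (filtering mode).
#' @param design Design tibble with `sample_id` and `condition`.
#' @param min_frac Minimum fraction of non-missing samples required per
#'   group (default 0.5).
#' @return The filtered feature tibble (row subset of `features`).
#' @export
filter_by_group_prevalence <- function(features, mask, design, min_frac = 0.5) {
  check_design(design, features)
  m <- feature_matrix(features)
  mk <- as.matrix(mask[, colnames(m), drop = FALSE])
  if (!identical(dim(mk), dim(m))) abort("mask and feature table shapes differ.")
  cond <- design$condition[match(colnames(m), design$sample_id)]
  keep <- rep(TRUE, nrow(m))
  for (g in unique(cond)) {
    cols <- which(cond == g)
    if (length(cols) == 0) abort(paste0("condition with 0 samples: ", g))
    frac <- rowSums(!mk[, cols, drop = FALSE]) / length(cols)
    keep <- keep & (frac >= min_frac)
  }
  features[keep, , drop = FALSE]
}

#' k-nearest-neighbor imputation of absent intensities
#'
#' Only truly absent (`NA`) entries are imputed; observed low intensities are
#' left untouched. For each feature with absences, its `k` nearest features
#' (mean squared difference over mutually observed samples) that are observed
#' at the target sample supply the imputed value as their average. Features
#' missing more than `rowmax` of their samples fall back to their own
#' observed mean; a sample missing more than `colmax` of its features is a
#' hard error.
#'
#' @inheritParams sample_ids
#' @param k Number of neighbor features (default 10).
#' @param colmax Maximum tolerated per-sample missing fraction (default 0.95).
#' @param rowmax Per-feature missing fraction above which the feature-mean
#'   fallback is used (default 0.5).
#' @return Complete feature tibble (no `NA`, all values > 0).
#' @export
impute_knn <- function(features, k = 10, colmax = 0.95, rowmax = 0.5) {
  if (k < 1) abort("`k` must be >= 1.")
  m <- feature_matrix(features)
  obs <- !is.na(m)
  col_miss <- 1 - colMeans(obs)
  if (any(col_miss > colmax)) {
    abort(paste0("sample(s) exceed colmax missing fraction: ",
                 paste(colnames(m)[col_miss > colmax], collapse = ", ")))
  }
  row_miss <- 1 - rowMeans(obs)
  if (all(row_miss == 0)) return(features)

  x0 <- m
  x0[!obs] <- 0
  # mean squared difference over shared observed samples, via three products
  sq <- x0^2
  o <- obs * 1
  shared <- tcrossprod(o)
  ss <- tcrossprod(sq, o) + tcrossprod(o, sq) - 2 * tcrossprod(x0)
  d2 <- ifelse(shared > 0, ss / shared, Inf)
  diag(d2) <- Inf

  out <- m
  need <- which(row_miss > 0)
  for (i in need) {
    if (row_miss[i] > rowmax) {
      out[i, !obs[i, ]] <- mean(m[i, obs[i, ]])
      next
    }
    ord <- order(d2[i, ])
    for (j in which(!obs[i, ])) {
      nb <- ord[obs[ord, j]]
      nb <- nb[is.finite(d2[i, nb])]
      if (length(nb) == 0) {
        out[i, j] <- mean(m[i, obs[i, ]])
      } else {
        out[i, j] <- mean(m[head(nb, k), j])
      }
    }
  }
  if (any(is.na(out)) || any(out <= 0)) {
    abort("imputation produced non-positive or missing values; check input.")
  }
  as_feature_table(out, features)
}

#' Median-of-ratios normalization
#'
#' Per-feature reference = geometric mean across samples; a sample's size
#' factor is the median over features of intensity/reference; normalized
#' intensity = intensity / size factor. Requires a complete, strictly
#' positive matrix (run after imputation).
#'
#' @inheritParams sample_ids
#' @return Normalized feature tibble; per-sample size factors are attached as
#'   attribute `"size_factors"` (tibble `sample_id`, `size_factor`).
#' @export
normalize_median_ratio <- function(features) {
  m <- feature_matrix(features)
  if (any(is.na(m)) || any(m <= 0)) {
    abort("normalization needs a complete, strictly positive matrix.")
  }
  ref <- exp(rowMeans(log(m)))
  sf <- apply(m / ref, 2, median)
  norm <- sweep(m, 2L, sf, "/")
  out <- as_feature_table(norm, features)
  attr(out, "size_factors") <- tibble::tibble(
    sample_id = colnames(m), size_factor = unname(sf)
  )
  out
}

#' Log2 transform
#'
#' @inheritParams sample_ids
#' @return Feature tibble of log2 intensities.
#' @export
log2_transform <- function(features) {
  m <- feature_matrix(features)
  if (any(is.na(m)) || any(m <= 0)) {
    abort("log2 transform needs a complete, strictly positive matrix.")
  }
  as_feature_table(log2(m), features)
}

#' Full preprocessing chain
#'
#' Runs the fixed sequence quartile mask -> per-group prevalence filter ->
#' kNN imputation (absent entries only) -> median-of-ratios normalization ->
#' log2. The missingness threshold defaults to the first intensity quartile;
#' `censor = "high"` / `"high+medium"` instead use the third / second
#' quartile, reproducing the data-censoring comparison in which only
#' high-abundance (or high plus medium) features count as observed.
#'
#' @inheritParams filter_by_group_prevalence
#' @inheritParams impute_knn
#' @param censor `"none"` (threshold = q1), `"high"` (q3) or
#'   `"high+medium"` (q2).
#' @return List with `log2` (the processed feature tibble), `thresholds`
#'   (quartile tibble), `threshold_used`, `size_factors`, and counts
#'   `n_features_in` / `n_features_kept`.
#' @export
preprocess_features <- function(features, design, min_frac = 0.5,
                                censor = c("none", "high", "high+medium"),
                                k = 10, colmax = 0.95, rowmax = 0.5) {
  censor <- match.arg(censor)
  check_design(design, features)
  q <- compute_quartiles(features)
  thr <- switch(censor, none = q$q1, high = q$q3, `high+medium` = q$q2)
  mask <- build_missing_mask(features, thr, mode = "filtering")
  kept <- filter_by_group_prevalence(features, mask, design, min_frac)
  if (nrow(kept) == 0) abort("prevalence filter removed all features.")
  imp <- impute_knn(kept, k = k, colmax = colmax, rowmax = rowmax)
  norm <- normalize_median_ratio(imp)
  lg <- log2_transform(norm)
  list(
    log2 = lg,
    thresholds = q,
    threshold_used = thr,
    size_factors = attr(norm, "size_factors"),
    n_features_in = nrow(features),
    n_features_kept = nrow(kept)
  )
}
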