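# broom-style accessors: tidy() returns per-unit tibbles, glance() one-row
# summaries.

#' @describeIn robust_ica Tidy loadings: one row per feature x component.
#' @param x An `ms1_decomposition`.
#' @param matrix Which matrix to tidy: `"S"` (loadings) or `"A"`
#'   (activities).
#' @param ... Unused.
#' @export
tidy.ms1_decomposition <- function(x, matrix = c("S", "A"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "S") {
    as_tibble(x$S, rownames = "feature_id") |>
      tidyr::pivot_longer(-"feature_id", names_to = "component",
                          values_to = "loading")
  } else {
    as_tibble(x$A, rownames = "component") |>
      tidyr::pivot_longer(-"component", names_to = "sample_id",
                          values_to = "activity")
  }
}

#' @describeIn robust_ica One-row run summary.
#' @export
glance.ms1_decomposition <- function(x, ...) {
  tibble(n_features = nrow(x$S), n_samples = ncol(x$A),
         n_requested = x$n_requested, n_robust = x$n_robust,
         n_runs = x$n_runs,
         min_run_support = min(x$cluster_sizes) / (x$n_runs_used %||% x$n_runs))
}

#' @describeIn select_k Per-feature module assignments; pass the feature
#'   table via `features =` to carry `rt`/`mz` annotations along.
#' @param x An `ms1_feature_clustering`.
#' @param features Optional wide feature tibble for annotation columns.
#' @param ... Unused.
#' @export
tidy.ms1_feature_clustering <- function(x, features = NULL, ...) {
  out <- tibble(feature_id = x$feature_ids %||%
                  as.character(seq_along(x$labels)),
                module = x$labels,
                is_medoid = seq_along(x$labels) %in% x$medoids)
  if (!is.null(features)) {
    ann <- features[, intersect(ANNOT_COLS, names(features)), drop = FALSE]
    out <- dplyr::left_join(out, ann, by = "feature_id")
    out <- out[, unique(c("feature_id", "module", "rt", "mz", "is_medoid",
                          names(out))), drop = FALSE]
  }
  out
}

#' @describeIn select_k One-row clustering summary.
#' @export
glance.ms1_feature_clustering <- function(x, ...) {
  tibble(n_features = length(x$labels), chosen_k = x$chosen_k,
         cost = x$cost,
         silhouette = max(x$silhouette_by_k$silhouette))
}

#' @describeIn compute_eigenfeatures Long eigenfeature values per module and
#'   sample.
#' @param x An `ms1_eigenfeatures`.
#' @param ... Unused.
#' @export
tidy.ms1_eigenfeatures <- function(x, ...) {
  as_tibble(x$E, rownames = "module") |>
    tidyr::pivot_longer(-"module", names_to = "sample_id",
                        values_to = "eigenfeature")
}

#' @describeIn compute_eigenfeatures Per-module summary.
#' @export
glance.ms1_eigenfeatures <- function(x, ...) {
  tibble(module = rownames(x$E), size = unname(x$module_sizes),
         explained_variance = unname(x$explained_variance))
}

#' @describeIn correlate_eigenfeatures Long module x condition correlations.
#' @param x An `ms1_correlation_profile`.
#' @param ... Unused.
#' @export
tidy.ms1_correlation_profile <- function(x, ...) {
  if (length(x$R) == 0) {
    return(tibble(module = character(0), condition = character(0),
                  r = numeric(0)))
  }
  as_tibble(x$R, rownames = "module") |>
    tidyr::pivot_longer(-"module", names_to = "condition", values_to = "r")
}

#' @describeIn condition_tree Per-node AU/BP support plus merge heights.
#' @param x An `ms1_condition_tree`.
#' @param ... Unused.
#' @export
tidy.ms1_condition_tree <- function(x, ...) {
  dplyr::mutate(x$support, height = x$hclust$height)
}

#' @describeIn condition_tree One-row tree summary.
#' @export
glance.ms1_condition_tree <- function(x, ...) {
  tibble(n_conditions = length(x$hclust$labels), chosen_k = x$chosen_k,
         n_boot = x$n_boot,
         n_au_over_0.9 = sum(x$support$au > 0.9, na.rm = TRUE))
}

#' @describeIn permutation_pvalue One-row comparison summary.
#' @param x An `ms1_tree_comparison`.
#' @param ... Unused.
#' @export
glance.ms1_tree_comparison <- function(x, ...) {
  tibble(r_cophenetic = x$r_cophenetic, n_perm = x$n_perm,
         count_ge = x$count_ge, p_value = x$p_value)
}

#' @describeIn fit_lasso_loocv Nonzero coefficients of the final model.
#' @param x An `ms1_marker_model`.
#' @param ... Unused.
#' @export
tidy.ms1_marker_model <- function(x, ...) {
  out <- tibble(feature_id = names(x$coefficients),
                coefficient = unname(x$coefficients))
  out <- out[out$coefficient != 0, , drop = FALSE]
  if (!is.null(x$candidates)) {
    out <- dplyr::left_join(out, x$candidates, by = "feature_id")
  }
  out
}

#' @describeIn fit_lasso_loocv One-row model summary.
#' @export
glance.ms1_marker_model <- function(x, ...) {
  tibble(outcome = x$outcome %||% NA_character_,
         module = x$module_id %||% NA_character_,
         lambda_1se = x$lambda_1se, lambda_min = x$lambda_min,
         n_nonzero = length(x$nonzero_features), kept = x$kept,
         loocv_auc = x$loocv_auc)
}
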