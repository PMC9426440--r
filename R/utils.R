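# Internal helpers shared across the pipeline. The user-facing feature table
# is a wide tibble: feature_id [, rt, mz], then one numeric column per sample
# (missing measurements are NA). Internally everything runs on a features x
# samples matrix with feature_id rownames.

ANNOT_COLS <- c("feature_id", "rt", "mz")

#' Sample columns of a wide feature table
#'
#' @param features A wide feature tibble (`feature_id` plus optional `rt`,
#'   `mz` annotation columns; all remaining columns are sample intensities).
#' @return Character vector of sample IDs, in column order.
#' @export
sample_ids <- function(features) {
  setdiff(names(features), ANNOT_COLS)
}

#' Extract the features-by-samples intensity matrix from a feature tibble
#'
#' @inheritParams sample_ids
#' @return Numeric matrix (features x samples) with `feature_id` rownames.
#' @export
feature_matrix <- function(features) {
  check_feature_table(features)
  sids <- sample_ids(features)
  m <- as.matrix(features[, sids, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- features$feature_id
  m
}

#' Rebuild a wide feature tibble from a matrix plus annotations
#'
#' @param m Numeric features x samples matrix with feature_id rownames.
#' @param annotations Optional tibble with `feature_id` (and `rt`, `mz`)
#'   rows matching `m`; annotation rows for dropped features are discarded.
#' @return A wide feature tibble.
#' @export
as_feature_table <- function(m, annotations = NULL) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  out <- tibble::tibble(feature_id = rownames(m))
  if (!is.null(annotations)) {
    keep <- intersect(ANNOT_COLS, names(annotations))
    ann <- annotations[match(rownames(m), annotations$feature_id), keep, drop = FALSE]
    out <- dplyr::bind_cols(out["feature_id"], ann[setdiff(keep, "feature_id")])
  }
  dplyr::bind_cols(out, tibble::as_tibble(m, .name_repair = "minimal"))
}

check_feature_table <- function(features) {
  if (!is.data.frame(features) || !"feature_id" %in% names(features)) {
    abort("`features` must be a data frame with a `feature_id` column.")
  }
  if (anyDuplicated(features$feature_id)) {
    abort("duplicate feature_id values in feature table.")
  }
  sids <- sample_ids(features)
  if (length(sids) == 0) abort("feature table has no sample columns.")
  if (anyDuplicated(sids)) abort("duplicate sample columns in feature table.")
  bad <- sids[!vapply(features[sids], is.numeric, logical(1))]
  if (length(bad)) {
    abort(paste0("non-numeric sample column(s): ", paste(bad, collapse = ", ")))
  }
  neg <- vapply(features[sids], function(x) any(x < 0, na.rm = TRUE), logical(1))
  if (any(neg)) abort("negative intensities are not allowed.")
  invisible(features)
}

check_design <- function(design, features = NULL) {
  if (!is.data.frame(design) ||
      !all(c("sample_id", "condition") %in% names(design))) {
    abort("`design` must have `sample_id` and `condition` columns.")
  }
  if (anyDuplicated(design$sample_id)) abort("duplicated sample_id in design.")
  if (any(is.na(design$condition) | design$condition == "")) {
    abort("every sample needs a non-empty condition.")
  }
  if (!is.null(features)) {
    sids <- sample_ids(features)
    missing <- setdiff(sids, design$sample_id)
    if (length(missing)) {
      abort(paste0("samples absent from design: ", paste(missing, collapse = ", ")))
    }
    extra <- setdiff(design$sample_id, sids)
    if (length(extra)) {
      inform(paste0("design has ", length(extra),
                    " sample(s) not present in the feature table; ignored."))
    }
  }
  invisible(design)
}

condition_levels <- function(design) {
  cond <- as.character(design$condition)
  unique(cond)
}

# Pearson correlation between columns of a and b without cor()'s per-call
# overhead; both centered/scaled with denominator n.
fast_cor <- function(a, b = NULL) {
  a <- scale_cols(a)
  if (is.null(b)) return(crossprod(a) / nrow(a))
  crossprod(a, scale_cols(b)) / nrow(a)
}

scale_cols <- function(m) {
  m <- sweep(m, 2L, colMeans(m), "-")
  s <- sqrt(colMeans(m^2))
  if (any(s == 0)) abort("zero-variance column encountered in correlation.")
  sweep(m, 2L, s, "/")
}

# Deterministic child seeds below 2^31, derived from one master seed.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset) * 7L + 13L
}
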