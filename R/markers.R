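# Marker selection guided by the module-condition correlation profile: the
# module most correlated (in absolute value) with the outcome condition
# supplies candidate features; an L1-regularized logistic model is fit on
# them with the penalty chosen by leave-one-out cross-validation at
# lambda.1se, and discrimination is reported as LOOCV AUC.

#' Module most correlated with an outcome condition
#'
#' @param profile An `ms1_correlation_profile`.
#' @param outcome A condition level present in the profile.
#' @return The module row name with maximum `|r|` for `outcome` (ties go to
#'   the smallest module index, with a message).
#' @export
select_marker_module <- function(profile, outcome) {
  r <- profile_matrix(profile)
  if (nrow(r) == 0) abort("empty correlation profile.")
  if (!outcome %in% colnames(r)) {
    abort(paste0("outcome condition not in profile: ", outcome))
  }
  v <- abs(r[, outcome])
  best <- which(v == max(v))
  if (length(best) > 1) {
    inform(paste0("tie on |r| for ", outcome, "; keeping the smallest module."))
  }
  rownames(r)[best[1]]
}

#' L1-regularized logistic marker model with LOOCV-chosen penalty
#'
#' Fits a lasso (`alpha = 1`) logistic path over 100 log-spaced penalties
#' spanning two decades below the smallest all-zero penalty, picks
#' `lambda.1se` by leave-one-out cross-validated binomial deviance, refits on
#' all samples, and evaluates by leave-one-out AUC on held-out probabilities.
#' The model is `kept` only when more than one feature has a nonzero
#' coefficient. Features are standardized internally; coefficients are
#' reported on the input (log2) scale.
#'
#' @param x Numeric samples x features matrix (log2 intensities of the
#'   candidate module's features).
#' @param y Binary outcome: logical, 0/1, or a 2-level factor (second level
#'   = positive class).
#' @param seed Integer seed (recorded; the LOOCV folds are deterministic).
#' @return An `ms1_marker_model`.
#' @export
fit_lasso_loocv <- function(x, y, seed = 1) {
  x <- as.matrix(x)
  y <- as_binary(y)
  if (length(unique(y)) < 2 || min(table(y)) < 2) {
    abort("both outcome classes need at least 2 samples.")
  }
  if (ncol(x) < 2) abort("need at least 2 candidate features.")
  n <- nrow(x)

  lmax <- max(glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                             standardize = TRUE, nlambda = 5)$lambda)
  grid <- exp(seq(log(lmax), log(lmax) - 2 * log(10), length.out = 100))

  cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                          lambda = grid, standardize = TRUE,
                          foldid = seq_len(n), grouped = FALSE,
                          type.measure = "deviance")
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                        lambda = grid, standardize = TRUE)
  beta <- as.numeric(coef(fit, s = cv$lambda.1se))[-1]
  names(beta) <- colnames(x)
  nonzero <- beta[beta != 0]
  kept <- length(nonzero) > 1
  if (!kept) {
    inform(paste0("lasso kept ", length(nonzero),
                  " feature(s); model discarded (need > 1)."))
  }

  model <- structure(list(
    lambda_path = grid,
    cv_deviance = tibble::tibble(lambda = cv$lambda, mean = cv$cvm,
                                 se = cv$cvsd),
    lambda_1se = cv$lambda.1se,
    lambda_min = cv$lambda.min,
    coefficients = beta,
    nonzero_features = names(nonzero),
    kept = kept,
    loocv_auc = NA_real_,
    n = n,
    seed = as.integer(seed)
  ), class = "ms1_marker_model")
  if (kept) model$loocv_auc <- loocv_auc(model, x, y)
  model
}

as_binary <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) abort("`y` must be binary.")
  as.integer(y)
}

#' Leave-one-out AUC of a marker model
#'
#' Refits the lasso at the model's `lambda_1se` with each sample held out in
#' turn, scores the held-out sample, and computes AUC from the rank
#' statistic over held-out scores (mid-ranks for ties). In-fold predictions
#' are never used. The score is the feature term of the linear predictor,
#' `x_i' beta_fold`, with the fold intercept excluded: in leave-one-out the
#' intercept tracks the left-out label (removing a case lowers the training
#' prevalence), which would anti-rank the predictions of a model that has
#' learned nothing — the feature term is the part that actually carries
#' discriminative information and is monotone in the predicted probability
#' within any fold.
#'
#' @param model An `ms1_marker_model`.
#' @param x,y The data the model was fit on.
#' @return AUC in \[0, 1\]; degenerate constant scores (e.g. every fold
#'   intercept-only) give 0.5 with a warning.
#' @export
loocv_auc <- function(model, x, y) {
  x <- as.matrix(x)
  y <- as_binary(y)
  n <- nrow(x)
  score <- numeric(n)
  for (i in seq_len(n)) {
    fit_i <- glmnet::glmnet(x[-i, , drop = FALSE], y[-i],
                            family = "binomial", alpha = 1,
                            lambda = model$lambda_path, standardize = TRUE)
    beta_i <- as.numeric(coef(fit_i, s = model$lambda_1se))[-1]
    score[i] <- drop(x[i, ] %*% beta_i)
  }
  if (sd(score) == 0) {
    warn("held-out scores carry no feature signal; AUC set to 0.5.")
    return(0.5)
  }
  rank_auc(score, y)
}

rank_auc <- function(score, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(score, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Marker model for one condition contrast, guided by the module profile
#'
#' One-vs-rest contrast: picks the module with maximal |r| for `outcome`
#' via [select_marker_module()], then fits [fit_lasso_loocv()] on that
#' module's log2 features.
#'
#' @inheritParams sample_ids
#' @param clustering An `ms1_feature_clustering` over the same features.
#' @param profile An `ms1_correlation_profile` from the same run.
#' @param design Design tibble; `outcome` must be one of its condition
#'   levels.
#' @param outcome Condition level to discriminate from all others.
#' @param seed Integer seed.
#' @return An `ms1_marker_model` with `module_id`, `outcome` and a
#'   `candidates` tibble (feature_id, rt, mz) attached.
#' @export
fit_marker_model <- function(features, clustering, profile, design, outcome,
                             seed = 1) {
  check_design(design, features)
  module <- select_marker_module(profile, outcome)
  mod_idx <- match(module, profile$modules)
  m <- feature_matrix(features)
  labels <- clustering_labels(clustering, rownames(m))
  ids <- rownames(m)[labels == sort(unique(labels))[mod_idx]]
  if (length(ids) < 2) abort("selected module has fewer than 2 features.")
  x <- t(m[ids, , drop = FALSE])
  cond <- design$condition[match(rownames(x), design$sample_id)]
  y <- as.integer(cond == outcome)
  model <- fit_lasso_loocv(x, y, seed = seed)
  model$module_id <- module
  model$outcome <- outcome
  ann <- intersect(c("feature_id", "rt", "mz"), names(features))
  model$candidates <- features[features$feature_id %in% ids, ann, drop = FALSE]
  model
}

#' @export
print.ms1_marker_model <- function(x, ...) {
  cat("Lasso marker model")
  if (!is.null(x$outcome)) cat(" for outcome", x$outcome,
                               "(module", paste0(x$module_id, ")"))
  cat("\n  lambda.1se =", signif(x$lambda_1se, 4),
      "| nonzero features:", length(x$nonzero_features),
      "| kept:", x$kept, "\n")
  if (x$kept) cat("  LOOCV AUC =", sprintf("%.3f", x$loocv_auc), "\n")
  invisible(x)
}
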