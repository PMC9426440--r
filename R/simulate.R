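# Synthetic MS1 screens with known ground truth. The generator emulates the
# data model the pipeline assumes: log-normal feature intensities organized
# into block-correlated modules, condition-specific log2 shifts shared
# within planted condition groups, per-sample scaling factors, and
# intensity-dependent (MNAR) dropout concentrated below a low-intensity
# quantile.

#' Configuration for a synthetic MS1 screen
#'
#' Defaults describe a drug-screen-like layout: 16 conditions of 3
#' replicates (48 samples) falling into 3 planted groups — a control-like
#' group of 7 conditions with no effect, a strong-effect group of 4
#' (2 log2-units module shifts) and an intermediate group of 5 (1 log2
#' unit) — with 2000 features of which 12 modules of 100 carry the signal.
#'
#' @param n_features Total feature count.
#' @param n_modules Number of signal-carrying modules.
#' @param module_size Features per module (remaining features are
#'   unstructured noise).
#' @param n_replicates Replicates per condition.
#' @param group_sizes Named integer vector: conditions per planted group.
#' @param group_effect_sd Named numeric vector: log2 effect scale per group.
#' @param base_log2_mean,base_log2_sd Per-feature baseline log2 intensity
#'   distribution.
#' @param feature_noise_sd Per-entry residual noise (log2).
#' @param module_activity_sd Module-level per-sample noise shared by a
#'   module's features (log2).
#' @param sample_scale_sd Spread (log2) of per-sample scaling factors.
#' @param censor_quantile Intensity quantile below which dropout applies.
#' @param dropout_prob Probability that a sub-quantile entry is absent.
#' @param batch_drift Optional per-batch log2 shift (0 = off; two batches).
#' @param seed Integer seed.
#' @return A `ms1_sim_config` list.
#' @export
simulation_config <- function(n_features = 2000, n_modules = 12,
                              module_size = 100, n_replicates = 3,
                              group_sizes = c(control = 7, strong = 4,
                                              intermediate = 5),
                              group_effect_sd = c(control = 0, strong = 2,
                                                  intermediate = 1),
                              base_log2_mean = 24, base_log2_sd = 2,
                              feature_noise_sd = 0.5,
                              module_activity_sd = 0.25,
                              sample_scale_sd = 0.3,
                              censor_quantile = 0.25, dropout_prob = 0.6,
                              batch_drift = 0, seed = 1) {
  if (n_modules * module_size > n_features) {
    abort("module features exceed n_features.")
  }
  if (!all(names(group_sizes) %in% names(group_effect_sd))) {
    abort("every group needs an effect scale.")
  }
  if (censor_quantile < 0 || censor_quantile > 1 ||
      dropout_prob < 0 || dropout_prob > 1) {
    abort("probabilities must lie in [0, 1].")
  }
  structure(as.list(environment()), class = "ms1_sim_config")
}

#' Simulate a synthetic MS1 screen
#'
#' @param config An [simulation_config()] list.
#' @return List with `features` (wide feature tibble with `rt`/`mz`
#'   annotations and `NA` dropout), `design` (sample_id, condition,
#'   replicate, group), and `truth` (per-feature module labels, 0 = noise,
#'   plus the planted condition grouping).
#' @export
simulate_screen <- function(config = simulation_config()) {
  cf <- config
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(cf$seed))

  groups <- rep(names(cf$group_sizes), cf$group_sizes)
  n_cond <- length(groups)
  conditions <- sprintf("C%02d_%s", seq_len(n_cond), substr(groups, 1, 3))
  design <- tibble::tibble(
    sample_id = paste0(rep(conditions, each = cf$n_replicates), "_r",
                       rep(seq_len(cf$n_replicates), n_cond)),
    condition = rep(conditions, each = cf$n_replicates),
    replicate = rep(seq_len(cf$n_replicates), n_cond),
    group = rep(groups, each = cf$n_replicates)
  )
  n_samp <- nrow(design)

  module_of <- c(rep(seq_len(cf$n_modules), each = cf$module_size),
                 rep(0L, cf$n_features - cf$n_modules * cf$module_size))
  # per-module response direction per group, scaled by the group effect size
  coefs <- matrix(rnorm(cf$n_modules * length(cf$group_sizes)),
                  cf$n_modules, dimnames = list(NULL, names(cf$group_sizes)))
  effect <- sapply(seq_len(n_cond), function(c) {
    g <- groups[c]
    cf$group_effect_sd[[g]] * coefs[, g]
  })                                     # n_modules x n_cond

  base <- rnorm(cf$n_features, cf$base_log2_mean, cf$base_log2_sd)
  loading <- runif(cf$n_features, 0.75, 1.25)
  act_noise <- matrix(rnorm(cf$n_modules * n_samp, 0, cf$module_activity_sd),
                      cf$n_modules, n_samp)
  cond_idx <- match(design$condition, conditions)

  lg <- matrix(rnorm(cf$n_features * n_samp, 0, cf$feature_noise_sd),
               cf$n_features, n_samp) + base
  sig <- module_of > 0
  lg[sig, ] <- lg[sig, ] + loading[sig] *
    (effect[module_of[sig], cond_idx, drop = FALSE] +
       act_noise[module_of[sig], , drop = FALSE])
  if (cf$batch_drift != 0) {
    batch <- rep_len(c(0, cf$batch_drift), n_samp)
    lg <- sweep(lg, 2L, batch, "+")
  }
  scale_log2 <- rnorm(n_samp, 0, cf$sample_scale_sd)
  inten <- 2^sweep(lg, 2L, scale_log2, "+")

  if (cf$dropout_prob > 0 && cf$censor_quantile > 0) {
    thr <- quantile(inten, cf$censor_quantile, type = 7)
    drop <- inten < thr &
      matrix(runif(length(inten)) < cf$dropout_prob, nrow(inten))
    inten[drop] <- NA_real_
  }

  rownames(inten) <- sprintf("F%05d", seq_len(cf$n_features))
  colnames(inten) <- design$sample_id
  ann <- tibble::tibble(
    feature_id = rownames(inten),
    rt = round(runif(cf$n_features, 60, 3600), 2),
    mz = round(runif(cf$n_features, 300, 1500), 4)
  )
  features <- as_feature_table(inten, ann)

  list(
    features = features,
    design = design[, c("sample_id", "condition", "replicate")],
    truth = list(
      modules = tibble::tibble(feature_id = rownames(inten),
                               module = module_of),
      condition_groups = tibble::tibble(condition = conditions,
                                        group = groups),
      effect = effect,
      config = cf
    )
  )
}

#' Simulate non-Gaussian sources for ICA recovery checks
#'
#' Draws independent super-Gaussian sources, mixes them with a random
#' full-rank matrix and adds Gaussian noise; the truth is returned for
#' matched-correlation scoring.
#'
#' @param n_features,n_samples Output dimensions.
#' @param n_sources Number of independent sources
#'   (`<= min(n_features, n_samples)`).
#' @param distribution `"laplace"` or `"uniform_spiked"` (sparse spikes on a
#'   uniform background). Gaussian sources are refused: ICA cannot identify
#'   them.
#' @param noise_sd Additive Gaussian noise level.
#' @param seed Integer seed.
#' @return List with `x` (features x samples), `S` (true sources, unit-norm
#'   columns), `A` (true mixing), `kappa` (mixing condition number).
#' @export
simulate_sources <- function(n_features, n_samples, n_sources,
                             distribution = c("laplace", "uniform_spiked",
                                              "gaussian"),
                             noise_sd = 0, seed = 1) {
  distribution <- match.arg(distribution)
  if (distribution == "gaussian") {
    abort("gaussian sources are not identifiable by ICA; refused.")
  }
  if (n_sources > min(n_features, n_samples)) {
    abort("n_sources must be <= min(n_features, n_samples).")
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  s <- switch(distribution,
    laplace = matrix(stats::rexp(n_features * n_sources) -
                       stats::rexp(n_features * n_sources), n_features),
    uniform_spiked = {
      base <- matrix(runif(n_features * n_sources, -0.1, 0.1), n_features)
      spikes <- matrix(rbinom(n_features * n_sources, 1, 0.05) *
                         rnorm(n_features * n_sources, 0, 3), n_features)
      base + spikes
    }
  )
  s <- sweep(s, 2L, sqrt(colSums(s^2)), "/")
  a <- matrix(rnorm(n_sources * n_samples), n_sources)
  x <- s %*% a
  if (noise_sd > 0) {
    x <- x + matrix(rnorm(length(x), 0, noise_sd * sd(x)), nrow(x))
  }
  rownames(x) <- sprintf("F%05d", seq_len(n_features))
  colnames(x) <- sprintf("S%03d", seq_len(n_samples))
  list(x = x, S = s, A = a, kappa = kappa(a, exact = TRUE))
}
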