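# One-call orchestration: preprocess -> robust ICA -> feature modules ->
# eigenfeatures -> condition correlation -> bootstrapped condition tree ->
# optional marker models, with a single master seed fanned out to per-stage
# seeds by fixed offsets.

STAGE_SEED_OFFSETS <- c(ica = 101L, feature_k = 202L, tree = 303L,
                        markers = 404L)

#' Pipeline configuration
#'
#' Collects every stage's tunable parameters with the package defaults.
#'
#' @param min_frac Prevalence filter fraction (default 0.5).
#' @param censor Missingness threshold scheme, see [preprocess_features()].
#' @param knn_k,colmax,rowmax Imputation settings.
#' @param n_runs,var_target,tol,max_iter,min_support,link_threshold Robust
#'   ICA settings, see [robust_ica()].
#' @param n_comp Optional fixed ICA component count (overrides the
#'   PCA-guided choice).
#' @param feature_k_range Candidate module counts (default `10:50`).
#' @param restarts k-medoid restarts per k.
#' @param condition_k_range Candidate flat-cut sizes (default all).
#' @param n_boot,scales AU bootstrap settings.
#' @param markers Character vector of outcome conditions to fit marker
#'   models for (default none).
#' @param stratify_by Optional design column; the pipeline runs once per
#'   stratum.
#' @return A `ms1_screen_config` list.
#' @export
screen_config <- function(min_frac = 0.5,
                          censor = c("none", "high", "high+medium"),
                          knn_k = 10, colmax = 0.95, rowmax = 0.5,
                          n_runs = 100, n_comp = NULL, var_target = 0.99,
                          tol = 1e-6, max_iter = 1000, min_support = 0.5,
                          link_threshold = 0.1,
                          feature_k_range = 10:50, restarts = 1,
                          condition_k_range = NULL,
                          n_boot = 1000, scales = seq(0.5, 1.4, by = 0.1),
                          markers = character(0), stratify_by = NULL) {
  censor <- match.arg(censor)
  structure(as.list(environment()), class = "ms1_screen_config")
}

#' Run the full MS1 screening pipeline
#'
#' Executes preprocessing, robust consensus ICA, k-medoid feature-module
#' detection, eigenfeature computation, eigenfeature-condition correlation,
#' and bootstrapped condition clustering; optionally fits marker models for
#' requested outcome conditions. With `stratify_by` set, samples are
#' partitioned by that design column and the pipeline runs independently per
#' stratum (a named list of runs is returned).
#'
#' @inheritParams sample_ids
#' @param design Design tibble (`sample_id`, `condition`, covariates).
#' @param config A [screen_config()].
#' @param seed Master seed; per-stage seeds are derived at fixed offsets.
#' @return An `ms1_screen_run` with every stage result, stage timings, the
#'   derived per-stage seeds, and the configuration echo.
#' @export
run_screen <- function(features, design, config = screen_config(), seed = 1) {
  check_design(design, features)
  if (!is.null(config$stratify_by)) {
    col <- config$stratify_by
    if (!col %in% names(design)) {
      abort(paste0("stratify_by column not in design: ", col))
    }
    strata <- unique(as.character(design[[col]]))
    sub_cf <- config
    sub_cf$stratify_by <- NULL
    runs <- lapply(strata, function(s) {
      dsub <- design[design[[col]] == s, , drop = FALSE]
      fsub <- features[, c(intersect(ANNOT_COLS, names(features)),
                           dsub$sample_id), drop = FALSE]
      run_screen(fsub, dsub, sub_cf, seed = seed)
    })
    names(runs) <- strata
    return(structure(runs, class = "ms1_screen_runs"))
  }

  seeds <- vapply(STAGE_SEED_OFFSETS, function(o) derive_seed(seed, o),
                  integer(1))
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  prep <- clock("preprocess", preprocess_features(
    features, design, min_frac = config$min_frac, censor = config$censor,
    k = config$knn_k, colmax = config$colmax, rowmax = config$rowmax))
  dec <- clock("ica", robust_ica(
    prep$log2, n_runs = config$n_runs, n_comp = config$n_comp,
    var_target = config$var_target, tol = config$tol,
    max_iter = config$max_iter, min_support = config$min_support,
    link_threshold = config$link_threshold, seed = seeds[["ica"]]))
  fc <- clock("feature_clustering", cluster_features(
    dec, k_range = config$feature_k_range, seed = seeds[["feature_k"]],
    restarts = config$restarts))
  eig <- clock("eigenfeatures", compute_eigenfeatures(prep$log2, fc))
  dsub <- design[match(sample_ids(prep$log2), design$sample_id), ]
  prof <- clock("correlation", correlate_eigenfeatures(eig, dsub))
  tree <- clock("condition_tree", condition_tree(
    prof, k_range = config$condition_k_range, n_boot = config$n_boot,
    scales = config$scales, seed = seeds[["tree"]]))

  marker_models <- list()
  for (outc in config$markers) {
    marker_models[[outc]] <- clock(paste0("marker_", outc), fit_marker_model(
      prep$log2, fc, prof, dsub, outc, seed = seeds[["markers"]]))
  }

  structure(list(
    preprocess = prep, decomposition = dec, feature_clustering = fc,
    eigenfeatures = eig, profile = prof, tree = tree,
    markers = marker_models,
    design = dsub, config = config, seed = as.integer(seed),
    stage_seeds = seeds, timings = timings
  ), class = "ms1_screen_run")
}

#' @export
print.ms1_screen_runs <- function(x, ...) {
  cat("Stratified MS1 screen:", length(x), "independent runs\n")
  for (nm in names(x)) {
    cat("--", nm, "--\n")
    print(x[[nm]])
  }
  invisible(x)
}

#' @export
print.ms1_screen_run <- function(x, ...) {
  cat("MS1 screen run (seed ", x$seed, ")\n", sep = "")
  cat("  features kept:", x$preprocess$n_features_kept, "of",
      x$preprocess$n_features_in, "\n")
  cat("  robust components:", x$decomposition$n_robust, "\n")
  cat("  feature modules: k =", x$feature_clustering$chosen_k, "\n")
  cat("  condition cut: k =", x$tree$chosen_k, "\n")
  if (length(x$markers)) {
    cat("  marker models:", paste(names(x$markers), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write all pipeline outputs with a hashed manifest
#'
#' Emits the normalized log2 matrix, feature-module assignments,
#' eigenfeature matrix, module-by-condition correlation profile, the
#' condition tree as Newick with AU/BP node comments, the flat cut labels,
#' and a JSON run report (seeds, parameters, derived values). The manifest
#' lists each file with its MD5 content hash; a fixed-seed rerun yields
#' byte-identical hashes. Per-stage timings vary between reruns and are
#' therefore recorded in the manifest itself, not in any hashed file. On a
#' partial write the incomplete output directory contents are removed.
#'
#' @param run An `ms1_screen_run`.
#' @param out_dir Output directory (created if needed).
#' @return Tibble manifest (`file`, `md5`), invisibly; also written as
#'   `manifest.json` alongside the outputs.
#' @export
write_screen_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(file.path(out_dir, basename(files))), add = TRUE)

  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    files <<- c(files, path)
    path
  }

  emit("normalized_log2.tsv", function(p) write_feature_table(run$preprocess$log2, p))
  emit("feature_modules.tsv", function(p) readr::write_tsv(tidy(run$feature_clustering, features = run$preprocess$log2), p, progress = FALSE))
  emit("eigenfeatures.tsv", function(p) {
    e <- run$eigenfeatures$E
    readr::write_tsv(dplyr::bind_cols(tibble::tibble(module = rownames(e)),
                                      tibble::as_tibble(e)), p, progress = FALSE)
  })
  emit("correlation_profile.tsv", function(p) {
    r <- run$profile$R
    wide <- if (length(r) == 0) tibble::tibble(module = character(0)) else {
      dplyr::bind_cols(tibble::tibble(module = rownames(r)),
                       tibble::as_tibble(r, .name_repair = "minimal"))
    }
    readr::write_tsv(wide, p, progress = FALSE)
  })
  emit("condition_tree.nwk", function(p) write_tree_newick(run$tree, p))
  emit("condition_cut.tsv", function(p) {
    readr::write_tsv(tibble::tibble(condition = names(run$tree$cut_labels),
                                    cluster = unname(run$tree$cut_labels)),
                     p, progress = FALSE)
  })
  emit("run_report.json", function(p) write_run_report(run, p))

  manifest <- tibble::tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files))
  )
  jsonlite::write_json(
    list(files = manifest,
         timings_sec = as.list(run$timings)),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  ok <- TRUE
  invisible(manifest)
}

write_run_report <- function(run, path) {
  cf <- run$config
  cf$condition_k_range <- cf$condition_k_range %||% "auto"
  cf$n_comp <- cf$n_comp %||% "auto"
  cf$stratify_by <- cf$stratify_by %||% "none"
  report <- list(
    package_version = as.character(utils::packageVersion("ms1screen")),
    master_seed = run$seed,
    stage_seeds = as.list(run$stage_seeds),
    parameters = unclass(cf),
    derived = list(
      quartiles = as.list(run$preprocess$thresholds),
      missing_threshold = run$preprocess$threshold_used,
      n_features_in = run$preprocess$n_features_in,
      n_features_kept = run$preprocess$n_features_kept,
      n_components_requested = run$decomposition$n_requested,
      n_components_robust = run$decomposition$n_robust,
      feature_k = run$feature_clustering$chosen_k,
      condition_k = run$tree$chosen_k
    ),
    node_support = run$tree$support
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}
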