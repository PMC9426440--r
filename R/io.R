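#' Read an aligned MS1 feature intensity table
#'
#' Reads either a generic wide table (one row per feature, one column per
#' sample) or the consensus-feature text export produced by the OpenMS
#' TextExporter step that usually sits upstream of this package.
#'
#' In both dialects an intensity of zero and an empty cell are treated as an
#' absent measurement (`NA`): the upstream consensus builder reports 0 for
#' maps in which a feature was not matched.
#'
#' @param path Path to a delimited text file.
#' @param dialect `"wide"` expects a header of `feature_id[, rt, mz]` followed
#'   by sample columns; `"openms_consensus"` expects TextExporter consensus
#'   output (`#CONSENSUS` header comment, `MAP` lines naming the input runs,
#'   one `CONSENSUS` line per feature with per-map rt/mz/intensity columns).
#'   Comma and tab separation are both accepted.
#' @return A wide feature tibble: `feature_id`, optional `rt` (seconds) and
#'   `mz`, then one numeric intensity column per sample with `NA` marking
#'   absent measurements.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("feature_id\trt\tmz\ts1\ts2",
#'              "F1\t100\t500.2\t10\t20",
#'              "F2\t200\t600.4\t\t5"), tf)
#' read_feature_table(tf)
#' @export
read_feature_table <- function(path, dialect = c("wide", "openms_consensus")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  switch(dialect,
    wide = read_wide_table(path),
    openms_consensus = read_openms_consensus(path)
  )
}

read_wide_table <- function(path) {
  delim <- sniff_delim(readLines(path, n = 1L))
  # everything is read as text and converted through R's correctly rounded
  # strtod, so written doubles survive a round trip bit-exactly
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, na = c("", "NA", "na"),
                           col_types = readr::cols(.default = "c"))
  if (!"feature_id" %in% names(tab)) {
    abort("wide feature table must have a `feature_id` column.")
  }
  for (s in setdiff(names(tab), "feature_id")) {
    parsed <- suppressWarnings(as.numeric(tab[[s]]))
    bad <- which(!is.na(tab[[s]]) & is.na(parsed))
    if (length(bad)) {
      abort(paste0("unparseable numeric value in column `", s, "`, row ",
                   bad[1], ": \"", tab[[s]][bad[1]], "\""))
    }
    if (!s %in% ANNOT_COLS) parsed[!is.na(parsed) & parsed == 0] <- NA_real_
    tab[[s]] <- parsed
  }
  check_feature_table(tab)
  tibble::as_tibble(tab)
}

# TextExporter consensus layout: "#"-prefixed comment/header lines; a
# "#CONSENSUS" line naming columns (rt_cf, mz_cf, intensity_cf, then per-map
# rt_<i>/mz_<i>/intensity_<i>); "MAP" lines mapping map index -> run filename;
# "CONSENSUS" data lines. Map index links intensity columns to samples.
read_openms_consensus <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  header <- grep("^#?CONSENSUS\\b", lines, value = TRUE)
  header <- header[grepl("^#", header)]
  if (length(header) == 0) abort("no #CONSENSUS header line found.")
  delim <- sniff_delim(header[1])
  cols <- strsplit(sub("^#", "", header[1]), delim, fixed = TRUE)[[1]]

  map_lines <- lines[grepl("^#?MAP", lines) & !grepl("^#", lines)]
  map_names <- character(0)
  if (length(map_lines)) {
    parts <- strsplit(map_lines, delim, fixed = TRUE)
    idx <- vapply(parts, function(p) as.integer(p[2]), integer(1))
    fn <- vapply(parts, function(p) p[3], character(1))
    map_names[as.character(idx)] <- sub("\\.[A-Za-z0-9]+$", "", basename(fn))
  }

  data_lines <- lines[grepl("^CONSENSUS", lines)]
  if (length(data_lines) == 0) abort("no CONSENSUS data lines found.")
  parts <- strsplit(data_lines, delim, fixed = TRUE)
  n_col <- length(cols)
  vals <- vapply(parts, function(p) {
    p <- c(p, rep("", max(0, n_col - length(p))))[seq_len(n_col)]
    p
  }, character(n_col))
  vals <- t(vals)
  colnames(vals) <- cols

  int_cols <- grep("^intensity_[0-9]+$", cols, value = TRUE)
  if (length(int_cols) == 0) abort("no per-map intensity_<i> columns found.")
  map_idx <- sub("^intensity_", "", int_cols)
  sids <- ifelse(!is.na(map_names[map_idx]) & nzchar(map_names[map_idx]),
                 map_names[map_idx], paste0("map_", map_idx))

  num <- function(col) {
    x <- suppressWarnings(as.numeric(vals[, col]))
    bad <- which(nzchar(vals[, col]) & is.na(x))
    if (length(bad)) {
      abort(paste0("unparseable numeric value in consensus column `", col,
                   "`, data row ", bad[1]))
    }
    x
  }
  inten <- vapply(int_cols, num, numeric(nrow(vals)))
  if (is.null(dim(inten))) inten <- matrix(inten, nrow = 1)
  inten[inten == 0] <- NA_real_
  colnames(inten) <- sids

  out <- tibble::tibble(
    feature_id = sprintf("cons_%05d", seq_len(nrow(vals)))
  )
  if ("rt_cf" %in% cols) out$rt <- num("rt_cf")
  if ("mz_cf" %in% cols) out$mz <- num("mz_cf")
  out <- dplyr::bind_cols(out, tibble::as_tibble(inten, .name_repair = "minimal"))
  check_feature_table(out)
  out
}

sniff_delim <- function(line) {
  if (lengths(regmatches(line, gregexpr("\t", line))) >=
      lengths(regmatches(line, gregexpr(",", line)))) "\t" else ","
}

#' Write a wide feature table
#'
#' Values are written with a shortest round-trip representation, so
#' `read_feature_table(write_feature_table(x))` reproduces `x` exactly.
#'
#' @inheritParams sample_ids
#' @param path Output path; tab-separated.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  check_feature_table(features)
  out <- features
  for (s in setdiff(names(out), "feature_id")) {
    v <- sprintf("%.17g", out[[s]])
    v[is.na(out[[s]])] <- NA_character_
    out[[s]] <- v
  }
  readr::write_tsv(out, path, progress = FALSE, na = "")
  invisible(path)
}

#' Read a sample design table
#'
#' @param path Delimited file whose header contains at least `sample_id` and
#'   `condition`; any further columns are kept as covariates.
#' @return A tibble with `sample_id`, `condition` (character; level order =
#'   first appearance) and covariate columns.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0) abort("empty design file.")
  tab <- readr::read_delim(path, delim = sniff_delim(first),
                           show_col_types = FALSE, progress = FALSE)
  if (nrow(tab) == 0) abort("design file has no rows.")
  if (!all(c("sample_id", "condition") %in% names(tab))) {
    abort("design must have `sample_id` and `condition` columns.")
  }
  tab$sample_id <- as.character(tab$sample_id)
  tab$condition <- as.character(tab$condition)
  check_design(tab)
  tibble::as_tibble(tab)
}

#' Write a condition dendrogram as Newick with AU/BP node comments
#'
#' Internal nodes carry a bracketed comment `[&AU=...,BP=...]` which standard
#' Newick readers (for example [ape::read.tree()]) skip, preserving topology
#' and branch lengths on re-parse.
#'
#' @param tree A `condition_tree` object (see [condition_tree()]) or a plain
#'   `hclust`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  hc <- if (inherits(tree, "ms1_condition_tree")) tree$hclust else tree
  if (!inherits(hc, "hclust")) abort("`tree` must be a condition_tree or hclust.")
  support <- if (inherits(tree, "ms1_condition_tree")) tree$support else NULL
  writeLines(hclust_to_newick(hc, support), path)
  invisible(path)
}

# Recursive Newick serialization of an hclust; node k's branch length is the
# parent merge height minus its own height (leaves sit at height 0).
hclust_to_newick <- function(hc, support = NULL) {
  n <- length(hc$labels)
  fmt <- function(x) sprintf("%.10g", x)
  node_comment <- function(node) {
    if (is.null(support)) return("")
    i <- match(node, support$node)
    if (is.na(i)) return("")
    sprintf("[&AU=%s,BP=%s]", fmt(support$au[i]), fmt(support$bp[i]))
  }
  rec <- function(node, parent_height) {
    if (node < 0) {
      lab <- gsub("[,;:()\\[\\] ]", "_", hc$labels[-node])
      return(paste0(lab, ":", fmt(parent_height)))
    }
    h <- hc$height[node]
    kids <- hc$merge[node, ]
    inner <- paste(rec(kids[1], h), rec(kids[2], h), sep = ",")
    paste0("(", inner, ")", node_comment(node), ":", fmt(parent_height - h))
  }
  root <- n - 1L
  paste0(sub(":[^:]*$", "", rec(root, hc$height[root])), ";")
}
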