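# File plumbing: delimited feature tables, cluster maps, JSON results and
# run manifests, the file-based test front-end and the group-wise screen.

.table_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a feature table
#'
#' Delimited text with one header row; the first column holds sample IDs,
#' the remaining columns numeric features. Comma-separated for
#' \code{.csv}, tab-separated otherwise. Row order defines sample order.
#'
#' @param path file path.
#' @return Numeric matrix with sample IDs as row names.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .table_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("feature table needs an ID column and at least ",
                          "one feature column", call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicated sample ID: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric feature column in ", path,
                           call. = FALSE)
  rownames(m) <- ids
  m
}

#' Read a sample-to-cluster map
#'
#' Two-column delimited text (sample ID, cluster label) with a header row.
#'
#' @param path file path.
#' @return Named character vector: cluster labels named by sample ID.
#' @export
read_cluster_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .table_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("cluster map needs two columns (sample ID, ",
                          "cluster label)", call. = FALSE)
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

# Align y (and optionally a cluster map) to x's sample IDs; error naming
# the first ID that cannot be matched.
.align_by_id <- function(x, y, cluster_map = NULL) {
  ids <- rownames(x)
  if (is.null(ids) || is.null(rownames(y))) {
    stop("feature tables must carry sample IDs", call. = FALSE)
  }
  miss <- setdiff(ids, rownames(y))
  if (length(miss) > 0L) {
    stop("sample ID '", miss[1L], "' from the X table is missing in the Y ",
         "table", call. = FALSE)
  }
  extra <- setdiff(rownames(y), ids)
  if (length(extra) > 0L) {
    stop("sample ID '", extra[1L], "' from the Y table is missing in the X ",
         "table", call. = FALSE)
  }
  y <- y[ids, , drop = FALSE]
  clusters <- NULL
  if (!is.null(cluster_map)) {
    miss <- setdiff(ids, names(cluster_map))
    if (length(miss) > 0L) {
      stop("sample ID '", miss[1L], "' has no cluster assignment",
           call. = FALSE)
    }
    clusters <- unname(cluster_map[ids])
  }
  list(x = x, y = y, clusters = clusters)
}

#' Run the independence test on files
#'
#' Reads X and Y feature tables (and optionally a cluster map), aligns all
#' inputs by sample ID, runs \code{\link{hsic_test}} and optionally writes
#' the result as a single JSON record. Without a cluster file the plain
#' (i.i.d.) HSIC path is used and a notice is logged to stderr.
#'
#' @param x_file,y_file feature-table paths.
#' @param cluster_file optional cluster-map path.
#' @param out optional path for the JSON result.
#' @param ... passed on to \code{\link{hsic_test}}.
#' @return The \code{hsic_test} object, invisibly.
#' @export
hsic_test_files <- function(x_file, y_file, cluster_file = NULL, out = NULL,
                            ...) {
  x <- read_feature_table(x_file)
  y <- read_feature_table(y_file)
  cm <- if (!is.null(cluster_file)) read_cluster_map(cluster_file)
  if (is.null(cm)) {
    message("no cluster file given; treating samples as independent")
  }
  al <- .align_by_id(x, y, cm)
  res <- hsic_test(al$x, al$y, clusters = al$clusters, ...)
  res$data.name <- paste(basename(x_file), "and", basename(y_file))
  if (!is.null(out)) write_hsic_result(res, out)
  invisible(res)
}

#' Serialize a test result to JSON
#'
#' @param result an \code{hsic_test} object.
#' @param path output path.
#' @export
write_hsic_result <- function(result, path) {
  rec <- list(
    statistic = unname(result$statistic),
    statistic_name = result$statistic_name,
    p_value = result$p.value,
    method = result$method,
    n_units = result$n_units,
    n_samples = result$n_samples,
    n_permutations = result$n_permutations,
    moments = if (!is.null(result$moments))
      result$moments[c("mu", "sigma2", "gamma")],
    kernel_x = result$kernel_x,
    kernel_y = result$kernel_y,
    seed = result$seed
  )
  jsonlite::write_json(rec[!vapply(rec, is.null, logical(1L))], path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a run manifest
#'
#' Records command, configuration, seed, package version, timestamp and
#' input checksums next to an output so that a run can be traced.
#'
#' @param dir output directory (created if needed).
#' @param command character label of the command.
#' @param inputs character vector of input file paths (checksummed).
#' @param config list of configuration values.
#' @param seed integer seed or NULL.
#' @return Manifest path, invisibly.
#' @export
write_run_manifest <- function(dir, command, inputs = character(),
                               config = list(), seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    command = command,
    config = config,
    seed = seed,
    package_version = as.character(utils::packageVersion("chsic")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input_checksums = as.list(tools::md5sum(inputs))
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Group-wise association screen
#'
#' Tests X against each named group of Y columns (e.g. the metabolites of
#' one metabolic pathway) with one independence test per group, and applies
#' a Bonferroni correction at level \code{alpha / G} across the G groups.
#'
#' @param x sample matrix.
#' @param y sample matrix whose columns are partitioned into groups.
#' @param groups either a vector of length \code{ncol(y)} of group labels,
#'   or a named list mapping group names to column indices/names of
#'   \code{y}.
#' @param clusters optional cluster labels.
#' @param alpha family-wise level before correction (default 0.05).
#' @param ... passed on to \code{\link{hsic_test}}.
#' @return Data frame sorted by p-value: group, group size, statistic,
#'   p-value, Bonferroni threshold and rejection flag.
#' @export
hsic_screen <- function(x, y, groups, clusters = NULL, alpha = 0.05, ...) {
  if (!is.list(groups)) {
    if (length(groups) != ncol(y)) {
      stop("'groups' must name every column of 'y'", call. = FALSE)
    }
    groups <- split(seq_len(ncol(y)), factor(groups, levels = unique(groups)))
  }
  keep <- vapply(groups, length, integer(1L)) > 0L
  if (any(!keep)) {
    warning("skipping empty group(s): ",
            paste(names(groups)[!keep], collapse = ", "), call. = FALSE)
    groups <- groups[keep]
  }
  g <- length(groups)
  if (g == 0L) stop("no non-empty groups", call. = FALSE)
  threshold <- alpha / g
  rows <- lapply(names(groups), function(gn) {
    res <- hsic_test(x, y[, groups[[gn]], drop = FALSE], clusters = clusters,
                     ...)
    data.frame(group = gn, n_features = length(groups[[gn]]),
               statistic = unname(res$statistic), p_value = res$p.value,
               method = res$method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bonferroni_threshold <- threshold
  out$significant <- out$p_value <= threshold
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}
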