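#' Read a cell-by-feature matrix from disk
#'
#' Two dialects are supported. `dense_csv`: a delimited table with a header
#' of feature names and the first column holding cell ids (comma, tab or
#' whitespace delimited; autodetected by \code{data.table::fread}).
#' `mtx_triplet`: a MatrixMarket `.mtx` file (cells in rows) accompanied by
#' `<path>.rownames` and `<path>.colnames` sidecar text files carrying one
#' cell id / feature name per line.
#'
#' @param path file path.
#' @param format `"dense_csv"` or `"mtx_triplet"`.
#' @return an [expression_matrix].
#' @export
read_matrix <- function(path, format = c("dense_csv", "mtx_triplet")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_data("file not found: ", path)
  if (format == "dense_csv") {
    dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
    if (ncol(dt) < 2L) stop_data("dense matrix needs an id column plus features: ", path)
    ids <- as.character(dt[[1L]])
    vals <- as.matrix(dt[, -1L, drop = FALSE])
    expression_matrix(vals, cell_ids = ids, feature_names = colnames(dt)[-1L])
  } else {
    rn_path <- paste0(path, ".rownames")
    cn_path <- paste0(path, ".colnames")
    if (!file.exists(rn_path)) stop_data("missing row-name sidecar: ", rn_path)
    if (!file.exists(cn_path)) stop_data("missing column-name sidecar: ", cn_path)
    m <- Matrix::readMM(path)
    rn <- readLines(rn_path)
    cn <- readLines(cn_path)
    if (length(rn) != nrow(m)) {
      stop_data("row-name sidecar has ", length(rn), " entries but matrix has ",
                nrow(m), " rows")
    }
    if (length(cn) != ncol(m)) {
      stop_data("column-name sidecar has ", length(cn), " entries but matrix has ",
                ncol(m), " columns")
    }
    expression_matrix(as.matrix(m), cell_ids = rn, feature_names = cn)
  }
}

#' Write a cell-by-feature matrix to disk
#'
#' Inverse of [read_matrix]; `read_matrix(write_matrix(x, p), format)`
#' reproduces `x` exactly.
#'
#' @param x an [expression_matrix].
#' @param path output path.
#' @param format `"dense_csv"` or `"mtx_triplet"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, format = c("dense_csv", "mtx_triplet")) {
  format <- match.arg(format)
  if (format == "dense_csv") {
    df <- data.frame(cell_id = x$cell_ids, x$values, check.names = FALSE)
    data.table::fwrite(df, path, sep = ",")
  } else {
    Matrix::writeMM(methods::as(Matrix::Matrix(x$values, sparse = TRUE), "generalMatrix"),
                    path)
    writeLines(x$cell_ids, paste0(path, ".rownames"))
    writeLines(x$feature_names, paste0(path, ".colnames"))
  }
  invisible(path)
}

#' Read / write per-cell label tables
#'
#' Labels travel as a two-column TSV (`cell_id`, `cell_type`) with header.
#'
#' @param path file path.
#' @return named character vector of cell types, names = cell ids.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = "character")
  if (ncol(dt) < 2L) stop_data("label table needs cell_id and cell_type columns")
  stats::setNames(as.character(dt[[2L]]), as.character(dt[[1L]]))
}

#' @rdname read_labels
#' @param labels named character vector (names = cell ids).
#' @export
write_labels <- function(labels, path) {
  data.table::fwrite(data.frame(cell_id = names(labels),
                                cell_type = unname(labels)),
                     path, sep = "\t")
  invisible(path)
}

#' Library-size log-normalization
#'
#' Each cell's values are divided by the cell's total, multiplied by `scale`,
#' then mapped through `log(1 + .)` — the de facto single-cell recipe.
#' All-zero cells pass through unchanged. The same transform is applied to
#' binary accessibility matrices; no TF-IDF weighting is used.
#'
#' @param x an [expression_matrix] with nonnegative values.
#' @param scale positive scale factor (default `1e4`).
#' @return an [expression_matrix] of normalized values.
#' @export
log_normalize <- function(x, scale = 1e4) {
  stopifnot(is.numeric(scale), scale > 0)
  v <- x$values
  if (any(v < 0)) stop_data("log_normalize requires nonnegative values")
  tot <- rowSums(v)
  nz <- tot > 0
  v[nz, ] <- log1p(v[nz, , drop = FALSE] / tot[nz] * scale)
  expression_matrix(v, x$cell_ids, x$feature_names, x$labels)
}

#' Restrict two matrices to their common feature space
#'
#' Cross-dataset transfer requires a shared feature list; both outputs carry
#' the intersection of the two feature sets in the same (reference) order.
#'
#' @param ref,query [expression_matrix] objects.
#' @return list with elements `ref` and `query`.
#' @export
intersect_features <- function(ref, query) {
  common <- intersect(ref$feature_names, query$feature_names)
  if (length(common) == 0L) stop_data("no features shared between reference and query")
  list(
    ref = expression_matrix(ref$values[, common, drop = FALSE],
                            ref$cell_ids, common, ref$labels),
    query = expression_matrix(query$values[, common, drop = FALSE],
                              query$cell_ids, common, query$labels)
  )
}

#' k-nearest-neighbor graph of the raw query data
#'
#' Builds the neighborhood graph that the contrastive loss preserves: the
#' query is log-normalized, reduced by PCA (deterministic full SVD via
#' \code{stats::prcomp}) to at most `n_components` dimensions, and each
#' cell's `k` exact Euclidean nearest neighbors (excluding itself) are
#' recorded. Distance ties are broken by ascending cell index so the graph
#' is reproducible.
#'
#' @param query an [expression_matrix] of raw query values.
#' @param n_components PCA dimensionality (default 50, clipped to the data).
#' @param k neighborhood size (default 15, clipped to `n_query - 1`).
#' @param normalize log-normalize before PCA (default TRUE; set FALSE if the
#'   input is already normalized).
#' @return an object of class `neighbor_graph`: list with `neighbor_indices`
#'   (n_query x k' integer matrix, ordered by increasing distance), `k`,
#'   `n_components`.
#' @export
build_knn_graph <- function(query, n_components = 50, k = 15, normalize = TRUE) {
  n <- n_cells(query)
  if (n < 2L) stop_data("need at least 2 query cells to build a neighbor graph")
  if (k < 1L) stop_data("k must be >= 1")
  x <- if (normalize) log_normalize(query)$values else query$values
  ncomp <- min(n_components, n - 1L, ncol(x))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = ncomp)$x
  keff <- min(k, n - 1L)
  # exact pairwise distances; squared distances suffice for ranking
  sq <- rowSums(pc * pc)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(pc)
  nbr <- matrix(0L, n, keff)
  for (i in seq_len(n)) {
    di <- d2[i, ]
    di[i] <- Inf
    ord <- order(di, seq_len(n))   # ties -> ascending cell index
    nbr[i, ] <- ord[seq_len(keff)]
  }
  structure(list(neighbor_indices = nbr, k = keff, n_components = ncomp),
            class = "neighbor_graph")
}
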