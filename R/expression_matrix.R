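#' Construct a cell-by-feature expression matrix
#'
#' The basic container on both the reference and query side: a dense
#' nonnegative cells x features matrix with unique cell and feature names,
#' and (reference only) an optional per-cell label vector.
#'
#' @param values numeric matrix (cells in rows) or a sparse Matrix; coerced
#'   to dense double.
#' @param cell_ids character vector, one unique id per row. Defaults to the
#'   row names of `values`.
#' @param feature_names character vector, one unique name per column.
#'   Defaults to the column names of `values`.
#' @param labels optional character vector of per-cell cell types.
#' @return an object of class `expression_matrix` with elements `values`,
#'   `cell_ids`, `feature_names`, `labels`.
#' @export
expression_matrix <- function(values, cell_ids = rownames(values),
                              feature_names = colnames(values),
                              labels = NULL) {
  if (inherits(values, "Matrix")) values <- as.matrix(values)
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(values)))
  if (is.null(feature_names)) feature_names <- paste0("feat", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids)
  feature_names <- as.character(feature_names)
  if (length(cell_ids) != nrow(values)) {
    stop_data("cell_ids length (", length(cell_ids), ") does not match row count (",
              nrow(values), ")")
  }
  if (length(feature_names) != ncol(values)) {
    stop_data("feature_names length (", length(feature_names),
              ") does not match column count (", ncol(values), ")")
  }
  if (anyDuplicated(cell_ids)) stop_data("duplicate cell ids")
  if (anyDuplicated(feature_names)) stop_data("duplicate feature names")
  check_finite(values, "expression matrix")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(values)) {
      stop_data("labels must have exactly one entry per cell")
    }
  }
  dimnames(values) <- list(cell_ids, feature_names)
  structure(list(values = values, cell_ids = cell_ids,
                 feature_names = feature_names, labels = labels),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d cells x %d features%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$labels)) "" else
                sprintf(" (%d labeled types)", length(unique(x$labels)))))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Number of cells / features
#' @param x an `expression_matrix`
#' @return integer count
#' @export
n_cells <- function(x) nrow(x$values)

#' @rdname n_cells
#' @export
n_features <- function(x) ncol(x$values)

# subset cells by index, keeping labels aligned
subset_cells <- function(x, idx) {
  expression_matrix(x$values[idx, , drop = FALSE],
                    cell_ids = x$cell_ids[idx],
                    feature_names = x$feature_names,
                    labels = if (is.null(x$labels)) NULL else x$labels[idx])
}
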