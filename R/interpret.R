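#' Integrated-gradients attribution of query predictions
#'
#' Attributes each cell's class score to its input features by integrating
#' the gradient of the target class's pre-softmax score along the straight
#' path from a baseline (default: all zeros, i.e., absent expression) to
#' the cell's observed profile:
#' `attr_j = (x_j - baseline_j) * integral_0^1 dF_target/dx_j (baseline + a (x - baseline)) da`,
#' approximated by a midpoint Riemann sum over `n_steps` path intervals.
#' Because the extractor is piecewise linear, each cell's partition is
#' additionally refined at the path positions where a first-hidden-layer
#' unit crosses zero (closed form in the path parameter), so for the default
#' single-hidden-layer architecture the quadrature is exact up to floating
#' point. The pre-softmax score is used as the target so the completeness
#' identity `sum_j attr_j = F(x) - F(baseline)` holds up to quadrature
#' error, which shrinks as `n_steps` grows. The model runs in evaluation
#' mode.
#'
#' @param model a trained `lb_model`.
#' @param x numeric matrix of query cells (rows) in the training feature
#'   order.
#' @param target integer class index per cell (1-based); typically the
#'   predicted class.
#' @param baseline numeric vector of length `ncol(x)` or a single value
#'   (default 0).
#' @param n_steps number of base path intervals (default 50).
#' @param chunk_rows cap on path points evaluated per forward pass.
#' @return an object of class `attribution_result`: list with
#'   `attributions` (n x features), `target_class`, `baseline`, `n_steps`.
#' @export
integrated_gradients <- function(model, x, target, baseline = 0, n_steps = 50,
                                 chunk_rows = 20000L) {
  stopifnot(inherits(model, "lb_model"))
  x <- as.matrix(x)
  if (n_steps < 1L) stop_data("n_steps must be >= 1")
  target <- as.integer(target)
  if (length(target) == 1L) target <- rep(target, nrow(x))
  if (length(target) != nrow(x)) stop_data("one target class per cell required")
  if (length(baseline) == 1L) baseline <- rep(baseline, ncol(x))
  if (length(baseline) != ncol(x)) stop_data("baseline width mismatch")
  n <- nrow(x)
  B <- matrix(baseline, n, ncol(x), byrow = TRUE)
  diffX <- x - B
  base_breaks <- seq(0, 1, length.out = n_steps + 1L)

  # first-hidden-layer pre-activations are affine in the path parameter:
  # z(a) = c + a*m; each zero crossing inside (0,1) is a gradient kink and
  # becomes a partition break for that cell
  # ReLU acts after the (affine, eval-mode) batch norm, so the crossing is
  # found on the normalized scale
  has_hidden <- length(model$config$hidden_dims) > 0L
  if (has_hidden) {
    W1 <- model$params$W1
    b1 <- as.vector(model$params$b1)
    scale1 <- as.vector(model$params$bn_g1) / sqrt(model$buffers$rv1 + bn_eps)
    Cz <- sweep(sweep(B %*% W1, 2L, b1, "+"), 2L, model$buffers$rm1, "-")
    Cz <- sweep(sweep(Cz, 2L, scale1, "*"), 2L,
                as.vector(model$params$bn_b1), "+")
    Mz <- sweep(diffX %*% W1, 2L, scale1, "*")
  }

  rows_x <- list(); rows_len <- list(); rows_cell <- list()
  for (i in seq_len(n)) {
    cross <- if (has_hidden) {
      cr <- -Cz[i, ] / Mz[i, ]
      cr[is.finite(cr) & cr > 0 & cr < 1]
    } else numeric(0)
    brk <- sort(unique(c(base_breaks, cross)))
    mids <- (utils::head(brk, -1) + utils::tail(brk, -1)) / 2
    lens <- diff(brk)
    rows_x[[i]] <- outer(mids, diffX[i, ]) +
      matrix(B[i, ], length(mids), ncol(x), byrow = TRUE)
    rows_len[[i]] <- lens
    rows_cell[[i]] <- rep(i, length(mids))
  }
  Xpath <- do.call(rbind, rows_x)
  wts <- unlist(rows_len)
  cell_of <- unlist(rows_cell)

  avg_grad <- matrix(0, n, ncol(x))
  start <- 1L
  while (start <= nrow(Xpath)) {
    end <- min(start + chunk_rows - 1L, nrow(Xpath))
    idx <- start:end
    tape <- ad_tape()
    Xnode <- ad_leaf(tape, Xpath[idx, , drop = FALSE])
    logits <- nn_logits_eval_tape(tape, model, Xnode)
    obj <- ad_sum(tape, ad_pick(tape, logits, target[cell_of[idx]]))
    ad_backward(tape, obj)
    g <- ad_grad(Xnode) * wts[idx]
    for (r in seq_along(idx)) {
      ci <- cell_of[idx[r]]
      avg_grad[ci, ] <- avg_grad[ci, ] + g[r, ]
    }
    start <- end + 1L
  }
  structure(list(attributions = diffX * avg_grad,
                 target_class = target, baseline = baseline,
                 n_steps = n_steps),
            class = "attribution_result")
}

# F(x) - F(baseline) for the completeness check, eval mode
logit_scores <- function(model, x, target) {
  d <- embed_cells(model, x)
  L <- sweep(d %*% model$params$W_cls, 2L, as.vector(model$params$b_cls), "+")
  L[cbind(seq_len(nrow(L)), target)]
}

#' Determinant features per cell and per cell type
#'
#' Per cell, the `n_per_cell` features with the largest attributions, in
#' descending order (attribution ties broken by ascending feature index).
#' Per predicted cell type (cells labeled `"Unknown"` are excluded), each
#' feature's occurrence frequency across that type's per-cell lists is
#' counted and the `n_per_type` most frequent features are kept; frequency
#' ties are broken by higher mean attribution within the type, then by
#' feature index.
#'
#' @param attr an `attribution_result` over the same cells as
#'   `predictions`.
#' @param predictions a `prediction_result` from [annotate_cells].
#' @param feature_names character vector naming the attribution columns.
#' @param n_per_cell per-cell list length (default 100, clipped to the
#'   feature count).
#' @param n_per_type per-type list length (default 50, clipped likewise).
#' @return an object of class `determinant_features`: list with
#'   `per_cell_top` (list of character vectors) and `per_type_top` (named
#'   list of data.frames with `feature`, `frequency`, `rank`).
#' @export
determinant_features <- function(attr, predictions, feature_names,
                                 n_per_cell = 100L, n_per_type = 50L) {
  A <- attr$attributions
  if (nrow(A) != length(predictions$cell_ids)) {
    stop_data("attributions and predictions cover different cells")
  }
  if (length(feature_names) != ncol(A)) stop_data("feature name count mismatch")
  n_per_cell <- min(n_per_cell, ncol(A))
  n_per_type <- min(n_per_type, ncol(A))

  per_cell_idx <- t(apply(A, 1L, function(row) {
    order(-row, seq_along(row))[seq_len(n_per_cell)]
  }))
  per_cell_top <- lapply(seq_len(nrow(A)),
                         function(i) feature_names[per_cell_idx[i, ]])
  names(per_cell_top) <- predictions$cell_ids

  types <- setdiff(unique(predictions$assigned_type), "Unknown")
  per_type_top <- lapply(types, function(tp) {
    cells <- which(predictions$assigned_type == tp)
    counts <- tabulate(as.vector(per_cell_idx[cells, , drop = FALSE]),
                       nbins = ncol(A))
    mean_attr <- colMeans(A[cells, , drop = FALSE])
    ord <- order(-counts, -mean_attr, seq_len(ncol(A)))[seq_len(n_per_type)]
    data.frame(feature = feature_names[ord],
               frequency = counts[ord] / length(cells),
               rank = seq_len(n_per_type),
               stringsAsFactors = FALSE)
  })
  names(per_type_top) <- types
  structure(list(per_cell_top = per_cell_top, per_type_top = per_type_top),
            class = "determinant_features")
}

#' Key-gene hit rate (KGHR)
#'
#' Fraction of a cell type's determinant features that appear in the
#' curated marker list for that type:
#' `KGHR(t) = |determinant(t) intersect markers(t)| / |determinant(t)|`.
#' Only types present in both inputs are scored.
#'
#' @param determinant a `determinant_features` object, or a named list of
#'   character vectors of features per type.
#' @param markers named list of character vectors of curated markers per
#'   type.
#' @return named numeric vector of hit rates in `[0, 1]`.
#' @export
kghr <- function(determinant, markers) {
  det_lists <- if (inherits(determinant, "determinant_features")) {
    lapply(determinant$per_type_top, function(df) df$feature)
  } else {
    determinant
  }
  types <- intersect(names(det_lists), names(markers))
  if (length(types) == 0L) stop_data("no cell types shared between inputs")
  out <- vapply(types, function(tp) {
    dl <- det_lists[[tp]]
    if (length(dl) == 0L) stop_data("empty determinant list for type ", tp)
    length(intersect(dl, markers[[tp]])) / length(dl)
  }, numeric(1))
  out
}

#' Write interpretation tables
#'
#' Per-type determinant features go to a TSV with columns `cell_type`,
#' `rank`, `feature`, `frequency`; hit rates to a TSV with `cell_type`,
#' `kghr`.
#'
#' @param determinant a `determinant_features` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_determinant_features <- function(determinant, path) {
  rows <- lapply(names(determinant$per_type_top), function(tp) {
    df <- determinant$per_type_top[[tp]]
    data.frame(cell_type = tp, rank = df$rank, feature = df$feature,
               frequency = df$frequency, stringsAsFactors = FALSE)
  })
  data.table::fwrite(do.call(rbind, rows), path, sep = "\t")
  invisible(path)
}

#' @rdname export_determinant_features
#' @param rates named numeric vector from [kghr].
#' @export
export_kghr <- function(rates, path) {
  data.table::fwrite(data.frame(cell_type = names(rates), kghr = unname(rates)),
                     path, sep = "\t")
  invisible(path)
}

#' Read a curated marker-gene table
#'
#' Two-column TSV (`cell_type`, `feature`), one marker per line.
#'
#' @param path file path.
#' @return named list of character vectors per type.
#' @export
read_marker_lists <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  df <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = "character")
  split(df[[2L]], df[[1L]])
}

#' @rdname read_marker_lists
#' @param markers named list of character vectors.
#' @export
write_marker_lists <- function(markers, path) {
  df <- data.frame(cell_type = rep(names(markers), lengths(markers)),
                   feature = unlist(markers, use.names = FALSE))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
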