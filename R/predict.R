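#' Annotate query cells with open-set rejection
#'
#' Runs the trained extractor and classifier in evaluation mode (all
#' parameters fixed) on the query and assigns each cell the class with the
#' highest probability — but only when that probability strictly exceeds
#' `threshold`; otherwise the cell is labeled `"Unknown"`, flagging a
#' potential novel cell type absent from the reference. The threshold is a
#' prediction-time knob only; it plays no role in training.
#'
#' @param model a trained `lb_model` (from [fit_annotator] or
#'   [load_model]).
#' @param query an [expression_matrix], normalized the same way as the
#'   training data, with the training feature set.
#' @param threshold rejection threshold in `[0, 1)` (default 0.95).
#' @return an object of class `prediction_result`: list with `cell_ids`,
#'   `assigned_type` (class name or `"Unknown"`), `confidence` (row maxima
#'   of the probabilities), `full_probabilities` (n x K matrix, columns
#'   named by class).
#' @export
annotate_cells <- function(model, query, threshold = 0.95) {
  stopifnot(inherits(model, "lb_model"))
  if (is.null(model$classes)) stop_data("model has not been trained")
  if (threshold < 0 || threshold >= 1) stop_data("threshold must lie in [0, 1)")
  x <- query$values
  if (!identical(query$feature_names, model$feature_names)) {
    if (setequal(query$feature_names, model$feature_names)) {
      x <- x[, model$feature_names, drop = FALSE]
    } else {
      stop_data("query features do not match the model's training features")
    }
  }
  d <- embed_cells(model, x)
  cls <- classify_cells(model, d)
  colnames(cls$p) <- model$classes
  assigned <- ifelse(cls$confidence > threshold,
                     model$classes[cls$predicted_class], "Unknown")
  structure(list(cell_ids = query$cell_ids,
                 assigned_type = assigned,
                 confidence = cls$confidence,
                 full_probabilities = cls$p,
                 threshold = threshold),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  tab <- sort(table(x$assigned_type), decreasing = TRUE)
  cat(sprintf("predictions for %d cells (threshold %g):\n",
              length(x$cell_ids), x$threshold))
  print(tab)
  invisible(x)
}

#' Write predictions to a TSV file
#'
#' Columns, in fixed order: `cell_id`, `assigned_type` (the literal string
#' `"Unknown"` for rejected cells, never an empty field), `confidence`,
#' then optionally one probability column per class (`prob_<class>`).
#'
#' @param result a `prediction_result`.
#' @param path output path.
#' @param probabilities include per-class probability columns (default
#'   FALSE).
#' @return `path`, invisibly.
#' @export
export_predictions <- function(result, path, probabilities = FALSE) {
  stopifnot(inherits(result, "prediction_result"))
  df <- data.frame(cell_id = result$cell_ids,
                   assigned_type = result$assigned_type,
                   confidence = result$confidence,
                   stringsAsFactors = FALSE)
  if (probabilities) {
    pr <- as.data.frame(result$full_probabilities)
    names(pr) <- paste0("prob_", colnames(result$full_probabilities))
    df <- cbind(df, pr)
  }
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname export_predictions
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  data.table::fread(path, header = TRUE, data.table = FALSE)
}
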