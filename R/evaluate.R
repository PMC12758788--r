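#' Annotation accuracy
#'
#' Fraction of cells whose predicted type string equals the true type. In
#' open-set evaluation, supply `novel_types`: true labels in that set are
#' remapped to `"Unknown"` first, so a novel cell counts as correct exactly
#' when it was rejected.
#'
#' @param true_labels,predicted_labels character vectors of equal length.
#' @param novel_types optional character vector of query-only types.
#' @return scalar in `[0, 1]`.
#' @export
annotation_accuracy <- function(true_labels, predicted_labels,
                                novel_types = NULL) {
  if (length(true_labels) == 0L) stop_data("empty input")
  if (length(true_labels) != length(predicted_labels)) {
    stop_data("label vectors differ in length")
  }
  truth <- as.character(true_labels)
  if (!is.null(novel_types)) truth[truth %in% novel_types] <- "Unknown"
  mean(truth == as.character(predicted_labels))
}

#' Confusion matrix over the union of observed labels
#'
#' @param true_labels,predicted_labels character vectors of equal length.
#' @return square integer matrix, rows = truth, columns = prediction.
#' @export
confusion_matrix <- function(true_labels, predicted_labels) {
  lev <- sort(union(unique(true_labels), unique(predicted_labels)))
  table(factor(true_labels, levels = lev),
        factor(predicted_labels, levels = lev))
}

#' Macro-averaged F1 score
#'
#' Unweighted mean of per-class F1 over the classes present in the truth;
#' a class with zero precision and recall contributes F1 = 0. Classes that
#' appear only in the predictions (e.g., `"Unknown"` during closed-set
#' evaluation) are excluded from the average.
#'
#' @param true_labels,predicted_labels character vectors of equal length.
#' @return list with `macro_f1` and named `per_class_f1`; or the scalar if
#'   `details = FALSE`.
#' @param details return the per-class breakdown (default FALSE).
#' @export
macro_f1 <- function(true_labels, predicted_labels, details = FALSE) {
  if (length(true_labels) == 0L) stop_data("empty input")
  if (length(true_labels) != length(predicted_labels)) {
    stop_data("label vectors differ in length")
  }
  truth <- as.character(true_labels)
  pred <- as.character(predicted_labels)
  classes <- sort(unique(truth))
  f1 <- vapply(classes, function(k) {
    tp <- sum(truth == k & pred == k)
    fp <- sum(truth != k & pred == k)
    fn <- sum(truth == k & pred != k)
    if ((2 * tp + fp + fn) == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  if (details) list(macro_f1 = mean(f1), per_class_f1 = f1) else mean(f1)
}

#' Novel-cell-type detection AUROC
#'
#' Area under the ROC curve for separating novel from shared-type cells,
#' scoring each cell's novelty as `1 - confidence`. Computed with the
#' midrank (Mann-Whitney) formulation, so ties contribute 1/2.
#'
#' @param is_novel logical vector (TRUE = the cell's true type is absent
#'   from the reference).
#' @param confidence per-cell maximum predicted probability.
#' @return scalar AUROC in `[0, 1]`.
#' @export
novelty_auroc <- function(is_novel, confidence) {
  is_novel <- as.logical(is_novel)
  if (length(is_novel) != length(confidence)) stop_data("length mismatch")
  n1 <- sum(is_novel); n0 <- sum(!is_novel)
  if (n1 == 0L || n0 == 0L) {
    stop_data("both novel and non-novel cells are required")
  }
  score <- 1 - confidence
  r <- rank(score, ties.method = "average")
  (sum(r[is_novel]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Open-set classification rate (OSCR)
#'
#' Sweeps the confidence threshold and plots the correct classification
#' rate on shared-type cells (correct prediction AND confidence above the
#' threshold) against the false positive rate on novel cells (confidence
#' above the threshold); returns the area under that curve by the trapezoid
#' rule. A perfect open-set classifier scores 1.
#'
#' @param true_labels character truth for all cells (novel cells carry
#'   their own type names).
#' @param predicted_labels character predictions ignoring rejection (the
#'   argmax class per cell).
#' @param confidence per-cell maximum predicted probability.
#' @param novel_mask logical, TRUE for cells of novel types.
#' @return scalar OSCR in `[0, 1]`.
#' @export
oscr <- function(true_labels, predicted_labels, confidence, novel_mask) {
  novel_mask <- as.logical(novel_mask)
  n_known <- sum(!novel_mask)
  n_novel <- sum(novel_mask)
  if (n_novel == 0L) stop_data("no novel cells; OSCR is undefined")
  if (n_known == 0L) stop_data("no shared-type cells; OSCR is undefined")
  correct <- !novel_mask &
    (as.character(true_labels) == as.character(predicted_labels))
  # thresholds at every distinct confidence, plus one below the minimum so
  # the curve reaches FPR = 1
  thr <- c(sort(unique(confidence), decreasing = TRUE), -Inf)
  ccr <- vapply(thr, function(t) sum(correct & confidence > t) / n_known,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(novel_mask & confidence > t) / n_novel,
                numeric(1))
  ord <- order(fpr, ccr)
  fpr <- c(0, fpr[ord]); ccr <- c(0, ccr[ord])
  sum(diff(fpr) * (utils::head(ccr, -1) + utils::tail(ccr, -1)) / 2)
}

#' Full evaluation report
#'
#' Closed-set metrics always; open-set metrics (novelty AUROC, OSCR) when
#' `novel_types` is given and the query contains novel cells.
#'
#' @param true_labels character truth per query cell.
#' @param predictions a `prediction_result` from [annotate_cells].
#' @param novel_types optional character vector of query-only type names.
#' @return an `evaluation_report` list: `accuracy`, `macro_f1`,
#'   `per_class_f1`, `confusion`, and optionally `auroc`, `oscr`.
#' @export
evaluation_report <- function(true_labels, predictions, novel_types = NULL) {
  truth <- as.character(true_labels)
  pred <- predictions$assigned_type
  open_set <- !is.null(novel_types) && any(truth %in% novel_types)
  truth_eval <- truth
  if (open_set) truth_eval[truth %in% novel_types] <- "Unknown"
  mf <- macro_f1(truth_eval, pred, details = TRUE)
  rep <- list(accuracy = annotation_accuracy(truth, pred, novel_types),
              macro_f1 = mf$macro_f1,
              per_class_f1 = mf$per_class_f1,
              confusion = confusion_matrix(truth_eval, pred))
  if (open_set) {
    novel_mask <- truth %in% novel_types
    argmax <- colnames(predictions$full_probabilities)[
      max.col(predictions$full_probabilities, ties.method = "first")]
    rep$auroc <- novelty_auroc(novel_mask, predictions$confidence)
    rep$oscr <- oscr(truth, argmax, predictions$confidence, novel_mask)
  }
  structure(rep, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("accuracy: %.4f  macro-F1: %.4f", x$accuracy, x$macro_f1))
  if (!is.null(x$auroc)) cat(sprintf("  AUROC: %.4f  OSCR: %.4f", x$auroc, x$oscr))
  cat("\n")
  invisible(x)
}
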