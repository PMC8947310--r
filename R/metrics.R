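#' Confusion matrix of truth against prediction
#'
#' A `k x k` count matrix with rows as truth and columns as prediction.
#'
#' @param truth,pred Vectors of class ids or labels, same length, nonempty.
#' @param labels Level set fixing the class order; defaults to the sorted
#'   union of the values (with [tongue_classes()] order when applicable).
#' @return A `confusion_matrix` (integer matrix with dimnames
#'   `truth`/`pred`).
#' @export
#' @examples
#' confusion_matrix(c(1, 1, 2), c(1, 2, 2), labels = 1:2)
confusion_matrix <- function(truth, pred, labels = NULL) {
  if (length(truth) == 0 || length(truth) != length(pred))
    abort("`truth` and `pred` must be nonempty and the same length.",
          class = "tonguecaps_invalid_input")
  if (is.null(labels)) {
    vals <- unique(c(truth, pred))
    labels <- if (all(vals %in% tongue_classes()))
      intersect(tongue_classes(), vals) else sort(vals)
  }
  t_f <- factor(truth, levels = labels)
  p_f <- factor(pred, levels = labels)
  cm <- unclass(table(truth = t_f, pred = p_f))
  structure(matrix(as.integer(cm), nrow(cm), ncol(cm),
                   dimnames = dimnames(cm)),
            class = "confusion_matrix")
}

#' Evaluate a fit on a test set
#'
#' Predicts every test image by its longest class capsule and tabulates the
#' confusion matrix.
#'
#' @param fit A `tonguecaps_fit`.
#' @param x List of input arrays (nonempty).
#' @param y Integer class ids (truth).
#' @param labels Optional label names for the matrix dimnames.
#' @return A [confusion_matrix()].
#' @export
evaluate_tonguecaps <- function(fit, x, y, labels = fit$labels) {
  if (length(x) == 0)
    abort("empty test set.", class = "tonguecaps_invalid_input")
  lens <- predict(fit, x, type = "lengths")
  pred <- apply(lens, 1, classify_lengths)
  k <- fit$model$spec$num_classes
  cm <- confusion_matrix(y, pred, labels = seq_len(k))
  if (!is.null(labels)) dimnames(cm) <- list(truth = labels, pred = labels)
  cm
}

#' One-vs-rest metrics for one class
#'
#' Collapses the multiclass confusion matrix to the binary problem "class c
#' against the rest": `TP = cm[c,c]`, `FN` the rest of row c, `FP` the rest
#' of column c, `TN` the remainder, and computes accuracy
#' `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`. A class absent from the truth (`TP+FN = 0`) has undefined
#' sensitivity, returned as `NaN` with a warning.
#'
#' @param cm A [confusion_matrix()] (total > 0).
#' @param class_index Class index (or label) to treat as positive.
#' @return One-row tibble: `class`, `tp`, `fn`, `fp`, `tn`, `accuracy`,
#'   `sensitivity`, `specificity`.
#' @export
one_vs_rest_metrics <- function(cm, class_index) {
  if (sum(cm) == 0)
    abort("confusion matrix is empty.", class = "tonguecaps_invalid_input")
  if (is.character(class_index))
    class_index <- match(class_index, rownames(cm))
  c <- class_index
  tp <- cm[c, c]
  fn <- sum(cm[c, ]) - tp
  fp <- sum(cm[, c]) - tp
  tn <- sum(cm) - tp - fn - fp
  sens <- if (tp + fn == 0) {
    warning("class absent from truth: sensitivity undefined", call. = FALSE)
    NaN
  } else tp / (tp + fn)
  spec <- if (tn + fp == 0) NaN else tn / (tn + fp)
  tibble::tibble(class = if (!is.null(rownames(cm))) rownames(cm)[c] else as.character(c),
                 tp = tp, fn = fn, fp = fp, tn = tn,
                 accuracy = (tp + tn) / sum(cm),
                 sensitivity = sens, specificity = spec)
}

#' Macro (unweighted) average of per-class metrics
#'
#' The mean over classes of each metric, skipping undefined (`NaN`)
#' entries; errors if every entry of a metric is undefined.
#'
#' @param per_class Tibble from [metrics_report()]'s per-class rows (or
#'   rbound [one_vs_rest_metrics()] rows).
#' @return One-row tibble with `accuracy`, `sensitivity`, `specificity`.
#' @export
macro_average <- function(per_class) {
  avg <- function(v) {
    ok <- !is.nan(v)
    if (!any(ok))
      abort("all per-class values undefined.", class = "tonguecaps_invalid_input")
    mean(v[ok])
  }
  tibble::tibble(accuracy = avg(per_class$accuracy),
                 sensitivity = avg(per_class$sensitivity),
                 specificity = avg(per_class$specificity))
}

#' Per-class and macro metrics report
#'
#' One-vs-rest accuracy, sensitivity and specificity for every class plus
#' the unweighted macro average.
#'
#' @param cm A [confusion_matrix()].
#' @return Tibble with one row per class and a final `"macro"` row.
#' @export
metrics_report <- function(cm) {
  per <- dplyr::bind_rows(lapply(seq_len(nrow(cm)), function(c)
    one_vs_rest_metrics(cm, c)))
  macro <- dplyr::mutate(macro_average(per), class = "macro",
                         tp = NA_integer_, fn = NA_integer_,
                         fp = NA_integer_, tn = NA_integer_)
  dplyr::bind_rows(per, macro[, names(per)])
}
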