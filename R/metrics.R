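#' Classification accuracy
#'
#' @param truth,estimate Equal-length label vectors.
#' @return Fraction of correct predictions.
#' @export
#' @examples
#' accuracy(c(0, 1, 2, 3), c(0, 1, 2, 0))
accuracy <- function(truth, estimate) {
  if (length(truth) == 0) abort("empty input.")
  if (length(truth) != length(estimate)) abort("length mismatch.")
  mean(truth == estimate)
}

#' ROC curve points for a binary scoring
#'
#' Sweeps the decision threshold over every distinct score (plus a
#' sentinel above the maximum), counting true- and false-positive rates;
#' tied scores move as one group, producing the standard diagonal tie
#' segments.
#'
#' @param scores Numeric scores, higher meaning more positive.
#' @param labels Logical (or 0/1) labels; both classes must be present.
#' @return Tibble with `threshold`, `fpr`, `tpr`, ordered from (0, 0) to
#'   (1, 1).
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    abort("AUC undefined: both classes must be present.")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- !duplicated(grp, fromLast = TRUE)
  tibble::tibble(threshold = c(Inf, s[last]),
                 fpr = c(0, fp[last] / n_neg),
                 tpr = c(0, tp[last] / n_pos))
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

#' One-vs-rest ROC AUC and its macro average
#'
#' `auc_ovr()` scores class `class_index` against the rest using that
#' class's predicted probability and integrates the ROC curve by the
#' trapezoidal rule, which equals the rank (Mann-Whitney) statistic:
#' concordant pairs plus half the ties, divided by `n_pos * n_neg`.
#' `macro_auc()` averages the per-class AUCs arithmetically.
#'
#' @param probabilities `N x n_classes` matrix (or data frame) of class
#'   probabilities, columns ordered by 0-based class index.
#' @param labels Integer class labels in `[0, n_classes)`.
#' @param class_index 0-based class to treat as positive.
#' @return `auc_ovr()`: a single AUC. `macro_auc()`: the mean over classes.
#' @export
auc_ovr <- function(probabilities, labels, class_index) {
  probabilities <- as.matrix(probabilities)
  if (!any(labels == class_index)) {
    abort(sprintf("class %d absent from `labels`; AUC undefined.", class_index))
  }
  pts <- roc_points(probabilities[, class_index + 1L], labels == class_index)
  trapezoid_auc(pts$fpr, pts$tpr)
}

#' @rdname auc_ovr
#' @param classes 0-based class indices to average over (default: all
#'   columns of `probabilities`).
#' @export
macro_auc <- function(probabilities, labels, classes = NULL) {
  probabilities <- as.matrix(probabilities)
  if (is.null(classes)) classes <- seq_len(ncol(probabilities)) - 1L
  absent <- setdiff(classes, unique(labels))
  if (length(absent) > 0) {
    abort(sprintf("classes absent from `labels`: %s.",
                  paste(absent, collapse = ", ")))
  }
  mean(vapply(classes, function(k) auc_ovr(probabilities, labels, k),
              numeric(1)))
}

#' Evaluate predicted probabilities against true labels
#'
#' Builds the standard report: overall accuracy (argmax prediction, lowest
#' index wins ties, unless `estimate` is supplied), one-vs-rest AUC per
#' class, their arithmetic mean, and the confusion table.  For a cascade,
#' pass the *final* probability vectors (small-stream for exited samples,
#' large-stream for escalated ones), e.g. the `probs` column of
#' [cascade_predict()].
#'
#' @param truth Integer labels in `[0, n_classes)`.
#' @param probabilities `N x n_classes` matrix, or a list of probability
#'   vectors (a `probs` list-column).
#' @param estimate Optional predicted labels overriding the argmax.
#' @return An `eval_report`: list with `accuracy`, `per_class_auc` (named
#'   vector), `average_auc`, `n_samples`, `confusion` (n x n count matrix,
#'   true classes in rows) and `roc` (tibble of per-class ROC points).
#' @export
evaluate_predictions <- function(truth, probabilities, estimate = NULL) {
  if (is.list(probabilities) && !is.data.frame(probabilities)) {
    probabilities <- do.call(rbind, probabilities)
  }
  probabilities <- as.matrix(probabilities)
  n_classes <- ncol(probabilities)
  if (is.null(estimate)) estimate <- apply(probabilities, 1, which.max) - 1L
  classes <- seq_len(n_classes) - 1L
  per_class <- vapply(classes, function(k) auc_ovr(probabilities, truth, k),
                      numeric(1))
  names(per_class) <- as.character(classes)
  confusion <- table(factor(truth, levels = classes),
                     factor(estimate, levels = classes))
  confusion <- matrix(as.integer(confusion), n_classes, n_classes,
                      dimnames = list(truth = classes, estimate = classes))
  roc <- dplyr::bind_rows(lapply(classes, function(k) {
    pts <- roc_points(probabilities[, k + 1L], truth == k)
    pts$class <- k
    pts
  }))
  structure(list(accuracy = accuracy(truth, estimate),
                 per_class_auc = per_class,
                 average_auc = mean(per_class),
                 n_samples = length(truth),
                 confusion = confusion, roc = roc),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d, accuracy = %.4f, average AUC = %.4f\n",
              x$n_samples, x$accuracy, x$average_auc))
  invisible(x)
}

#' Serialize an evaluation report
#'
#' @param report An `eval_report`.
#' @param json_path JSON output (accuracy, per-class and average AUC).
#' @param confusion_csv_path Optional CSV for the confusion table.
#' @export
write_eval_report <- function(report, json_path,
                              confusion_csv_path = NULL) {
  jsonlite::write_json(list(accuracy = report$accuracy,
                            per_class_auc = as.list(report$per_class_auc),
                            average_auc = report$average_auc,
                            n_samples = report$n_samples),
                       json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(confusion_csv_path)) {
    utils::write.csv(report$confusion, confusion_csv_path)
  }
  invisible(report)
}
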