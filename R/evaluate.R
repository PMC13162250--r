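#' Confusion matrix with row-normalised percentages
#'
#' Counts with the true class by row and the predicted class by column, plus
#' row percentages (each row sums to 100 for classes that occur).
#'
#' @param predicted,truth factors or characters over the class set.
#' @param classes class levels (default the four particle classes).
#' @return an object of class `confusion_matrix`: list with integer
#'   `counts` and numeric `percent` matrices.
#' @export
confusion_matrix <- function(predicted, truth,
                             classes = particle_classes()) {
  if (!length(predicted) || length(predicted) != length(truth))
    stop("predictions and labels must be non-empty and of equal length")
  predicted <- factor(predicted, levels = classes)
  truth <- factor(truth, levels = classes)
  if (anyNA(predicted) || anyNA(truth))
    stop("labels outside the class set")
  counts <- table(truth = truth, predicted = predicted)
  counts <- matrix(as.integer(counts), nrow = length(classes),
                   dimnames = list(truth = classes, predicted = classes))
  rs <- rowSums(counts)
  percent <- 100 * counts / ifelse(rs == 0, 1, rs)
  structure(list(counts = counts, percent = percent), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, digits = 1, ...) {
  cat("Confusion matrix (row %):\n")
  print(round(x$percent, digits))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Per-class accuracy is the recall (row-normalised diagonal); the mean
#' accuracy is the unweighted mean of the four recalls.  F1 combines recall
#' with precision (column-normalised diagonal; a never-predicted class gets
#' precision 0).  When per-sample probabilities are supplied, the mean
#' confidence of a class averages the predictor's maximum probability over
#' all samples *predicted* as that class, correct or not.
#'
#' @param cm a `confusion_matrix`.
#' @param probabilities optional data frame from
#'   [predict.filament_cnn()] (columns `predicted` and `confidence`).
#' @return an object of class `metrics_report`: list with `per_class`
#'   (data frame: class, n, recall_pct, precision, f1, mean_confidence),
#'   `mean_accuracy_pct` and `mean_f1`.
#' @export
classification_metrics <- function(cm, probabilities = NULL) {
  stopifnot(inherits(cm, "confusion_matrix"))
  counts <- cm$counts
  classes <- rownames(counts)
  n_true <- rowSums(counts)
  if (any(n_true == 0))
    warning("class(es) absent from the truth set: ",
            paste(classes[n_true == 0], collapse = ", "))
  recall <- diag(counts) / ifelse(n_true == 0, NA, n_true)
  n_pred <- colSums(counts)
  precision <- ifelse(n_pred == 0, 0, diag(counts) / n_pred)
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  conf <- rep(NA_real_, length(classes))
  if (!is.null(probabilities)) {
    for (i in seq_along(classes)) {
      sel <- probabilities$predicted == classes[i]
      if (any(sel)) conf[i] <- mean(probabilities$confidence[sel])
    }
  }
  per_class <- data.frame(class = classes, n = as.integer(n_true),
                          recall_pct = 100 * recall, precision = precision,
                          f1 = f1, mean_confidence = conf, row.names = NULL)
  structure(list(per_class = per_class,
                 mean_accuracy_pct = mean(100 * recall, na.rm = TRUE),
                 mean_f1 = mean(f1, na.rm = TRUE)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Per-class metrics:\n")
  print(transform(x$per_class, recall_pct = round(recall_pct, 1),
                  precision = round(precision, 3), f1 = round(f1, 3),
                  mean_confidence = round(mean_confidence, 3)),
        row.names = FALSE)
  cat(sprintf("Mean accuracy: %.1f%%   Mean F1: %.3f\n",
              x$mean_accuracy_pct, x$mean_f1))
  invisible(x)
}
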