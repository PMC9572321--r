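#' Confusion matrix in ripeness display order
#'
#' Rows are actual classes, columns predicted, both in the fixed display
#' order.
#'
#' @param actual,predicted label vectors of equal length.
#' @return 4 x 4 integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(actual, predicted) {
  actual <- ripeness_factor(actual)
  predicted <- ripeness_factor(predicted)
  if (length(actual) != length(predicted) || length(actual) < 1)
    stop("actual and predicted must have equal positive length")
  m <- base::table(actual = actual, predicted = predicted)
  m <- matrix(as.integer(m), nrow(m), ncol(m), dimnames = dimnames(m))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Enter a confusion matrix by hand
#'
#' @param counts 4 x 4 nonnegative counts, rows actual, columns predicted,
#'   display order.
#' @return `confusion_matrix`.
#' @export
as_confusion <- function(counts) {
  counts <- as.matrix(counts)
  cls <- ripeness_classes()
  stopifnot(identical(dim(counts), c(4L, 4L)), all(counts >= 0),
            all(counts == round(counts)))
  dimnames(counts) <- list(actual = cls, predicted = cls)
  structure(matrix(as.integer(counts), 4, 4, dimnames = dimnames(counts)),
            class = c("confusion_matrix", "matrix"))
}

#' Correct classification rate
#'
#' @param cm a `confusion_matrix`.
#' @return Percent of samples on the diagonal, `100 * trace / total`.
#' @export
ccr <- function(cm) {
  tot <- sum(cm)
  if (tot == 0) stop("empty confusion matrix")
  100 * sum(diag(cm)) / tot
}

#' Misclassification fraction of a hard classifier
#'
#' The fraction of off-diagonal samples, `1 - trace/total` — the "MSE"
#' convention used for hard LDA/QDA classifiers, distinct from
#' [output_mse()] for continuous network outputs.
#'
#' @param cm a `confusion_matrix`.
#' @return Misclassified / total.
#' @export
classifier_mse <- function(cm) {
  tot <- sum(cm)
  if (tot == 0) stop("empty confusion matrix")
  1 - sum(diag(cm)) / tot
}

#' Mean squared error of continuous outputs against one-hot targets
#'
#' @param targets,outputs numeric matrices of equal shape.
#' @return Mean over all entries of the squared difference.
#' @export
output_mse <- function(targets, outputs) {
  targets <- as.matrix(targets); outputs <- as.matrix(outputs)
  if (!identical(dim(targets), dim(outputs))) stop("shape mismatch")
  mean((targets - outputs)^2)
}

#' Correlation of continuous outputs with one-hot targets
#'
#' Pearson correlation between the flattened target and output matrices
#' (membership coded 1, non-membership 0).
#'
#' @param targets,outputs numeric matrices of equal shape.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
output_correlation <- function(targets, outputs) {
  targets <- as.vector(as.matrix(targets))
  outputs <- as.vector(as.matrix(outputs))
  if (length(targets) != length(outputs)) stop("shape mismatch")
  if (stats::sd(targets) == 0 || stats::sd(outputs) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(targets, outputs)
}

#' Evaluate a fitted classifier on a feature table
#'
#' Builds the confusion matrix and the CCR/MSE (and, for the network, the
#' correlation of continuous outputs with one-hot targets) either over the
#' whole dataset or the test partition only.
#'
#' @param model a `discrim` or `ripeness_ann`.
#' @param table feature table with `class`.
#' @param scope `"all_data"` or `"test_only"`; `"test_only"` needs a
#'   partition (`part` or, for the network, the stored one).
#' @param part optional partition factor from [split_assign()].
#' @return Object of class `evaluation_report`: list with `confusion`,
#'   `ccr`, `mse`, `r` (networks only, else `NA`), and `scope`.
#' @export
evaluate_classifier <- function(model, table,
                                scope = c("all_data", "test_only"),
                                part = NULL) {
  scope <- match.arg(scope)
  y <- ripeness_factor(table$class)
  keep <- rep(TRUE, length(y))
  if (scope == "test_only") {
    if (is.null(part) && inherits(model, "ripeness_ann"))
      part <- model$partition
    if (is.null(part)) stop("test_only scope needs a partition")
    keep <- part == "test"
  }
  pred <- predict(model, table[keep, , drop = FALSE])
  cm <- confusion(y[keep], pred)
  r <- NA_real_
  mse <- classifier_mse(cm)
  if (inherits(model, "ripeness_ann")) {
    raw <- predict(model, table[keep, , drop = FALSE], type = "raw")
    r <- output_correlation(one_hot(y[keep]), raw)
    mse <- output_mse(one_hot(y[keep]), raw)
  }
  structure(list(confusion = cm, ccr = ccr(cm), mse = mse, r = r,
                 scope = scope),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation (", x$scope, ")\n", sep = "")
  print(unclass(x$confusion))
  cat(sprintf("CCR = %.2f%%, MSE = %.4f", x$ccr, x$mse))
  if (is.finite(x$r)) cat(sprintf(", r = %.4f", x$r))
  cat("\n")
  invisible(x)
}

#' Write an evaluation report to JSON
#'
#' @param report an `evaluation_report`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(
    list(scope = report$scope, ccr = report$ccr, mse = report$mse,
         r = report$r, confusion = unclass(report$confusion)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
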