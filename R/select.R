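#' The 16-feature reference subset
#'
#' The optimum feature subset reported for the original four-stage study:
#' means, skewnesses and kurtoses drawn from the B, L*, b*, nr/ng/nb,
#' I2/I3, cr/cb, H and S channels. Provided as a fixed registry so models
#' can be trained on this subset without re-running selection.
#'
#' @return Character vector of 16 feature names.
#' @export
optimum_features <- function() {
  c("mean_B", "skewness_Lstar", "kurtosis_Lstar", "mean_bstar",
    "mean_nr", "mean_ng", "skewness_ng", "mean_nb",
    "mean_I2", "mean_I3", "kurtosis_I3",
    "mean_cr", "mean_cb", "skewness_cb", "mean_H", "mean_S")
}

#' Resolve feature names against the canonical registry
#'
#' @param names character vector of feature names.
#' @return Integer column indices into [feature_registry()].
#' @export
resolve_feature_names <- function(names) {
  reg <- feature_registry()
  idx <- match(names, reg)
  if (anyNA(idx)) {
    bad <- names[is.na(idx)]
    near <- vapply(bad, function(b) {
      d <- utils::adist(b, reg)
      paste(reg[order(d)[1:3]], collapse = ", ")
    }, "")
    stop("unknown feature name(s): ",
         paste(sprintf("'%s' (nearest: %s)", bad, near), collapse = "; "))
  }
  idx
}

# stratified cross-validated QDA misclassification rate of a feature subset
.cv_qda_error <- function(x, y, folds, reg) {
  wrong <- 0L
  for (f in sort(unique(folds))) {
    te <- folds == f
    tab_tr <- data.frame(class = y[!te], x[!te, , drop = FALSE],
                         check.names = FALSE)
    m <- fit_discriminant(tab_tr, subset = colnames(x), kind = "qda",
                          reg = reg, standardize = TRUE)
    pred <- predict(m, x[te, , drop = FALSE])
    wrong <- wrong + sum(pred != y[te])
  }
  wrong / length(y)
}

#' Forward sequential feature selection with a QDA criterion
#'
#' Greedy forward selection over the feature columns: at each step the
#' candidate minimizing the stratified k-fold cross-validated QDA
#' misclassification rate of the augmented subset is added; selection
#' stops when no candidate strictly improves the criterion, or at
#' `max_features`. Features are z-scored on the training folds inside the
#' QDA fit; candidate ties break by canonical registry order; the fold
#' assignment is fixed once from the seed, so the trace is deterministic.
#'
#' @param table feature table as from [extract_table()].
#' @param max_features optional cap on the subset size.
#' @param cv_folds folds of the stratified cross-validation criterion.
#' @param seed integer seed controlling the fold assignment.
#' @param reg ridge regularization passed to the QDA fits.
#' @return Object of class `selection_trace`: list with `selected`
#'   (ordered names), `steps` (data frame of accepted steps with the
#'   criterion path), `criterion`, `cv_folds`, `seed`.
#' @export
sfs_quadratic <- function(table, max_features = NULL, cv_folds = 5L,
                          seed = 1L, reg = 1e-6) {
  y <- ripeness_factor(table$class)
  feat <- intersect(feature_registry(), colnames(table))
  if (length(feat) == 0)
    feat <- setdiff(colnames(table), c("image_id", "class"))
  x <- as.matrix(table[, feat, drop = FALSE])
  storage.mode(x) <- "double"
  nk <- base::table(y)
  if (length(nk) < 2 || any(nk < cv_folds))
    stop("each class needs at least cv_folds samples")
  if (is.null(max_features)) max_features <- length(feat)

  # fixed stratified fold assignment
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(cv_folds), length(idx))
  }

  selected <- character(0)
  crit <- Inf
  steps <- list()
  while (length(selected) < max_features) {
    cand <- setdiff(feat, selected)
    if (length(cand) == 0) break
    errs <- vapply(cand, function(f)
      .cv_qda_error(x[, c(selected, f), drop = FALSE], y, folds, reg),
      numeric(1))
    best <- which.min(errs)   # ties -> first in registry order
    if (errs[best] >= crit) break
    selected <- c(selected, cand[best])
    crit <- errs[best]
    steps[[length(steps) + 1L]] <-
      data.frame(feature = cand[best], criterion = crit)
    if (crit == 0) break
  }
  structure(list(selected = selected,
                 steps = do.call(rbind, steps),
                 criterion = "qda_cv_error",
                 cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("forward selection (", x$criterion, ", ", x$cv_folds,
      "-fold): ", length(x$selected), " features\n", sep = "")
  if (!is.null(x$steps)) print(x$steps, row.names = FALSE)
  invisible(x)
}

#' Serialize a selection trace to JSON
#'
#' @param trace a `selection_trace`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_selection_trace <- function(trace, path) {
  jsonlite::write_json(
    list(selected = trace$selected, steps = trace$steps,
         criterion = trace$criterion, cv_folds = trace$cv_folds,
         seed = trace$seed),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
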