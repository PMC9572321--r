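#' Fit a linear or quadratic discriminant classifier
#'
#' Gaussian class-conditional model over a feature subset: per-class mean
#' vectors with a pooled within-class covariance (LDA) or per-class
#' covariances (QDA). Features are z-scored (training statistics) before
#' fitting by default, and a ridge `reg * I` is added to any covariance
#' whose smallest eigenvalue falls below 1e-8.
#'
#' @param table data frame with a `class` column plus feature columns, as
#'   from [extract_table()].
#' @param subset character vector of feature names to use; default all
#'   feature columns.
#' @param kind `"lda"` or `"qda"`.
#' @param reg ridge added to near-singular covariances (on the z-scored
#'   scale); 0 disables regularization.
#' @param priors per-class prior probabilities in display order; default
#'   the empirical class frequencies.
#' @param standardize z-score features with training mean/sd.
#' @return Object of class `discrim`.
#' @seealso [predict.discrim()]
#' @export
fit_discriminant <- function(table, subset = NULL,
                             kind = c("lda", "qda"),
                             reg = 1e-6, priors = NULL,
                             standardize = TRUE) {
  kind <- match.arg(kind)
  stopifnot(reg >= 0)
  y <- droplevels(ripeness_factor(table$class))
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (is.null(subset))
    subset <- setdiff(colnames(table), c("image_id", "class"))
  x <- as.matrix(table[, subset, drop = FALSE])
  storage.mode(x) <- "double"
  cls <- levels(y)
  nk <- base::table(y)
  if (any(nk < 2)) stop("every class needs at least 2 training samples")
  if (is.null(priors)) priors <- as.numeric(nk) / sum(nk)
  stopifnot(length(priors) == length(cls), abs(sum(priors) - 1) < 1e-8)
  ctr <- if (standardize) colMeans(x) else rep(0, ncol(x))
  # population scale so the fit is invariant to sample duplication
  scl <- if (standardize)
    sqrt(colMeans(sweep(x, 2, colMeans(x))^2)) else rep(1, ncol(x))
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  means <- do.call(rbind, lapply(cls, function(cl)
    colMeans(xs[y == cl, , drop = FALSE])))
  rownames(means) <- cls
  regularize <- function(S) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-8) {
      if (reg <= 0)
        stop("singular covariance; set reg > 0 to regularize")
      S <- S + diag(reg, ncol(S))
    }
    S
  }
  # maximum-likelihood (plug-in) covariance estimates: within-class scatter
  # over n, so duplicating the training set leaves the model unchanged
  if (kind == "lda") {
    pooled <- matrix(0, ncol(xs), ncol(xs))
    for (cl in cls) {
      xc <- xs[y == cl, , drop = FALSE]
      pooled <- pooled + crossprod(sweep(xc, 2, colMeans(xc)))
    }
    covs <- list(pooled = regularize(pooled / nrow(xs)))
  } else {
    covs <- lapply(cls, function(cl) {
      xc <- xs[y == cl, , drop = FALSE]
      regularize(crossprod(sweep(xc, 2, colMeans(xc))) / nrow(xc))
    })
    names(covs) <- cls
  }
  structure(list(kind = kind, classes = cls, class_means = means,
                 covariances = covs, priors = priors, reg = reg,
                 feature_subset = subset,
                 standardization = list(center = ctr, scale = scl)),
            class = "discrim")
}

# per-class Gaussian log-posterior scores (up to the shared constant)
.discrim_scores <- function(object, xs) {
  cls <- object$classes
  scores <- matrix(NA_real_, nrow(xs), length(cls),
                   dimnames = list(NULL, cls))
  for (k in seq_along(cls)) {
    S <- if (object$kind == "lda") object$covariances$pooled
         else object$covariances[[k]]
    ch <- chol(S)
    d <- sweep(xs, 2, object$class_means[k, ])
    z <- backsolve(ch, t(d), transpose = TRUE)
    scores[, k] <- log(object$priors[k]) - sum(log(diag(ch))) -
      0.5 * colSums(z^2)
  }
  scores
}

#' Predict ripeness classes from a discriminant model
#'
#' Classifies by the maximum Gaussian log-posterior; ties resolve to the
#' class earlier in display order.
#'
#' @param object a `discrim` model.
#' @param newdata data frame or matrix containing the model's feature
#'   subset.
#' @param type `"class"` for the label factor, `"scores"` for the per-class
#'   log-posterior score matrix.
#' @param ... unused.
#' @return Factor of predicted classes, or the score matrix.
#' @export
predict.discrim <- function(object, newdata,
                            type = c("class", "scores"), ...) {
  type <- match.arg(type)
  missing_f <- setdiff(object$feature_subset, colnames(newdata))
  if (length(missing_f) > 0)
    stop("missing feature(s): ", paste(missing_f, collapse = ", "))
  x <- as.matrix(as.data.frame(newdata)[, object$feature_subset,
                                        drop = FALSE])
  storage.mode(x) <- "double"
  xs <- sweep(sweep(x, 2, object$standardization$center), 2,
              object$standardization$scale, "/")
  scores <- .discrim_scores(object, xs)
  if (type == "scores") return(scores)
  factor(object$classes[apply(scores, 1, which.max)],
         levels = object$classes)
}

#' @export
print.discrim <- function(x, ...) {
  cat(toupper(x$kind), "classifier:", length(x$feature_subset),
      "features,", length(x$classes), "classes\n")
  cat("priors:", paste(sprintf("%s=%.3f", x$classes, x$priors),
                       collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.discrim <- function(object, ...) {
  print(object)
  cat("\nclass means (standardized scale):\n")
  print(round(object$class_means, 4))
  invisible(object)
}

#' @export
coef.discrim <- function(object, ...) object$class_means
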