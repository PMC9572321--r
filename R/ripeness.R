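#' Ripeness stage registry
#'
#' The four maturity stages a fruit is graded into, in the fixed display
#' order used throughout the package for one-hot encoding and
#' confusion-matrix axes: overripe, ripe, secondary unripe, initial unripe.
#'
#' @return Character vector of the four stage identifiers, in display order.
#' @examples
#' ripeness_classes()
#' @export
ripeness_classes <- function() {
  c("overripe", "ripe", "secondary_unripe", "initial_unripe")
}

#' Coerce labels to the canonical ripeness factor
#'
#' @param x character or factor of stage labels.
#' @return Factor with levels in display order.
#' @export
ripeness_factor <- function(x) {
  lv <- ripeness_classes()
  x <- as.character(x)
  bad <- setdiff(unique(x), lv)
  if (length(bad) > 0L) {
    stop("unknown ripeness label(s): ", paste(bad, collapse = ", "))
  }
  factor(x, levels = lv)
}

#' One-hot encode ripeness labels
#'
#' Rows are samples, columns the four stages in display order; 1 marks
#' membership, 0 non-membership.
#'
#' @param y labels coercible by [ripeness_factor()].
#' @return Numeric matrix, n x 4.
#' @export
one_hot <- function(y) {
  f <- ripeness_factor(y)
  m <- matrix(0, length(f), nlevels(f), dimnames = list(NULL, levels(f)))
  m[cbind(seq_along(f), as.integer(f))] <- 1
  m
}
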