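#' Training configuration for the neural network
#'
#' @param max_epochs maximum full-batch epochs.
#' @param early_stop_patience epochs without validation-MSE improvement
#'   before stopping.
#' @param seed integer seed for weight initialization.
#' @return Object of class `train_config`.
#' @export
train_config <- function(max_epochs = 400L, early_stop_patience = 6L,
                         seed = 1L) {
  stopifnot(max_epochs >= 1, early_stop_patience >= 1)
  structure(list(max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed),
                 optimizer = "rprop-"),
            class = "train_config")
}

# forward pass on already-scaled inputs: list(hidden, output)
.ann_forward <- function(w, x) {
  h <- tanh(x %*% t(w$W1) + matrix(w$b1, nrow(x), length(w$b1),
                                   byrow = TRUE))
  y <- h %*% t(w$W2) + matrix(w$b2, nrow(x), length(w$b2), byrow = TRUE)
  list(hidden = h, output = y)
}

.ann_scale <- function(x, scaling) {
  rng <- scaling$max - scaling$min
  rng[rng == 0] <- 1
  sweep(sweep(x, 2, scaling$min), 2, rng, "/") * 2 - 1
}

#' Train a single-hidden-layer ripeness network
#'
#' A multilayer perceptron with `n_hidden` tangent-sigmoid hidden units and
#' four linear output units, trained by full-batch resilient
#' backpropagation (Rprop-) on the mean squared error against one-hot
#' class targets. Inputs are min-max scaled to `[-1, 1]` (training-set
#' statistics). Training stops early when the validation MSE has not
#' improved for `early_stop_patience` epochs, and the weights of the best
#' validation epoch are restored. Deterministic given the seeds.
#'
#' @param table feature table as from [extract_table()].
#' @param subset feature names used as inputs; default all feature columns.
#' @param n_hidden hidden units, between 2 and 20.
#' @param split a [split_config()] with train/validation/test ratios
#'   (default 60:20:20).
#' @param cfg a [train_config()].
#' @return Object of class `ripeness_ann` with the weights, scaling,
#'   partition assignment and per-epoch `history` (train and validation
#'   MSE).
#' @export
train_ann <- function(table, subset = NULL, n_hidden = 10L,
                      split = split_config(c(train = 0.6, validation = 0.2,
                                             test = 0.2)),
                      cfg = train_config()) {
  stopifnot(n_hidden >= 2, n_hidden <= 20)
  if (!all(c("train", "validation") %in% names(split$ratios)))
    stop("split must provide train and validation partitions")
  y <- ripeness_factor(table$class)
  if (is.null(subset))
    subset <- setdiff(colnames(table), c("image_id", "class"))
  x <- as.matrix(table[, subset, drop = FALSE])
  storage.mode(x) <- "double"
  part <- split_assign(y, split)
  tr <- part == "train"; va <- part == "validation"
  if (sum(tr) == 0 || sum(va) == 0)
    stop("train and validation partitions must be nonempty")
  scaling <- list(min = apply(x[tr, , drop = FALSE], 2, min),
                  max = apply(x[tr, , drop = FALSE], 2, max))
  xs <- .ann_scale(x, scaling)
  tgt <- one_hot(y)
  xtr <- xs[tr, , drop = FALSE]; ttr <- tgt[tr, , drop = FALSE]
  xva <- xs[va, , drop = FALSE]; tva <- tgt[va, , drop = FALSE]
  d <- ncol(xs); K <- ncol(tgt)

  set.seed(cfg$seed)
  w <- list(W1 = matrix(stats::rnorm(n_hidden * d, sd = 1 / sqrt(d)),
                        n_hidden, d),
            b1 = rep(0, n_hidden),
            W2 = matrix(stats::rnorm(K * n_hidden, sd = 1 / sqrt(n_hidden)),
                        K, n_hidden),
            b2 = rep(0, K))

  grad <- function(w) {
    f <- .ann_forward(w, xtr)
    e <- f$output - ttr
    n <- nrow(xtr) * K
    dY <- 2 * e / n
    dH <- (dY %*% w$W2) * (1 - f$hidden^2)
    list(W1 = t(dH) %*% xtr, b1 = colSums(dH),
         W2 = t(dY) %*% f$hidden, b2 = colSums(dY))
  }
  mse <- function(w, xx, tt) mean((.ann_forward(w, xx)$output - tt)^2)

  # Rprop-: per-parameter step sizes adapted by gradient sign agreement
  delta <- lapply(w, function(p) p * 0 + 0.01)
  gprev <- lapply(w, function(p) p * 0)
  best <- list(w = w, val = Inf, epoch = 0L)
  hist_tr <- hist_va <- numeric(cfg$max_epochs)
  stall <- 0L
  epoch <- 0L
  while (epoch < cfg$max_epochs) {
    epoch <- epoch + 1L
    g <- grad(w)
    for (p in names(w)) {
      sgn <- sign(g[[p]] * gprev[[p]])
      delta[[p]] <- pmin(pmax(delta[[p]] *
        ifelse(sgn > 0, 1.2, ifelse(sgn < 0, 0.5, 1)), 1e-9), 1)
      w[[p]] <- w[[p]] - sign(g[[p]]) * delta[[p]]
    }
    gprev <- g
    hist_tr[epoch] <- mse(w, xtr, ttr)
    hist_va[epoch] <- mse(w, xva, tva)
    if (!is.finite(hist_tr[epoch]))
      stop("diverged; reduce step size")
    if (hist_va[epoch] < best$val - 1e-12) {
      best <- list(w = w, val = hist_va[epoch], epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$early_stop_patience) break
    }
  }
  history <- data.frame(epoch = seq_len(epoch),
                        train_mse = hist_tr[seq_len(epoch)],
                        validation_mse = hist_va[seq_len(epoch)])
  structure(list(n_input = d, n_hidden = as.integer(n_hidden), n_output = K,
                 weights = best$w, input_scaling = scaling,
                 feature_subset = subset, classes = levels(y),
                 partition = part, best_epoch = best$epoch,
                 validation_mse = best$val, history = history,
                 split = split, config = cfg),
            class = "ripeness_ann")
}

#' Predict with a ripeness network
#'
#' @param object a `ripeness_ann`.
#' @param newdata data frame or matrix with the model's input features.
#' @param type `"class"` for labels (argmax of the four linear outputs,
#'   ties to the earlier display class) or `"raw"` for the continuous
#'   outputs.
#' @param ... unused.
#' @return Factor of classes, or an n x 4 output matrix.
#' @export
predict.ripeness_ann <- function(object, newdata,
                                 type = c("class", "raw"), ...) {
  type <- match.arg(type)
  if (is.matrix(newdata) && is.null(colnames(newdata))) {
    if (ncol(newdata) != object$n_input) stop("feature dimension mismatch")
    x <- newdata
  } else {
    missing_f <- setdiff(object$feature_subset, colnames(newdata))
    if (length(missing_f) > 0)
      stop("missing feature(s): ", paste(missing_f, collapse = ", "))
    x <- as.matrix(as.data.frame(newdata)[, object$feature_subset,
                                          drop = FALSE])
  }
  storage.mode(x) <- "double"
  out <- .ann_forward(object$weights, .ann_scale(x, object$input_scaling))$output
  colnames(out) <- object$classes
  if (type == "raw") return(out)
  factor(object$classes[apply(out, 1, which.max)], levels = object$classes)
}

#' @export
print.ripeness_ann <- function(x, ...) {
  cat(sprintf("ripeness_ann %d-%d-%d (tanh hidden, linear output)\n",
              x$n_input, x$n_hidden, x$n_output))
  cat(sprintf("best epoch %d, validation MSE %.5f\n",
              x$best_epoch, x$validation_mse))
  invisible(x)
}

#' @export
summary.ripeness_ann <- function(object, ...) {
  print(object)
  cat("partition sizes:\n")
  print(base::table(object$partition))
  invisible(object)
}

#' Scan hidden-layer sizes
#'
#' Trains one network per hidden-layer size and reports, for each
#' structure, the (best-epoch) validation MSE, the Pearson correlation of
#' the flattened test outputs with the one-hot test targets, and the
#' correct classification rate over the whole dataset; a test-only CCR is
#' reported alongside. The optimum is the structure with the highest
#' whole-dataset CCR, ties broken by higher test correlation, then lower
#' validation MSE.
#'
#' @inheritParams train_ann
#' @param hidden_range integer vector of hidden sizes (default `2:20`).
#' @return Object of class `ann_scan`: list with `report` (one row per
#'   structure), `best_hidden`, `best_model`, and `models`.
#' @export
scan_structures <- function(table, subset = NULL, hidden_range = 2:20,
                            split = split_config(c(train = 0.6,
                                                   validation = 0.2,
                                                   test = 0.2)),
                            cfg = train_config()) {
  stopifnot(length(hidden_range) >= 1, all(hidden_range >= 2),
            all(hidden_range <= 20))
  y <- ripeness_factor(table$class)
  tgt <- one_hot(y)
  models <- vector("list", length(hidden_range))
  rows <- vector("list", length(hidden_range))
  for (i in seq_along(hidden_range)) {
    h <- hidden_range[i]
    m <- train_ann(table, subset, n_hidden = h, split = split, cfg = cfg)
    te <- m$partition == "test"
    pred_all <- predict(m, table)
    r_test <- ccr_test <- NA_real_
    if (any(te)) {
      raw_te <- predict(m, table[te, , drop = FALSE], type = "raw")
      r_test <- output_correlation(tgt[te, , drop = FALSE], raw_te)
      ccr_test <- ccr(confusion(y[te], pred_all[te]))
    }
    cm_all <- confusion(y, pred_all)
    rows[[i]] <- data.frame(
      structure = sprintf("%d-%d-%d", m$n_input, h, m$n_output),
      n_hidden = h,
      mse_validation = m$validation_mse,
      r_test = r_test,
      ccr_all = ccr(cm_all),
      ccr_test = ccr_test)
    models[[i]] <- m
  }
  report <- do.call(rbind, rows)
  ord <- order(-report$ccr_all, -report$r_test, report$mse_validation)
  best <- ord[1]
  structure(list(report = report, best_hidden = report$n_hidden[best],
                 best_model = models[[best]], models = models),
            class = "ann_scan")
}

#' @export
print.ann_scan <- function(x, ...) {
  cat("ANN structure scan,", nrow(x$report), "structures\n")
  print(x$report[, c("structure", "mse_validation", "r_test", "ccr_all")],
        row.names = FALSE)
  cat("optimum:", x$report$structure[x$report$n_hidden == x$best_hidden],
      "\n")
  invisible(x)
}
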