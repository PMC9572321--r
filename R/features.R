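#' Names of the 15 per-channel statistics
#'
#' Nine first-order statistics of the masked pixel values and six texture
#' statistics of the masked gray-level co-occurrence matrix, in canonical
#' order.
#'
#' @return Character vector of length 15.
#' @export
statistic_names <- function() {
  c("min", "mean", "max", "std", "cv", "median", "mode",
    "skewness", "kurtosis",
    "homogeneity", "covariance", "contrast", "correlation",
    "entropy", "energy")
}

#' Canonical feature registry
#'
#' The 285 feature names `<statistic>_<channel>` in fixed column order:
#' channels in [channel_names()] order, the 15 statistics within each.
#'
#' @return Character vector of length 285.
#' @export
feature_registry <- function() {
  as.vector(vapply(channel_names(),
                   function(ch) paste0(statistic_names(), "_", ch),
                   character(15)))
}

#' First-order statistics of a sample
#'
#' Population standard deviation; `cv = std/mean` (0 when the mean is 0);
#' mode as the midpoint of the densest of 256 equal-width bins over the
#' sample range; skewness `m3/m2^1.5` and non-excess kurtosis `m4/m2^2`.
#' On a zero-variance sample, cv, skewness and kurtosis are 0 by
#' convention.
#'
#' @param values nonempty numeric vector of finite values.
#' @return Named numeric of length 9: min, mean, max, std, cv, median,
#'   mode, skewness, kurtosis.
#' @export
first_order_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty sample")
  if (any(!is.finite(values))) stop("non-finite values in sample")
  mu <- mean(values)
  d <- values - mu
  m2 <- mean(d^2)
  std <- sqrt(m2)
  rng <- range(values)
  if (diff(rng) > 0) {
    cnt <- tabulate(pmin(256L, findInterval(values,
      seq(rng[1], rng[2], length.out = 257L), rightmost.closed = TRUE)), 256L)
    k <- which.max(cnt)
    mode <- rng[1] + (k - 0.5) * diff(rng) / 256
  } else {
    mode <- values[1]
  }
  if (m2 > 0) {
    cv <- if (mu != 0) std / mu else 0
    skew <- mean(d^3) / m2^1.5
    kurt <- mean(d^4) / m2^2
  } else {
    cv <- skew <- kurt <- 0
  }
  c(min = rng[1], mean = mu, max = rng[2], std = std, cv = cv,
    median = stats::median(values), mode = mode,
    skewness = skew, kurtosis = kurt)
}

#' Co-occurrence configuration
#'
#' @param levels number of quantization levels (>= 2).
#' @param offsets list of nonzero `c(dy, dx)` pixel offsets; the default is
#'   the four distance-1 directions 0, 45, 90 and 135 degrees.
#' @param symmetric count each pair in both orders.
#' @return Object of class `glcm_config`.
#' @export
glcm_config <- function(levels = 8L,
                        offsets = list(c(0L, 1L), c(1L, 1L),
                                       c(1L, 0L), c(1L, -1L)),
                        symmetric = TRUE) {
  levels <- as.integer(levels)
  stopifnot(levels >= 2)
  for (o in offsets)
    if (length(o) != 2 || all(o == 0)) stop("offsets must be nonzero (dy,dx)")
  structure(list(levels = levels, offsets = offsets, symmetric = symmetric),
            class = "glcm_config")
}

# quantize masked values into 1..levels equal-width bins over the masked
# min-max range; NA outside the mask
.quantize <- function(channel, mask, levels) {
  q <- matrix(NA_integer_, nrow(channel), ncol(channel))
  v <- channel[mask]
  rng <- range(v)
  if (diff(rng) > 0) {
    q[mask] <- pmin(levels, 1L + as.integer(floor(
      (v - rng[1]) / diff(rng) * levels)))
  } else {
    q[mask] <- 1L
  }
  q
}

#' Masked gray-level co-occurrence matrix
#'
#' Quantizes the channel to `levels` equal-width bins over the masked
#' min-max range, counts pixel pairs whose both ends lie inside the mask,
#' symmetrizes, normalizes each offset's matrix to sum 1 and averages the
#' normalized matrices over offsets.
#'
#' @param channel H x W numeric matrix.
#' @param mask logical H x W matrix.
#' @param cfg a [glcm_config()].
#' @return `levels` x `levels` matrix summing to 1.
#' @export
glcm <- function(channel, mask, cfg = glcm_config()) {
  stopifnot(is.matrix(channel), is.matrix(mask),
            identical(dim(channel), dim(mask)))
  L <- cfg$levels
  q <- .quantize(channel, mask, L)
  h <- nrow(q); w <- ncol(q)
  acc <- matrix(0, L, L)
  used <- 0L
  total_pairs <- 0L
  for (o in cfg$offsets) {
    dy <- o[1]; dx <- o[2]
    r1 <- max(1, 1 - dy):min(h, h - dy)
    c1 <- max(1, 1 - dx):min(w, w - dx)
    if (length(r1) < 1 || length(c1) < 1) next
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dy, c1 + dx, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    n <- sum(ok)
    if (n == 0L) next
    total_pairs <- total_pairs + n
    cnt <- matrix(tabulate((a[ok] - 1L) * L + b[ok], L * L), L, L,
                  byrow = TRUE)
    if (cfg$symmetric) cnt <- cnt + t(cnt)
    acc <- acc + cnt / sum(cnt)
    used <- used + 1L
  }
  if (total_pairs < 2L) stop("degenerate region: fewer than 2 valid pairs")
  acc / used
}

#' Texture statistics of a co-occurrence matrix
#'
#' `contrast = sum p(i,j) (i-j)^2`; `homogeneity = sum p/(1+|i-j|)`;
#' `energy = sum p^2`; `entropy = -sum p log2 p`;
#' `covariance = sum p (i - mu_i)(j - mu_j)`; `correlation` is the
#' covariance normalized by the marginal standard deviations, 1 by
#' convention when either marginal is degenerate.
#'
#' @param P square matrix normalized to sum 1.
#' @return Named numeric of length 6: homogeneity, covariance, contrast,
#'   correlation, entropy, energy.
#' @export
texture_features <- function(P) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (abs(sum(P) - 1) > 1e-8) stop("co-occurrence matrix is not normalized")
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  pi_ <- rowSums(P); pj_ <- colSums(P)
  mi <- sum(seq_len(L) * pi_); mj <- sum(seq_len(L) * pj_)
  si <- sqrt(sum((seq_len(L) - mi)^2 * pi_))
  sj <- sqrt(sum((seq_len(L) - mj)^2 * pj_))
  cov <- sum(P * (i - mi) * (j - mj))
  corr <- if (si * sj > 0) cov / (si * sj) else 1
  pos <- P[P > 0]
  c(homogeneity = sum(P / (1 + abs(i - j))),
    covariance = cov,
    contrast = sum(P * (i - j)^2),
    correlation = corr,
    entropy = -sum(pos * log2(pos)),
    energy = sum(P^2))
}

#' Extract the 285 features of one image
#'
#' For each of the 19 channels: the nine first-order statistics of the
#' fruit pixels and the six texture statistics of the masked co-occurrence
#' matrix.
#'
#' @param x a `masked_image` or `channel_stack`.
#' @param cfg a [glcm_config()].
#' @return Named numeric of length 285, in [feature_registry()] order.
#' @export
extract_features <- function(x, cfg = glcm_config()) {
  if (inherits(x, "masked_image")) x <- to_channels(x)
  stopifnot(inherits(x, "channel_stack"))
  if (sum(x$mask) < 2L) stop("mask must contain at least 2 pixels")
  out <- unlist(lapply(channel_names(), function(nm) {
    ch <- x$channels[[nm]]
    fo <- first_order_stats(ch[x$mask])
    tx <- texture_features(glcm(ch, x$mask, cfg))
    v <- c(fo, tx)
    names(v) <- paste0(names(v), "_", nm)
    v
  }))
  stopifnot(identical(names(out), feature_registry()))
  out
}

#' Feature table of a labelled image set
#'
#' Segments nothing: the set's images are masked with their ground-truth
#' masks unless `masks` are supplied. Use [preprocess_pipeline()] first to
#' evaluate the full pipeline on raw images.
#'
#' @param set a `labeled_image_set`.
#' @param cfg a [glcm_config()].
#' @param masks optional list of logical masks overriding `set$masks`.
#' @return Data frame: `image_id`, `class`, then the 285 feature columns.
#' @export
extract_table <- function(set, cfg = glcm_config(), masks = NULL) {
  stopifnot(inherits(set, "labeled_image_set"))
  n <- length(set$images)
  if (n == 0L) stop("empty image set")
  if (is.null(masks)) masks <- set$masks
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- tryCatch(
      extract_features(apply_mask(set$images[[i]], masks[[i]]), cfg),
      error = function(e) stop("feature extraction failed for image ", i,
                               ": ", conditionMessage(e)))
  }
  tab <- as.data.frame(do.call(rbind, rows))
  data.frame(image_id = seq_len(n), class = set$labels, tab,
             check.names = FALSE)
}

#' Write / read a feature table as CSV
#'
#' @param table data frame from [extract_table()].
#' @param path CSV path.
#' @return `write_feature_table` the path invisibly; `read_feature_table`
#'   the table with `class` restored as the canonical factor.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  tab$class <- ripeness_factor(tab$class)
  tab
}
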