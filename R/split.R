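#' Split configuration
#'
#' Train/test (default 80:20) or train/validation/test (60:20:20)
#' partitions, stratified by class by default.
#'
#' @param ratios named numeric summing to 1; names from
#'   `c("train","validation","test")`.
#' @param stratified split within each class.
#' @param seed integer seed for the random assignment.
#' @return Object of class `split_config`.
#' @export
split_config <- function(ratios = c(train = 0.8, test = 0.2),
                         stratified = TRUE, seed = 1L) {
  stopifnot(all(ratios > 0), abs(sum(ratios) - 1) < 1e-8,
            all(names(ratios) %in% c("train", "validation", "test")))
  structure(list(ratios = ratios, stratified = stratified,
                 seed = as.integer(seed)),
            class = "split_config")
}

#' Assign samples to partitions
#'
#' Deterministic given the configuration seed. Within each stratum the
#' partition sizes follow the largest-remainder rule, so every partition
#' receives samples whenever the stratum is large enough.
#'
#' @param labels class labels.
#' @param cfg a [split_config()].
#' @return Factor of partition names, same length as `labels`.
#' @export
split_assign <- function(labels, cfg = split_config()) {
  labels <- as.factor(labels)
  n <- length(labels)
  parts <- names(cfg$ratios)
  out <- character(n)
  set.seed(cfg$seed)
  strata <- if (cfg$stratified) split(seq_len(n), labels)
            else list(seq_len(n))
  for (idx in strata) {
    idx <- idx[sample.int(length(idx))]
    k <- length(idx)
    share <- cfg$ratios * k
    sizes <- floor(share)
    extra <- order(share - sizes, decreasing = TRUE)
    n_extra <- k - sum(sizes)
    if (n_extra > 0) sizes[extra[seq_len(n_extra)]] <-
      sizes[extra[seq_len(n_extra)]] + 1L
    pos <- 0L
    for (p in seq_along(parts)) {
      if (sizes[p] > 0) out[idx[pos + seq_len(sizes[p])]] <- parts[p]
      pos <- pos + sizes[p]
    }
  }
  factor(out, levels = parts)
}
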