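# shared fixtures and independent oracles

# small scene for fast tests
tiny_scene <- function(seed = 11L, ...) {
  scene_config(image_size = c(80L, 100L), fruit_axes = c(16, 22),
               seed = seed, ...)
}

# memoized small labelled set (4 classes x per_class, small frames)
.fixture_env <- new.env(parent = emptyenv())
tiny_set <- function(per_class = 4L, seed = 11L) {
  key <- paste0("set_", per_class, "_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_dataset(default_profiles(), per_class,
                                            tiny_scene(seed))
  .fixture_env[[key]]
}

tiny_table <- function(per_class = 4L, seed = 11L) {
  key <- paste0("tab_", per_class, "_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- extract_table(tiny_set(per_class, seed))
  .fixture_env[[key]]
}

# brute-force GLCM oracle: explicit loop over every pixel and offset
glcm_bruteforce <- function(channel, mask, levels = 8L,
                            offsets = list(c(0L, 1L), c(1L, 1L),
                                           c(1L, 0L), c(1L, -1L)),
                            symmetric = TRUE) {
  v <- channel[mask]
  rng <- range(v)
  q <- matrix(NA_integer_, nrow(channel), ncol(channel))
  if (diff(rng) > 0) {
    q[mask] <- pmin(levels, 1L + as.integer(
      floor((channel[mask] - rng[1]) / diff(rng) * levels)))
  } else q[mask] <- 1L
  acc <- matrix(0, levels, levels)
  used <- 0L
  for (o in offsets) {
    cnt <- matrix(0, levels, levels)
    for (r in seq_len(nrow(q))) for (c in seq_len(ncol(q))) {
      r2 <- r + o[1]; c2 <- c + o[2]
      if (r2 < 1 || r2 > nrow(q) || c2 < 1 || c2 > ncol(q)) next
      if (is.na(q[r, c]) || is.na(q[r2, c2])) next
      cnt[q[r, c], q[r2, c2]] <- cnt[q[r, c], q[r2, c2]] + 1
    }
    if (symmetric) cnt <- cnt + t(cnt)
    if (sum(cnt) > 0) { acc <- acc + cnt / sum(cnt); used <- used + 1L }
  }
  acc / used
}

# independent sRGB (D65) -> CIELAB reference conversion
srgb_to_lab_ref <- function(rgb) {
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, byrow = TRUE)
  xyz <- as.vector(M %*% lin)
  wp <- c(0.95047, 1.0, 1.08883)
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3),
                          t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(xyz / wp)
  c(L = 116 * fx[2] - 16,
    a = 500 * (fx[1] - fx[2]),
    b = 200 * (fx[2] - fx[3]))
}

# Monte-Carlo oracle for the expected channel means of a colour profile
# under the scene's additive sensor noise
mc_channel_oracle <- function(profile, noise_sd, n = 200000L, seed = 4242L) {
  set.seed(seed)
  ch <- chol(profile$rgb_covariance + diag(noise_sd^2, 3))
  x <- matrix(rep(profile$mean_rgb, each = n), n) +
    matrix(stats::rnorm(3 * n), n) %*% ch
  x[x < 0] <- 0; x[x > 1] <- 1
  arr <- array(c(x[, 1], x[, 2], x[, 3]), dim = c(n, 1, 3))
  ch <- to_channels(arr)$channels
  list(mean = vapply(ch, mean, numeric(1)),
       se = vapply(ch, function(v) stats::sd(v) / sqrt(n), numeric(1)))
}

# circular disk / ellipse indicator for preprocess tests
.ellipse_helper <- function(h, w, center, radius) {
  rr <- matrix(seq_len(h), h, w) - center[1]
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - center[2]
  rr^2 + cc^2 <= radius^2
}
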