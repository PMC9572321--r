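# hexcone HSV -> RGB on [0,1] scalars (vectorized); inverse of rgb2hsv
.hsv2rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b, deparse.level = 0)
}

#' Colour profile of a ripeness class
#'
#' Describes the within-fruit colour distribution of one ripeness stage: a
#' mean RGB colour, a 3x3 covariance of the pixel-level colour fluctuation,
#' and the spatial correlation length (in pixels) of that fluctuation.
#'
#' @param class_id one of [ripeness_classes()].
#' @param mean_rgb length-3 numeric in `[0,1]`.
#' @param rgb_covariance symmetric positive semi-definite 3x3 matrix.
#' @param texture_scale nonnegative correlation length of the within-fruit
#'   colour noise, pixels.
#' @return Object of class `class_color_profile`.
#' @export
class_color_profile <- function(class_id, mean_rgb, rgb_covariance,
                                texture_scale = 2) {
  class_id <- match.arg(class_id, ripeness_classes())
  mean_rgb <- as.numeric(mean_rgb)
  stopifnot(length(mean_rgb) == 3, all(mean_rgb >= 0), all(mean_rgb <= 1))
  rgb_covariance <- as.matrix(rgb_covariance)
  stopifnot(identical(dim(rgb_covariance), c(3L, 3L)))
  if (max(abs(rgb_covariance - t(rgb_covariance))) > 1e-12)
    stop("rgb_covariance must be symmetric")
  if (min(eigen(rgb_covariance, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-12)
    stop("rgb_covariance must be positive semi-definite")
  stopifnot(texture_scale >= 0)
  structure(list(class_id = class_id, mean_rgb = mean_rgb,
                 rgb_covariance = rgb_covariance,
                 texture_scale = texture_scale),
            class = "class_color_profile")
}

#' Default colour profiles for the four ripeness stages
#'
#' The stages have qualitatively distinct exterior colours (initial unripe
#' whitish/cream, secondary unripe pink-red, ripe bluish, overripe green
#' tinted). The default means are parameterised in HSV and solved so that,
#' for each stage, the fruit-pixel means of the H, S and blue channels track
#' the per-class channel statistics the study design is anchored to.
#'
#' @param sd marginal standard deviation of the within-fruit RGB noise.
#' @param texture_scale spatial correlation length of that noise, pixels.
#' @return Named list of four [class_color_profile()] objects, display order.
#' @export
default_profiles <- function(sd = 0.008, texture_scale = 2) {
  # mean colours calibrated (Monte Carlo, under the default within-fruit
  # plus sensor noise of sd 0.008 each) so the expected fruit-pixel means
  # of H, S and the blue channel hit the per-class anchor values:
  #   H: 0.143898 0.393190 0.247182 0.149145
  #   S: 0.183587 0.165916 0.500831 0.284045
  #   B: 0.227351 0.246726 0.228051 0.318771
  tab <- rbind(
    overripe         = c(0.275996, 0.266555, 0.227304),
    ripe             = c(0.230321, 0.274780, 0.246671),
    secondary_unripe = c(0.346461, 0.457173, 0.228067),
    initial_unripe   = c(0.443794, 0.430033, 0.318822))
  cov3 <- diag(rep(sd^2, 3))
  out <- lapply(rownames(tab), function(cl)
    class_color_profile(cl, tab[cl, ], cov3, texture_scale))
  names(out) <- rownames(tab)
  out
}

#' Scene configuration for synthetic fruit images
#'
#' A single elliptical fruit on a near-white paper-like background, with an
#' optional soft shadow lobe next to the fruit and additive sensor noise.
#'
#' @param image_size `c(height, width)` in pixels.
#' @param background_rgb background colour, near white.
#' @param fruit_axes ellipse semi-axes `c(a, b)` in pixels.
#' @param fruit_angle ellipse orientation, radians.
#' @param fruit_center `c(row, col)` of the ellipse centre; default image
#'   centre.
#' @param shadow_strength multiplicative darkening of the shadow lobe, in
#'   `[0,1]`; 0 disables the shadow.
#' @param noise_sd standard deviation of additive i.i.d. sensor noise.
#' @param seed integer seed controlling all randomness of the scene.
#' @return Object of class `scene_config`.
#' @export
scene_config <- function(image_size = c(120L, 160L),
                         background_rgb = c(0.97, 0.97, 0.96),
                         fruit_axes = c(30, 42),
                         fruit_angle = 0.4,
                         fruit_center = NULL,
                         shadow_strength = 0.15,
                         noise_sd = 0.008,
                         seed = 1L) {
  image_size <- as.integer(image_size)
  stopifnot(length(image_size) == 2, all(image_size >= 1))
  stopifnot(length(background_rgb) == 3,
            all(background_rgb >= 0), all(background_rgb <= 1))
  if (any(fruit_axes <= 0)) stop("degenerate ellipse: fruit axes must be > 0")
  if (is.null(fruit_center)) fruit_center <- (image_size + 1) / 2
  stopifnot(shadow_strength >= 0, shadow_strength <= 1, noise_sd >= 0)
  # fruit must fit entirely inside the frame
  reach <- max(fruit_axes)
  if (fruit_center[1] - reach < 1 || fruit_center[1] + reach > image_size[1] ||
      fruit_center[2] - reach < 1 || fruit_center[2] + reach > image_size[2])
    stop("fruit ellipse extends outside the image frame")
  structure(list(image_size = image_size, background_rgb = background_rgb,
                 fruit_axes = as.numeric(fruit_axes),
                 fruit_angle = fruit_angle,
                 fruit_center = as.numeric(fruit_center),
                 shadow_strength = shadow_strength, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# boolean H x W ellipse indicator at centre (r0, c0)
.ellipse_mask <- function(h, w, center, axes, angle) {
  rr <- matrix(seq_len(h), h, w) - center[1]
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - center[2]
  u <- cc * cos(angle) + rr * sin(angle)
  v <- -cc * sin(angle) + rr * cos(angle)
  (u / axes[2])^2 + (v / axes[1])^2 <= 1
}

# spatially correlated Gaussian field with exactly unit marginal variance:
# white noise convolved (circular boundary) with a Gaussian kernel and
# divided by the kernel's L2 norm
.correlated_field <- function(h, w, scale) {
  z <- matrix(stats::rnorm(h * w), h, w)
  if (scale > 0) {
    size <- 2L * as.integer(ceiling(3 * scale)) + 1L
    k <- EBImage::makeBrush(size, shape = "Gaussian", sigma = scale)
    z <- EBImage::filter2(z, k, boundary = "circular") / sqrt(sum(k^2))
  }
  z
}

#' Generate one synthetic fruit image
#'
#' Renders an elliptical fruit whose pixels are drawn from the profile's
#' colour distribution (spatially correlated Gaussian fluctuation around the
#' mean colour), on a near-white background with an optional soft shadow
#' lobe adjacent to the fruit, plus additive sensor noise. With all noise
#' sources at zero the image is exactly piecewise constant.
#'
#' @param profile a [class_color_profile()].
#' @param scene a [scene_config()].
#' @return List with `image` (H x W x 3 array in `[0,1]`), `mask` (logical
#'   H x W ground-truth fruit mask), and `class` (the profile's stage).
#' @export
generate_image <- function(profile, scene = scene_config()) {
  stopifnot(inherits(profile, "class_color_profile"),
            inherits(scene, "scene_config"))
  lum <- function(x) sum(c(0.2989, 0.5870, 0.1140) * x)
  if (lum(scene$background_rgb) <= lum(profile$mean_rgb))
    stop("background luminance must exceed the class mean luminance")
  h <- scene$image_size[1]; w <- scene$image_size[2]
  set.seed(scene$seed)
  mask <- .ellipse_mask(h, w, scene$fruit_center, scene$fruit_axes,
                        scene$fruit_angle)
  img <- array(rep(scene$background_rgb, each = h * w), dim = c(h, w, 3))

  # within-fruit colour fluctuation: correlated unit fields coloured by the
  # Cholesky factor of the profile covariance
  if (max(abs(profile$rgb_covariance)) > 0) {
    z <- vapply(1:3, function(k)
      .correlated_field(h, w, profile$texture_scale), matrix(0, h, w))
    ch <- chol(profile$rgb_covariance + diag(1e-12, 3))
    idx <- which(mask)
    zm <- cbind(z[, , 1][idx], z[, , 2][idx], z[, , 3][idx])
    eps <- zm %*% ch
    for (k in 1:3) {
      plane <- img[, , k]
      plane[idx] <- profile$mean_rgb[k] + eps[, k]
      img[, , k] <- plane
    }
  } else {
    for (k in 1:3) {
      plane <- img[, , k]
      plane[mask] <- profile$mean_rgb[k]
      img[, , k] <- plane
    }
  }

  # soft shadow: multiplicative darkening lobe outside the fruit, offset
  # toward the lower-right as if lit from the upper-left
  if (scene$shadow_strength > 0) {
    off <- 0.25 * scene$fruit_axes
    sc <- scene$fruit_center + c(off[1], off[2])
    sax <- scene$fruit_axes * 1.15
    rr <- matrix(seq_len(h), h, w) - sc[1]
    cc <- matrix(seq_len(w), h, w, byrow = TRUE) - sc[2]
    u <- cc * cos(scene$fruit_angle) + rr * sin(scene$fruit_angle)
    v <- -cc * sin(scene$fruit_angle) + rr * cos(scene$fruit_angle)
    rho <- sqrt((u / sax[2])^2 + (v / sax[1])^2)
    wgt <- pmax(0, 1 - rho) * !mask
    fac <- 1 - scene$shadow_strength * wgt
    for (k in 1:3) img[, , k] <- img[, , k] * fac
  }

  if (scene$noise_sd > 0)
    img <- img + array(stats::rnorm(h * w * 3, sd = scene$noise_sd),
                       dim = c(h, w, 3))
  img[img < 0] <- 0
  img[img > 1] <- 1
  list(image = img, mask = mask, class = profile$class_id)
}

#' Generate a labelled synthetic dataset
#'
#' One image per (class, replicate), with per-image scene seeds derived
#' deterministically from the dataset seed; two calls with the same seed
#' produce bit-identical images and label sequence. Fruit geometry is
#' jittered slightly between replicates.
#'
#' @param profiles list of four [class_color_profile()], one per class.
#' @param per_class images per class (the emulated study design uses 40).
#' @param scene base [scene_config()]; its seed is the dataset seed.
#' @return Object of class `labeled_image_set`: list with `images`, `masks`,
#'   `labels` (factor in display order), and `seeds`.
#' @export
generate_dataset <- function(profiles = default_profiles(), per_class = 40,
                             scene = scene_config()) {
  stopifnot(per_class >= 1)
  cls <- ripeness_classes()
  have <- vapply(profiles, function(p) p$class_id, "")
  if (!setequal(have, cls) || length(profiles) != 4)
    stop("profiles must contain exactly one profile per ripeness class; ",
         "missing: ", paste(setdiff(cls, have), collapse = ", "))
  profiles <- profiles[match(cls, have)]
  n <- 4L * as.integer(per_class)
  images <- vector("list", n); masks <- vector("list", n)
  labels <- character(n); seeds <- integer(n)
  i <- 0L
  for (ci in seq_along(cls)) {
    for (r in seq_len(per_class)) {
      i <- i + 1L
      sd_i <- (scene$seed + 7919L * i) %% 2147483647L
      # geometry jitter, deterministic in the per-image seed
      set.seed(sd_i)
      jit <- stats::runif(3, -1, 1)
      sc_i <- scene
      sc_i$seed <- sd_i
      sc_i$fruit_axes <- scene$fruit_axes * (1 + 0.08 * jit[1:2])
      sc_i$fruit_angle <- scene$fruit_angle + 0.5 * jit[3]
      out <- generate_image(profiles[[ci]], sc_i)
      images[[i]] <- out$image; masks[[i]] <- out$mask
      labels[i] <- cls[ci]; seeds[i] <- sd_i
    }
  }
  structure(list(images = images, masks = masks,
                 labels = ripeness_factor(labels), seeds = seeds),
            class = "labeled_image_set")
}

#' @export
print.labeled_image_set <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat("labeled_image_set:", length(x$images), "images,",
      paste(d[1], "x", d[2]), "px\n")
  print(table(x$labels))
  invisible(x)
}

#' Write a labelled image set to disk
#'
#' Writes one PNG per image, a `labels.csv` (`filename,class`) and a JSON
#' manifest recording filenames, classes and per-image seeds.
#'
#' @param set a `labeled_image_set`.
#' @param dir output directory, created if needed.
#' @return Invisibly, the manifest as a data frame.
#' @export
write_image_set <- function(set, dir) {
  stopifnot(inherits(set, "labeled_image_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(set$images)
  fn <- sprintf("img_%03d_%s.png", seq_len(n), as.character(set$labels))
  for (i in seq_len(n))
    png::writePNG(set$images[[i]], file.path(dir, fn[i]))
  man <- data.frame(filename = fn, class = as.character(set$labels),
                    seed = set$seeds, stringsAsFactors = FALSE)
  utils::write.csv(man[, c("filename", "class")],
                   file.path(dir, "labels.csv"), row.names = FALSE)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(man)
}
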