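#' Canonical channel names
#'
#' The 19 scalar channels derived from an RGB image, in fixed canonical
#' order: the RGB primaries, Ohta's decorrelated I1I2I3, CIELAB, the
#' chromaticity-normalized nr/ng/nb, the chromatic deviations cr/cg/cb,
#' HSV, and the BT.601 gray level.
#'
#' @return Character vector of length 19.
#' @export
channel_names <- function() {
  c("R", "G", "B", "I1", "I2", "I3", "Lstar", "astar", "bstar",
    "nr", "ng", "nb", "cr", "cg", "cb", "H", "S", "V", "gray")
}

#' Decompose a masked image into 19 colour channels
#'
#' Per pixel: `gray = 0.2989 R + 0.5870 G + 0.1140 B` (BT.601);
#' `I1 = (R+G+B)/3`, `I2 = (R-B)/2`, `I3 = (2G-R-B)/4` (Ohta);
#' `nr = R/(R+G+B)` etc., 0 where the sum is 0; `cr = R - gray` etc.
#' (chromatic deviation from gray); HSV by the hexcone model with H scaled
#' to `[0,1]` and `H = 0` when `S = 0`; CIELAB via sRGB gamma decoding,
#' the D65 XYZ transform and the standard Lab functions.
#'
#' @param x a `masked_image` from [apply_mask()]/[preprocess_pipeline()],
#'   or an H x W x 3 array in `[0,1]` (full-frame mask assumed).
#' @return Object of class `channel_stack`: list with `channels` (named
#'   list of 19 H x W matrices) and `mask`.
#' @export
to_channels <- function(x) {
  if (is.array(x) && !inherits(x, "masked_image")) {
    .check_rgb(x)
    x <- structure(list(image = x,
                        mask = matrix(TRUE, dim(x)[1], dim(x)[2])),
                   class = "masked_image")
  }
  stopifnot(inherits(x, "masked_image"))
  img <- x$image
  .check_rgb(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  R <- matrix(img[, , 1], h, w)
  G <- matrix(img[, , 2], h, w)
  B <- matrix(img[, , 3], h, w)
  gray <- 0.2989 * R + 0.5870 * G + 0.1140 * B
  s3 <- R + G + B
  nz <- s3 > 0
  nr <- ng <- nb <- matrix(0, h, w)
  nr[nz] <- R[nz] / s3[nz]; ng[nz] <- G[nz] / s3[nz]; nb[nz] <- B[nz] / s3[nz]
  hsv <- grDevices::rgb2hsv(rbind(as.vector(R), as.vector(G), as.vector(B)),
                            maxColorValue = 1)
  lab <- grDevices::convertColor(cbind(as.vector(R), as.vector(G),
                                       as.vector(B)),
                                 from = "sRGB", to = "Lab")
  m <- function(v) matrix(v, h, w)
  ch <- list(
    R = R, G = G, B = B,
    I1 = s3 / 3, I2 = (R - B) / 2, I3 = (2 * G - R - B) / 4,
    Lstar = m(lab[, 1]), astar = m(lab[, 2]), bstar = m(lab[, 3]),
    nr = nr, ng = ng, nb = nb,
    cr = R - gray, cg = G - gray, cb = B - gray,
    H = m(hsv[1, ]), S = m(hsv[2, ]), V = m(hsv[3, ]),
    gray = gray)
  stopifnot(identical(names(ch), channel_names()))
  structure(list(channels = ch, mask = x$mask), class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  cat("channel_stack: 19 channels,",
      paste(dim(x$mask), collapse = " x "), "px,",
      sum(x$mask), "fruit pixels\n")
  invisible(x)
}

#' Export channels as min-max scaled PNG rasters (inspection only)
#'
#' @param stack a `channel_stack`.
#' @param dir output directory.
#' @return Invisibly, the written file names.
#' @export
export_channels <- function(stack, dir) {
  stopifnot(inherits(stack, "channel_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fn <- file.path(dir, paste0("channel_", channel_names(), ".png"))
  for (i in seq_along(fn)) {
    v <- stack$channels[[i]]
    rng <- range(v)
    if (diff(rng) > 0) v <- (v - rng[1]) / diff(rng) else v <- v * 0
    png::writePNG(v, fn[i])
  }
  invisible(fn)
}
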