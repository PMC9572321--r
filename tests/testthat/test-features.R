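test_that("first-order statistics match hand-computed moments", {
  expect_equal(first_order_stats(rep(3.2, 10)),
               c(min = 3.2, mean = 3.2, max = 3.2, std = 0, cv = 0,
                 median = 3.2, mode = 3.2, skewness = 0, kurtosis = 0))
  s <- first_order_stats(1:4)
  expect_equal(s[["mean"]], 2.5)
  expect_equal(s[["std"]], sqrt(1.25))
  expect_equal(s[["cv"]], sqrt(1.25) / 2.5)
  expect_equal(s[["median"]], 2.5)
  expect_equal(s[["skewness"]], 0)
  expect_equal(s[["kurtosis"]], 1.64)
  expect_error(first_order_stats(numeric(0)), "empty")
})

test_that("kurtosis is non-excess: a large Gaussian sample gives ~3", {
  set.seed(17)
  k <- first_order_stats(rnorm(2e5))[["kurtosis"]]
  expect_lt(abs(k - 3), 0.1)
})

test_that("the mode is the densest histogram bin midpoint", {
  x <- c(rep(0.5, 50), runif(50))
  m <- first_order_stats(x)[["mode"]]
  expect_lt(abs(m - 0.5), diff(range(x)) / 256)
})

test_that("co-occurrence matrix matches the worked 2x2 example", {
  ch <- matrix(c(0, 1, 0, 1), 2)          # [[0,0],[1,1]] row-wise
  cfg <- glcm_config(levels = 2, offsets = list(c(0L, 1L)))
  P <- glcm(ch, matrix(TRUE, 2, 2), cfg)
  expect_equal(P, matrix(c(0.5, 0, 0, 0.5), 2))
  tx <- texture_features(P)
  expect_equal(tx[["contrast"]], 0)
  expect_equal(tx[["homogeneity"]], 1)
  expect_equal(tx[["energy"]], 0.5)
  expect_equal(tx[["entropy"]], 1)
  expect_equal(tx[["covariance"]], 0.25)
  expect_equal(tx[["correlation"]], 1)
})

test_that("degenerate regions follow the stated conventions", {
  # constant region: single entry 1 at (1,1)
  P <- glcm(matrix(0.7, 4, 4), matrix(TRUE, 4, 4), glcm_config(levels = 4))
  expect_equal(P[1, 1], 1)
  expect_equal(sum(P), 1)
  tx <- texture_features(P)
  expect_equal(tx[["contrast"]], 0)
  expect_equal(tx[["homogeneity"]], 1)
  expect_equal(tx[["energy"]], 1)
  expect_equal(tx[["entropy"]], 0)
  expect_equal(tx[["correlation"]], 1)
  # fewer than 2 valid pairs
  m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE
  expect_error(glcm(matrix(runif(16), 4), m), "degenerate region")
  expect_error(texture_features(matrix(0.3, 2, 2)), "not normalized")
})

test_that("uniform co-occurrence attains maximum entropy", {
  L <- 4
  P <- matrix(1 / L^2, L, L)
  tx <- texture_features(P)
  expect_equal(tx[["entropy"]], 2 * log2(L))
  expect_equal(tx[["energy"]], 1 / L^2)
  expect_equal(tx[["correlation"]], 0)
})

test_that("texture features equal brute-force pair enumeration", {
  set.seed(31)
  for (trial in 1:12) {
    h <- sample(2:8, 1); w <- sample(2:8, 1)
    ch <- matrix(runif(h * w), h, w)
    mask <- matrix(runif(h * w) < 0.8, h, w)
    if (sum(mask) < 4) mask[] <- TRUE
    P <- tryCatch(glcm(ch, mask), error = function(e) NULL)
    if (is.null(P)) next
    expect_equal(P, glcm_bruteforce(ch, mask), tolerance = 1e-12)
  }
  # masking out one row only changes pairs touching that row
  ch <- matrix(runif(36), 6)
  m1 <- matrix(TRUE, 6, 6)
  m2 <- m1; m2[3, ] <- FALSE
  expect_equal(glcm(ch, m2), glcm_bruteforce(ch, m2), tolerance = 1e-12)
})

test_that("extraction yields 285 finite, registry-ordered features", {
  set <- tiny_set(per_class = 1L)
  fv <- extract_features(apply_mask(set$images[[1]], set$masks[[1]]))
  expect_length(fv, 285L)
  expect_identical(names(fv), feature_registry())
  expect_true(all(is.finite(fv)))
  # ranges and order statistics
  for (nm in channel_names()) {
    expect_lte(fv[[paste0("min_", nm)]], fv[[paste0("median_", nm)]])
    expect_lte(fv[[paste0("median_", nm)]], fv[[paste0("max_", nm)]])
    expect_lte(fv[[paste0("min_", nm)]], fv[[paste0("mean_", nm)]])
    expect_gt(fv[[paste0("energy_", nm)]], 0)
    expect_lte(fv[[paste0("energy_", nm)]], 1)
    expect_gte(fv[[paste0("entropy_", nm)]], 0)
    expect_lte(abs(fv[[paste0("correlation_", nm)]]), 1 + 1e-12)
  }
})

test_that("zero-noise fruit has zero spread and zero contrast", {
  prof <- class_color_profile("ripe", c(0.23, 0.27, 0.25), matrix(0, 3, 3))
  im <- generate_image(prof, tiny_scene(noise_sd = 0, shadow_strength = 0))
  fv <- extract_features(apply_mask(im$image, im$mask))
  expect_true(all(fv[paste0("std_", channel_names())] == 0))
  expect_true(all(fv[paste0("contrast_", channel_names())] == 0))
})

test_that("features ignore background pixel values", {
  set <- tiny_set(per_class = 1L)
  img <- set$images[[1]]; mask <- set$masks[[1]]
  f1 <- extract_features(apply_mask(img, mask))
  scr <- img
  for (k in 1:3) {
    plane <- scr[, , k]
    plane[!mask] <- runif(sum(!mask))
    scr[, , k] <- plane
  }
  f2 <- extract_features(structure(list(image = scr, mask = mask),
                                   class = "masked_image"))
  expect_equal(f1, f2)
})

test_that("feature tables are rectangular, labelled and order-stable", {
  tab <- tiny_table(per_class = 2L)
  expect_equal(dim(tab), c(8L, 287L))
  expect_identical(colnames(tab)[1:2], c("image_id", "class"))
  expect_identical(colnames(tab)[-(1:2)], feature_registry())
  expect_false(anyNA(tab))
  expect_error(extract_table(structure(list(images = list()),
                                       class = "labeled_image_set")),
               "empty")
  # CSV round trip
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_equal(back$class, tab$class)
  expect_equal(as.matrix(back[, -(1:2)]), as.matrix(tab[, -(1:2)]),
               tolerance = 1e-12, ignore_attr = TRUE)
})
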