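test_that("1-D two-class LDA has its boundary midway between the means", {
  tab <- data.frame(class = rep(c("overripe", "ripe"), each = 2),
                    x = c(-2, -1, 1, 2))
  m <- fit_discriminant(tab, "x", kind = "lda", reg = 0,
                        standardize = FALSE, priors = c(0.5, 0.5))
  s <- predict(m, data.frame(x = c(-0.001, 0.001, 0.5)), type = "scores")
  expect_gt(s[1, "overripe"], s[1, "ripe"])
  expect_gt(s[2, "ripe"], s[2, "overripe"])
  expect_identical(as.character(predict(m, data.frame(x = 0.5))), "ripe")
})

test_that("QDA equals LDA when per-class covariances are identical", {
  # class B is a shifted copy of class A, so sample covariances match
  set.seed(4)
  a <- matrix(rnorm(40), 20, 2)
  b <- sweep(a, 2, c(4, -3), "+")
  tab <- data.frame(class = rep(c("overripe", "ripe"), each = 20),
                    f1 = c(a[, 1], b[, 1]), f2 = c(a[, 2], b[, 2]))
  lda <- fit_discriminant(tab, c("f1", "f2"), "lda", reg = 0)
  qda <- fit_discriminant(tab, c("f1", "f2"), "qda", reg = 0)
  nd <- data.frame(f1 = rnorm(25, 2), f2 = rnorm(25, -1))
  sl <- predict(lda, nd, type = "scores")
  sq <- predict(qda, nd, type = "scores")
  # posteriors agree: score differences between classes coincide
  expect_equal(sl[, 1] - sl[, 2], sq[, 1] - sq[, 2], tolerance = 1e-10)
})

test_that("well-separated classes are fit to 100% training accuracy", {
  tab <- tiny_table(per_class = 4L)
  for (kind in c("lda", "qda")) {
    m <- fit_discriminant(tab, optimum_features(), kind)
    expect_equal(ccr(confusion(tab$class, predict(m, tab))), 100)
  }
})

test_that("scores agree with an independent Gaussian log-density oracle", {
  set.seed(14)
  tab <- tiny_table(per_class = 6L)
  sub <- c("mean_H", "mean_S", "mean_B")
  m <- fit_discriminant(tab, sub, "qda", reg = 1e-6, standardize = FALSE)
  x <- as.matrix(tab[, sub])
  pts <- x[sample(nrow(x), 5), ] + matrix(rnorm(15, sd = 0.01), 5)
  colnames(pts) <- sub
  s <- predict(m, pts, type = "scores")
  for (k in seq_along(m$classes)) {
    mu <- m$class_means[k, ]
    S <- m$covariances[[k]]
    for (i in 1:5) {
      d <- pts[i, ] - mu
      ref <- log(m$priors[k]) - 0.5 * determinant(S)$modulus[1] -
        0.5 * drop(d %*% solve(S) %*% d)
      expect_equal(s[i, k], ref, tolerance = 1e-8, ignore_attr = TRUE)
    }
  }
})

test_that("predictions agree with MASS on the same training data", {
  skip_if_not_installed("MASS")
  tab <- tiny_table(per_class = 6L)
  sub <- c("mean_H", "mean_S", "mean_bstar", "mean_I2")
  for (kind in c("lda", "qda")) {
    # discriminant classification is affine-equivariant, so the internal
    # z-scoring does not change the predicted classes
    ours <- fit_discriminant(tab, sub, kind)
    ref <- if (kind == "lda")
      MASS::lda(tab[, sub], grouping = tab$class)
    else MASS::qda(tab[, sub], grouping = tab$class)
    expect_identical(as.character(predict(ours, tab)),
                     as.character(predict(ref, tab[, sub])$class))
  }
})

test_that("points at a class mean classify to it; ties break by display order", {
  means <- data.frame(class = ripeness_classes(),
                      f1 = c(0, 4, 0, 4), f2 = c(0, 0, 4, 4))
  tab <- means[rep(1:4, each = 3), ]
  set.seed(6)
  tab$f1 <- tab$f1 + rnorm(12, sd = 1e-3)
  tab$f2 <- tab$f2 + rnorm(12, sd = 1e-3)
  m <- fit_discriminant(tab, c("f1", "f2"), "lda",
                        priors = rep(0.25, 4), standardize = FALSE)
  # force exact spherical symmetry for the tie case
  m$class_means <- as.matrix(means[, c("f1", "f2")])
  m$covariances$pooled <- diag(2)
  pred <- predict(m, means[, c("f1", "f2")])
  expect_identical(as.character(pred), ripeness_classes())
  # centre point equidistant from all four: first display class wins
  centre <- predict(m, data.frame(f1 = 2, f2 = 2))
  expect_identical(as.character(centre), "overripe")
})

test_that("model structure is invariant to duplicating all samples", {
  tab <- tiny_table(per_class = 2L)
  sub <- c("mean_H", "mean_S")
  m1 <- fit_discriminant(tab, sub, "lda", reg = 0)
  m2 <- fit_discriminant(rbind(tab, tab), sub, "lda", reg = 0)
  expect_equal(m1$class_means, m2$class_means, tolerance = 1e-10)
  expect_equal(m1$covariances$pooled, m2$covariances$pooled,
               tolerance = 1e-10)
  expect_identical(as.character(predict(m1, tab)),
                   as.character(predict(m2, tab)))
})

test_that("standardization makes scores invariant to feature rescaling", {
  tab <- tiny_table(per_class = 4L)
  sub <- c("mean_H", "mean_S")
  m1 <- fit_discriminant(tab, sub, "qda")
  tab2 <- tab
  tab2$mean_H <- tab2$mean_H * 1000 + 5
  m2 <- fit_discriminant(tab2, sub, "qda")
  s1 <- predict(m1, tab, type = "scores")
  s2 <- predict(m2, tab2, type = "scores")
  expect_equal(s1, s2, tolerance = 1e-8)
})

test_that("degenerate fits fail with actionable errors", {
  tab <- data.frame(class = rep(c("overripe", "ripe"), each = 3),
                    f1 = c(1, 1, 1, 2, 2, 2), f2 = c(3, 3, 3, 4, 4, 4))
  expect_error(fit_discriminant(tab, c("f1", "f2"), "qda", reg = 0),
               "reg > 0")
  m <- fit_discriminant(tab, c("f1", "f2"), "qda", reg = 1e-6)
  expect_s3_class(m, "discrim")
  expect_error(predict(m, data.frame(f1 = 1)), "missing feature")
  expect_error(fit_discriminant(
    data.frame(class = c("ripe", "overripe"), f1 = 1:2), "f1"),
    "at least 2")
})
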