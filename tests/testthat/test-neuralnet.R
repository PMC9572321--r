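# hand-buildable network for forward-pass checks
manual_ann <- function(W1, b1, W2, b2, scaling_min, scaling_max, classes) {
  structure(list(n_input = ncol(W1), n_hidden = nrow(W1),
                 n_output = nrow(W2),
                 weights = list(W1 = W1, b1 = b1, W2 = W2, b2 = b2),
                 input_scaling = list(min = scaling_min, max = scaling_max),
                 feature_subset = paste0("f", seq_len(ncol(W1))),
                 classes = classes),
            class = "ripeness_ann")
}

test_that("the forward pass matches closed-form tanh arithmetic", {
  W1 <- matrix(c(1, -1, 0.5, 2), 2)
  W2 <- matrix(c(0.3, -0.2, 1, 0.7), 2)
  m <- manual_ann(W1, c(0.1, -0.1), W2, c(0, 0.5),
                  scaling_min = c(-1, -1), scaling_max = c(1, 1),
                  classes = c("overripe", "ripe"))
  x <- matrix(c(0.2, -0.4), 1, dimnames = list(NULL, c("f1", "f2")))
  h <- tanh(W1 %*% c(0.2, -0.4) + c(0.1, -0.1))
  want <- as.vector(W2 %*% h + c(0, 0.5))
  got <- predict(m, x, type = "raw")
  expect_equal(as.vector(got), want, tolerance = 1e-12)
})

test_that("a zero-initialized network outputs its biases everywhere", {
  m <- manual_ann(matrix(0, 3, 2), rep(0, 3), matrix(0, 4, 3),
                  c(0.1, 0.2, 0.3, 0.4), c(0, 0), c(1, 1),
                  ripeness_classes())
  x <- matrix(runif(10), 5, 2, dimnames = list(NULL, c("f1", "f2")))
  out <- predict(m, x, type = "raw")
  expect_true(all(apply(out, 1, function(r)
    identical(unname(r), c(0.1, 0.2, 0.3, 0.4)))))
  # argmax tie: equal outputs resolve to the earlier display class
  tie <- manual_ann(matrix(0, 3, 2), rep(0, 3), matrix(0, 4, 3),
                    c(0.5, 0.5, 0.1, 0.1), c(0, 0), c(1, 1),
                    ripeness_classes())
  expect_identical(as.character(predict(tie, x)[1]), "overripe")
})

test_that("a linearly separable toy is learned to 100% training accuracy", {
  set.seed(2)
  n <- 30
  tab <- data.frame(
    class = rep(c("overripe", "ripe"), each = n),
    f1 = c(rnorm(n, -2), rnorm(n, 2)),
    f2 = c(rnorm(n, 1), rnorm(n, -1)))
  m <- train_ann(tab, c("f1", "f2"), n_hidden = 2,
                 split = split_config(c(train = 0.6, validation = 0.2,
                                        test = 0.2), seed = 3),
                 cfg = train_config(max_epochs = 200, seed = 3))
  tr <- m$partition == "train"
  pred <- predict(m, tab[tr, ])
  expect_equal(mean(pred == tab$class[tr]), 1)
})

test_that("training is deterministic given the seeds", {
  tab <- tiny_table(per_class = 4L)
  a <- train_ann(tab, optimum_features(), n_hidden = 5,
                 cfg = train_config(seed = 9))
  b <- train_ann(tab, optimum_features(), n_hidden = 5,
                 cfg = train_config(seed = 9))
  expect_identical(a$weights, b$weights)
  expect_identical(a$history, b$history)
})

test_that("the best validation epoch is restored and reported", {
  tab <- tiny_table(per_class = 4L)
  m <- train_ann(tab, optimum_features(), n_hidden = 4,
                 cfg = train_config(max_epochs = 150, seed = 2))
  expect_equal(m$validation_mse, min(m$history$validation_mse))
  expect_equal(m$history$validation_mse[m$best_epoch], m$validation_mse)
  # more epochs never worsen the best validation MSE
  m2 <- train_ann(tab, optimum_features(), n_hidden = 4,
                  cfg = train_config(max_epochs = 300, seed = 2))
  expect_lte(m2$validation_mse, m$validation_mse + 1e-12)
})

test_that("trained nets beat a frozen-hidden least-squares baseline", {
  # random frozen hidden layer + least-squares output layer bounds the
  # achievable training MSE from above
  tab <- tiny_table(per_class = 4L)
  sub <- optimum_features()
  # disable early stopping so the comparison is on converged training MSE
  m <- train_ann(tab, sub, n_hidden = 8,
                 cfg = train_config(max_epochs = 400,
                                    early_stop_patience = 400, seed = 5))
  tr <- m$partition == "train"
  x <- as.matrix(tab[tr, sub])
  xs <- ripegrade:::.ann_scale(x, m$input_scaling)
  tgt <- one_hot(tab$class)[tr, ]
  set.seed(5)
  W1 <- matrix(rnorm(8 * ncol(xs)), 8)
  H <- cbind(1, tanh(xs %*% t(W1)))
  beta <- qr.solve(H, tgt)
  baseline <- mean((H %*% beta - tgt)^2)
  expect_lte(min(m$history$train_mse), baseline + 1e-6)
})

test_that("divergence and invalid sizes raise errors", {
  tab <- tiny_table(per_class = 4L)
  expect_error(train_ann(tab, optimum_features(), n_hidden = 1), "n_hidden")
  expect_error(train_ann(tab, optimum_features(), n_hidden = 25), "n_hidden")
  m <- train_ann(tab, optimum_features(), n_hidden = 3,
                 cfg = train_config(max_epochs = 30, seed = 1))
  expect_error(predict(m, matrix(0, 2, 3)), "dimension mismatch")
})

test_that("the structure scan reports all sizes and a coherent optimum", {
  tab <- tiny_table(per_class = 5L)
  scan <- scan_structures(tab, optimum_features(), hidden_range = 2:6,
                          cfg = train_config(max_epochs = 150, seed = 4))
  expect_equal(nrow(scan$report), 5L)
  expect_identical(scan$report$structure[1], "16-2-4")
  expect_true(all(c("mse_validation", "r_test", "ccr_all", "ccr_test")
                  %in% colnames(scan$report)))
  best_row <- scan$report[scan$report$n_hidden == scan$best_hidden, ]
  expect_equal(best_row$ccr_all, max(scan$report$ccr_all))
  # single-size scan is trivially optimum
  one <- scan_structures(tab, optimum_features(), hidden_range = 5L,
                         cfg = train_config(max_epochs = 80, seed = 4))
  expect_equal(nrow(one$report), 1L)
  expect_equal(one$best_hidden, 5L)
})

test_that("models survive a JSON serialization round trip", {
  tab <- tiny_table(per_class = 4L)
  m <- train_ann(tab, optimum_features(), n_hidden = 4,
                 cfg = train_config(max_epochs = 60, seed = 8))
  path <- withr::local_tempfile(fileext = ".json")
  serialize_model(m, path)
  back <- deserialize_model(path)
  expect_equal(predict(back, tab, type = "raw"),
               predict(m, tab, type = "raw"), tolerance = 1e-12)
  d <- fit_discriminant(tab, c("mean_H", "mean_S"), "qda")
  path2 <- withr::local_tempfile(fileext = ".json")
  serialize_model(d, path2)
  back2 <- deserialize_model(path2)
  expect_identical(as.character(predict(back2, tab)),
                   as.character(predict(d, tab)))
})
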