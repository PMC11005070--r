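test_that("bipolar sigmoid is odd, bounded and matches hand values", {
  expect_equal(bipolar_sigmoid(0, 1), 0)
  expect_equal(bipolar_sigmoid(0, 5), 0)
  expect_equal(bipolar_sigmoid(50, 1), 1, tolerance = 1e-12)
  expect_equal(bipolar_sigmoid(-50, 1), -1, tolerance = 1e-12)
  expect_equal(bipolar_sigmoid(1, 2), tanh(1))
  expect_equal(bipolar_sigmoid(1, 2), 0.76159, tolerance = 1e-5)
  x <- seq(-3, 3, by = 0.1)
  expect_equal(bipolar_sigmoid(-x, 1.7), -bipolar_sigmoid(x, 1.7))
  expect_true(all(diff(bipolar_sigmoid(x, 0.5)) > 0))
})

test_that("feature normalization maps cutoffs to [-1, 1] and clips", {
  cut <- rbind(low = c(0, -10), high = c(4, 10))
  expect_equal(unname(normalize_features(c(0, -10), cut)), c(-1, -1))
  expect_equal(unname(normalize_features(c(4, 10), cut)), c(1, 1))
  expect_equal(unname(normalize_features(c(2, 0), cut)), c(0, 0))
  expect_equal(unname(normalize_features(c(9, 99), cut)), c(1, 1))
  expect_equal(unname(normalize_features(c(-5, -99), cut)), c(-1, -1))
  bad <- rbind(low = c(1, 0), high = c(1, 5))
  expect_error(normalize_features(c(1, 1), bad), "degenerate")
})

test_that("percentile cutoffs leave at least 98% of training values
           unclipped", {
  set.seed(33)
  x <- matrix(rnorm(5000), 1000, 5)
  cut <- feature_cutoffs(x)
  z <- normalize_features(x, cut)
  expect_gte(mean(abs(z) < 1), 0.98)
  expect_error(feature_cutoffs(matrix(1, 10, 2)), "degenerate")
})

test_that("the forward pass matches a hand-computed toy network", {
  w1 <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2)
  b1 <- c(0.05, -0.05)
  w2 <- matrix(c(0.5, -0.6), 2, 1)
  b2 <- 0.1
  x <- matrix(c(1, -1), 1, 2)
  sig <- 2
  h <- bipolar_sigmoid(x %*% w1 + rbind(b1), sig)
  o_hand <- bipolar_sigmoid(h %*% w2 + b2, sig)
  acts <- kcscreen:::mlp_forward_all(list(w1, w2), list(b1, b2), sig, x)
  expect_equal(acts[[3]][1, 1], unname(o_hand[1, 1]), tolerance = 1e-12)
  # all-zero weights give all-zero outputs
  acts0 <- kcscreen:::mlp_forward_all(list(w1 * 0, w2 * 0),
                                      list(b1 * 0, 0), sig, x)
  expect_equal(acts0[[3]][1, 1], 0)
  expect_true(all(abs(acts[[3]]) < 1))
})

test_that("analytic backprop gradients match numerical differentiation", {
  set.seed(4)
  X <- matrix(rnorm(15), 5, 3)
  Tg <- matrix(rbinom(10, 1, 0.5), 5, 2)
  sig <- 1.5
  par <- kcscreen:::mlp_init(c(3, 4, 2), seed = 11)
  gr <- kcscreen:::mlp_gradients(par$weights, par$biases, sig, X, Tg)
  f <- function(p) kcscreen:::mlp_mse(
    kcscreen:::mlp_forward_all(p$weights, p$biases, sig, X)[[3]], Tg)
  h <- 1e-5
  worst <- 0
  for (l in 1:2) {
    for (i in seq_along(par$weights[[l]])) {
      up <- par; up$weights[[l]][i] <- up$weights[[l]][i] + h
      dn <- par; dn$weights[[l]][i] <- dn$weights[[l]][i] - h
      num <- (f(up) - f(dn)) / (2 * h)
      worst <- max(worst, abs(num - gr$weights[[l]][i]) /
                     max(abs(num), 1e-8))
    }
    for (i in seq_along(par$biases[[l]])) {
      up <- par; up$biases[[l]][i] <- up$biases[[l]][i] + h
      dn <- par; dn$biases[[l]][i] <- dn$biases[[l]][i] - h
      num <- (f(up) - f(dn)) / (2 * h)
      worst <- max(worst, abs(num - gr$biases[[l]][i]) /
                     max(abs(num), 1e-8))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("backpropagation solves XOR", {
  x <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- factor(c("off", "on", "on", "off"))
  cut <- rbind(low = c(0, 0), high = c(1, 1))
  fit <- mlp_fit(x, y, hidden = 4, learning_rate = 0.5, momentum = 0.9,
                 max_epochs = 5000, patience = 5000, seed = 1,
                 cutoffs = cut)
  expect_lt(min(fit$training_log), 0.05)
  expect_equal(as.character(predict(fit, x)$class),
               as.character(y))
})

test_that("training is reproducible bitwise from the seed", {
  set.seed(9)
  x <- matrix(rnorm(80), 20, 4)
  y <- factor(rep(c("a", "b"), 10))
  f1 <- mlp_fit(x, y, hidden = 5, max_epochs = 300, seed = 77)
  f2 <- mlp_fit(x, y, hidden = 5, max_epochs = 300, seed = 77)
  expect_identical(f1$training_log, f2$training_log)
  expect_identical(f1$weights, f2$weights)
  f3 <- mlp_fit(x, y, hidden = 5, max_epochs = 300, seed = 78)
  expect_false(identical(f1$weights, f3$weights))
})

test_that("linearly separable classes are fitted to 100% accuracy", {
  set.seed(10)
  x <- rbind(matrix(rnorm(60, -2), 30, 2), matrix(rnorm(60, 2), 30, 2))
  y <- factor(rep(c("lo", "hi"), each = 30))
  fit <- mlp_fit(x, y, hidden = 4, max_epochs = 1500, seed = 3)
  expect_equal(mean(predict(fit, x)$class == y), 1)
})

test_that("training error descends for nearly all epochs", {
  set.seed(12)
  x <- rbind(matrix(rnorm(100, -1), 25, 4), matrix(rnorm(100, 1), 25, 4))
  y <- factor(rep(c("a", "b"), each = 25))
  fit <- mlp_fit(x, y, hidden = 6, max_epochs = 800, patience = 800,
                 seed = 5)
  expect_gte(mean(diff(fit$training_log) <= 1e-12), 0.9)
})

test_that("gross learning rates wreck the fit instead of converging", {
  # with bounded bipolar activations the squared error cannot overflow, so
  # a bad learning rate shows up as a uselessly high plateau, not NaN
  set.seed(13)
  x <- rbind(matrix(rnorm(100, -2), 25, 4), matrix(rnorm(100, 2), 25, 4))
  y <- factor(rep(c("a", "b"), each = 25))
  good <- mlp_fit(x, y, hidden = 4, learning_rate = 0.05,
                  max_epochs = 800, seed = 2)
  bad <- mlp_fit(x, y, hidden = 4, learning_rate = 1e4, momentum = 0.95,
                 max_epochs = 800, seed = 2)
  expect_lt(utils::tail(good$training_log, 1), 0.05)
  expect_gt(min(bad$training_log), 0.2)
})

test_that("winner-take-all classification breaks ties by class order", {
  classes <- c("Abn", "Kcn", "MyPO", "Normal", "SKcn")
  outputs <- c(0.1, 0.9, -0.2, 0.0, 0.3)
  expect_equal(classes[which.max(outputs)], "Kcn")
  tie <- c(0.5, 0.5, 0.1, 0.1, 0.1)
  expect_equal(classes[which.max(tie)], "Abn")
})

test_that("hyperparameter search returns complete reports and rejects
           bad configurations by score", {
  set.seed(14)
  x <- rbind(matrix(rnorm(120, -1.5), 30, 4),
             matrix(rnorm(120, 1.5), 30, 4))
  y <- factor(rep(c("a", "b"), each = 30))
  xt <- rbind(matrix(rnorm(40, -1.5), 10, 4),
              matrix(rnorm(40, 1.5), 10, 4))
  yt <- factor(rep(c("a", "b"), each = 10))
  grid <- list(list(hidden = 4L, learning_rate = 0.05,
                    max_epochs = 600L, seed = 1L),
               list(hidden = 4L, learning_rate = 1e4, momentum = 0.95,
                    max_epochs = 600L, seed = 1L))
  res <- hyperparameter_search(x, y, xt, yt, grid)
  expect_equal(nrow(res$report), 2L)
  expect_lt(res$report$macro_f1[2], res$report$macro_f1[1])
  expect_equal(res$best, 1L)
  expect_s3_class(res$model, "kc_mlp")
  one <- hyperparameter_search(x, y, xt, yt, grid[1])
  expect_equal(nrow(one$report), 1L)
  expect_error(hyperparameter_search(x, y, xt, yt, list()), "empty")
})
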