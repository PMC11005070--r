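# Multilayer perceptron with backpropagation, written out in full:
# bipolar sigmoid activations, [-1, 1] input normalization against
# percentile cutoffs, full-batch gradient descent with momentum on the
# squared error against 1/0 class targets, and winner-take-all decisions.

#' Bipolar sigmoid activation
#'
#' `2 / (1 + exp(-sigma * x)) - 1`, an odd, strictly increasing map of the
#' reals onto (-1, 1); equals `tanh(sigma * x / 2)`.
#'
#' @param x Numeric input.
#' @param sigma Steepness (> 0).
#' @return Activation values in (-1, 1).
#' @export
bipolar_sigmoid <- function(x, sigma = 1) {
  2 / (1 + exp(-sigma * x)) - 1
}

# derivative in terms of the activation value a
bipolar_sigmoid_deriv <- function(a, sigma) sigma * (1 - a^2) / 2

#' Per-feature normalization cutoffs from training data
#'
#' Low/high cutoffs per feature (default: the 1st and 99th empirical
#' percentiles), used to map raw index values affinely into [-1, 1].
#'
#' @param x Numeric training matrix (rows = eyes, columns = features).
#' @param probs Length-2 probabilities for the low/high cutoff.
#' @return A 2 x p matrix with rows `low` and `high`.
#' @export
feature_cutoffs <- function(x, probs = c(0.01, 0.99)) {
  x <- as.matrix(x)
  q <- apply(x, 2L, stats::quantile, probs = probs, names = FALSE, type = 7)
  rownames(q) <- c("low", "high")
  if (any(q["high", ] - q["low", ] <= 0))
    stop("degenerate cutoffs: a feature has no spread between the percentiles")
  q
}

#' Normalize features into [-1, 1] against cutoffs
#'
#' Affine map of `[low, high]` onto `[-1, 1]` per feature; values beyond the
#' cutoffs are clipped to the interval ends.
#'
#' @param x Numeric matrix or vector of raw feature values.
#' @param cutoffs A [feature_cutoffs()] matrix.
#' @return Matrix of the same shape with values in [-1, 1].
#' @export
normalize_features <- function(x, cutoffs) {
  one_row <- is.null(dim(x))
  x <- rbind(x)
  if (ncol(x) != ncol(cutoffs)) stop("feature count does not match cutoffs")
  lo <- cutoffs["low", ]; hi <- cutoffs["high", ]
  if (any(hi - lo <= 0)) stop("degenerate cutoffs (low >= high)")
  z <- sweep(sweep(x, 2L, lo), 2L, (hi - lo) / 2, "/") - 1
  z <- pmin(pmax(z, -1), 1)
  if (one_row) z[1L, ] else z
}

# forward pass returning all layer activations (list; [[1]] = input)
mlp_forward_all <- function(weights, biases, sigma, X) {
  acts <- vector("list", length(weights) + 1L)
  acts[[1L]] <- X
  for (l in seq_along(weights)) {
    Zl <- acts[[l]] %*% weights[[l]]
    Zl <- sweep(Zl, 2L, biases[[l]], "+")
    acts[[l + 1L]] <- bipolar_sigmoid(Zl, sigma)
  }
  acts
}

# mean squared error over all output entries, optionally row-weighted
mlp_mse <- function(out, target, rw = NULL) {
  if (is.null(rw)) return(mean((out - target)^2))
  sum(rw * rowSums((out - target)^2)) / (sum(rw) * ncol(target))
}

# analytic gradients of mlp_mse wrt weights and biases
mlp_gradients <- function(weights, biases, sigma, X, target, rw = NULL) {
  acts <- mlp_forward_all(weights, biases, sigma, X)
  L <- length(weights)
  n <- nrow(X); K <- ncol(target)
  gw <- vector("list", L); gb <- vector("list", L)
  scale_w <- if (is.null(rw)) rep(1 / (n * K), n) else rw / (sum(rw) * K)
  delta <- 2 * scale_w * (acts[[L + 1L]] - target) *
    bipolar_sigmoid_deriv(acts[[L + 1L]], sigma)
  for (l in L:1) {
    gw[[l]] <- crossprod(acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L)
      delta <- (delta %*% t(weights[[l]])) *
        bipolar_sigmoid_deriv(acts[[l]], sigma)
  }
  list(weights = gw, biases = gb, error = mlp_mse(acts[[L + 1L]], target, rw))
}

# fan-in scaled uniform initialization, reproducible from seed
mlp_init <- function(layer_sizes, seed) {
  L <- length(layer_sizes) - 1L
  weights <- vector("list", L); biases <- vector("list", L)
  local_seed(seed, {
    for (l in seq_len(L)) {
      fan_in <- layer_sizes[l]
      weights[[l]] <- matrix(stats::runif(fan_in * layer_sizes[l + 1L],
                                          -0.5, 0.5) / sqrt(fan_in),
                             fan_in, layer_sizes[l + 1L])
      biases[[l]] <- stats::runif(layer_sizes[l + 1L], -0.5, 0.5) /
        sqrt(fan_in)
    }
  })
  list(weights = weights, biases = biases)
}

# evaluate expr with a temporary RNG state seeded from `seed`
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  eval.parent(substitute(expr))
}

#' Fit a multilayer perceptron classifier by backpropagation
#'
#' Trains a fully connected perceptron with bipolar sigmoid activations on
#' every neuron by full-batch gradient descent with momentum on the mean
#' squared error between the network outputs and 1/0 class-indicator
#' targets. Inputs are normalized into [-1, 1] against per-feature
#' percentile cutoffs derived from the training data (or supplied). The
#' input layer has one neuron per feature and the output layer one neuron
#' per class; classification is winner-take-all over the output neurons.
#'
#' Training is deterministic given the seed: initial weights are
#' fan-in-scaled uniform draws, and the per-epoch training error is recorded
#' in `training_log`.
#'
#' @param x Numeric matrix of raw feature values (rows = eyes).
#' @param y Class labels (factor; its levels fix the output-neuron order).
#' @param hidden Integer vector of hidden-layer sizes.
#' @param learning_rate Gradient-descent step size (> 0).
#' @param momentum Momentum coefficient in [0, 1).
#' @param sigma Activation steepness (> 0).
#' @param max_epochs Epoch budget.
#' @param patience Early stop after this many epochs without improvement of
#'   the training error.
#' @param seed Integer seed for weight initialization.
#' @param cutoffs Optional [feature_cutoffs()] matrix; computed from `x`
#'   when omitted.
#' @param class_weights Optional named per-class sample weights (e.g.
#'   inverse class frequencies); `NULL` (default) weights all eyes equally.
#' @return An object of class `kc_mlp`.
#' @examples
#' x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 3), 20))
#' y <- factor(rep(c("a", "b"), each = 20))
#' fit <- mlp_fit(x, y, hidden = 4, max_epochs = 500, seed = 1)
#' mean(predict(fit, x)$class == y)
#' @export
mlp_fit <- function(x, y, hidden = 15L, learning_rate = 0.05,
                    momentum = 0.9, sigma = 1, max_epochs = 5000L,
                    patience = 200L, seed = 1L, cutoffs = NULL,
                    class_weights = NULL) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (momentum < 0 || momentum >= 1) stop("momentum must be in [0, 1)")
  if (sigma <= 0) stop("sigma must be > 0")
  if (is.null(cutoffs)) cutoffs <- feature_cutoffs(x)
  X <- normalize_features(x, cutoffs)
  classes <- levels(y)
  target <- matrix(0, nrow(X), length(classes))
  target[cbind(seq_len(nrow(X)), as.integer(y))] <- 1
  rw <- NULL
  if (!is.null(class_weights)) {
    if (is.null(names(class_weights)) || anyNA(class_weights[classes]))
      stop("class_weights must be named by class")
    rw <- as.numeric(class_weights[as.character(y)])
  }
  layer_sizes <- c(ncol(X), as.integer(hidden), length(classes))
  par <- mlp_init(layer_sizes, seed)
  vel_w <- lapply(par$weights, function(w) w * 0)
  vel_b <- lapply(par$biases, function(b) b * 0)
  log_err <- numeric(max_epochs)
  best <- Inf; best_epoch <- 0L
  epoch <- 0L
  while (epoch < max_epochs) {
    epoch <- epoch + 1L
    gr <- mlp_gradients(par$weights, par$biases, sigma, X, target, rw)
    if (!is.finite(gr$error))
      stop("training diverged (non-finite loss); reduce learning_rate")
    log_err[epoch] <- gr$error
    if (gr$error < best - 1e-12) { best <- gr$error; best_epoch <- epoch }
    if (epoch - best_epoch >= patience) break
    for (l in seq_along(par$weights)) {
      vel_w[[l]] <- momentum * vel_w[[l]] - learning_rate * gr$weights[[l]]
      vel_b[[l]] <- momentum * vel_b[[l]] - learning_rate * gr$biases[[l]]
      par$weights[[l]] <- par$weights[[l]] + vel_w[[l]]
      par$biases[[l]] <- par$biases[[l]] + vel_b[[l]]
    }
  }
  model <- list(layer_sizes = layer_sizes, weights = par$weights,
                biases = par$biases, sigma = sigma, cutoffs = cutoffs,
                classes = classes, training_log = log_err[seq_len(epoch)],
                config = list(hidden = as.integer(hidden),
                              learning_rate = learning_rate,
                              momentum = momentum, sigma = sigma,
                              max_epochs = as.integer(max_epochs),
                              patience = as.integer(patience),
                              seed = as.integer(seed)))
  class(model) <- "kc_mlp"
  model
}

#' Forward pass of a fitted perceptron on normalized inputs
#'
#' @param model A `kc_mlp`.
#' @param X Matrix of inputs already normalized to [-1, 1].
#' @return Matrix of output-neuron activations in (-1, 1).
#' @export
mlp_forward <- function(model, X) {
  acts <- mlp_forward_all(model$weights, model$biases, model$sigma,
                          as.matrix(X))
  acts[[length(acts)]]
}

#' Classify feature vectors with a fitted perceptron
#'
#' Normalizes the raw feature rows against the model's cutoffs, runs the
#' forward pass, and assigns each row to the class of the output neuron
#' with the highest activation (winner-take-all; exact ties resolve to the
#' first class in the model's class order).
#'
#' @param object A `kc_mlp`.
#' @param newdata Numeric matrix (or vector) of raw feature values.
#' @param ... Unused.
#' @return List with `class` (factor) and `outputs` (activation matrix,
#'   one column per class).
#' @export
predict.kc_mlp <- function(object, newdata, ...) {
  X <- normalize_features(as.matrix(rbind(newdata)), object$cutoffs)
  out <- mlp_forward(object, X)
  colnames(out) <- object$classes
  idx <- apply(out, 1L, which.max)   # which.max: first maximum wins ties
  list(class = factor(object$classes[idx], levels = object$classes),
       outputs = out)
}

#' @export
print.kc_mlp <- function(x, ...) {
  cat("Multilayer perceptron classifier\n")
  cat("  architecture:", paste(x$layer_sizes, collapse = "-"),
      " (bipolar sigmoid, sigma =", x$sigma, ")\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat(sprintf("  trained %d epochs, final training MSE %.5f\n",
              length(x$training_log), utils::tail(x$training_log, 1L)))
  invisible(x)
}

#' @export
summary.kc_mlp <- function(object, ...) {
  log <- object$training_log
  cat("Multilayer perceptron classifier\n")
  cat("  architecture:", paste(object$layer_sizes, collapse = "-"), "\n")
  cat("  sigma:", object$sigma, " lr:", object$config$learning_rate,
      " momentum:", object$config$momentum, "\n")
  cat(sprintf("  epochs: %d  training MSE: first %.5f  best %.5f\n",
              length(log), log[1L], min(log)))
  cat("  normalization cutoffs:\n")
  print(round(object$cutoffs, 4))
  invisible(object)
}

#' @export
coef.kc_mlp <- function(object, ...) {
  list(weights = object$weights, biases = object$biases)
}

#' Plot the training error curve of a fitted perceptron
#'
#' @param x A `kc_mlp`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.kc_mlp <- function(x, ...) {
  graphics::plot(seq_along(x$training_log), x$training_log, type = "l",
                 xlab = "epoch", ylab = "training MSE",
                 main = "Backpropagation error descent", ...)
  invisible(x)
}

#' Grid search over training hyperparameters
#'
#' Trains one perceptron per configuration and scores each on the held-out
#' test set by macro-averaged F1; ties break on the stability of the error
#' descent (variance of the last decile of the training log, smaller is
#' better). Configurations that diverge score NA and are skipped.
#'
#' @param x_train,y_train Training features and labels.
#' @param x_test,y_test Held-out features and labels used for scoring.
#' @param grid List of configuration lists; each may set any of `hidden`,
#'   `learning_rate`, `momentum`, `sigma`, `max_epochs`, `patience`, `seed`.
#' @param cutoffs Optional shared normalization cutoffs.
#' @param class_weights Optional per-class sample weights.
#' @return List with `model` (the winning `kc_mlp`) and `report` (one row
#'   per configuration: hyperparameters, macro-F1, stability, epochs).
#' @export
hyperparameter_search <- function(x_train, y_train, x_test, y_test, grid,
                                  cutoffs = NULL, class_weights = NULL) {
  if (length(grid) == 0L) stop("empty hyperparameter grid")
  rows <- vector("list", length(grid))
  models <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    cfg <- grid[[i]]
    model <- tryCatch(
      do.call(mlp_fit, c(list(x = x_train, y = y_train, cutoffs = cutoffs,
                              class_weights = class_weights), cfg)),
      error = function(e) NULL)
    f1 <- NA_real_; stab <- NA_real_; epochs <- NA_integer_
    if (!is.null(model)) {
      pred <- predict(model, x_test)$class
      cm <- confusion_matrix(y_test, pred)
      f1s <- vapply(levels(droplevels(as.factor(y_test))),
                    function(cl) class_metrics(cm, cl)$f1, numeric(1))
      f1 <- mean(f1s)
      log <- model$training_log
      tailpart <- log[max(1L, floor(0.9 * length(log))):length(log)]
      stab <- stats::var(tailpart)
      epochs <- length(log)
    }
    models[[i]] <- model
    rows[[i]] <- data.frame(
      config = i,
      hidden = paste(cfg$hidden %||% 15L, collapse = "x"),
      learning_rate = cfg$learning_rate %||% 0.05,
      momentum = cfg$momentum %||% 0.9,
      sigma = cfg$sigma %||% 1,
      macro_f1 = f1, stability = stab, epochs = epochs)
  }
  report <- do.call(rbind, rows)
  if (all(is.na(report$macro_f1))) stop("all configurations diverged")
  ord <- order(-report$macro_f1, report$stability, report$config,
               na.last = TRUE)
  best <- ord[1L]
  list(model = models[[best]], report = report, best = best)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
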