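#' MLP training configuration
#'
#' The supervised correctness classifier: a fully connected 70-20-10-1
#' network with rectified-linear hidden layers and a logistic output,
#' trained full-batch for 500 epochs with the adaptive-moment (Adam)
#' optimiser on binary cross-entropy.
#'
#' @param layer_sizes Integer vector of layer widths, input first and a
#'   single output unit last (default `c(70, 20, 10, 1)`).
#' @param epochs Training epochs (default 500).
#' @param learning_rate Adam step size (default 1e-3).
#' @param beta1,beta2,epsilon Adam moment decay rates and stabiliser.
#' @param seed Seed for the weight initialisation.
#' @return An object of class `mlp_config`.
#' @export
mlp_config <- function(layer_sizes = c(70L, 20L, 10L, 1L), epochs = 500L,
                       learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                       epsilon = 1e-8, seed = 1L) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2 || any(layer_sizes < 1)) {
    stop("layer_sizes needs at least an input and an output layer")
  }
  if (layer_sizes[length(layer_sizes)] != 1L) {
    stop("the output layer must have a single (logistic) unit")
  }
  if (epochs < 1) stop("epochs must be positive")
  structure(
    list(layer_sizes = layer_sizes, epochs = as.integer(epochs),
         learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
         epsilon = epsilon, seed = as.integer(seed)),
    class = "mlp_config"
  )
}

# He-scaled Gaussian initialisation; deterministic given the seed
.mlp_init <- function(layer_sizes, seed) {
  set.seed(seed)
  n_layers <- length(layer_sizes) - 1L
  W <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    fan_in <- layer_sizes[l]
    W[[l]] <- matrix(stats::rnorm(fan_in * layer_sizes[l + 1L],
                                  sd = sqrt(2 / fan_in)),
                     nrow = fan_in)
    b[[l]] <- numeric(layer_sizes[l + 1L])
  }
  list(W = W, b = b)
}

#' Forward pass of the MLP
#'
#' ReLU activations on every hidden layer, logistic on the output.
#'
#' @param params List with weight matrices `W` and bias vectors `b`.
#' @param x Numeric matrix, one row per sample.
#' @return List with `prob` (output probabilities) and `activations`
#'   (per-layer outputs, for backpropagation).
#' @export
mlp_forward <- function(params, x) {
  x <- as.matrix(x)
  n_layers <- length(params$W)
  acts <- vector("list", n_layers + 1L)
  acts[[1L]] <- x
  a <- x
  for (l in seq_len(n_layers)) {
    z <- a %*% params$W[[l]] +
      matrix(params$b[[l]], nrow(a), length(params$b[[l]]), byrow = TRUE)
    a <- if (l < n_layers) pmax(z, 0) else 1 / (1 + exp(-z))
    acts[[l + 1L]] <- a
  }
  list(prob = as.numeric(a), activations = acts)
}

#' Binary cross-entropy loss and analytic gradients
#'
#' Full-batch mean binary cross-entropy of the network output against 0/1
#' labels, with gradients from explicit backpropagation (the logistic +
#' cross-entropy combination gives the exact output-layer delta
#' `prob - y`, so no clipping enters the gradient).
#'
#' @param params List with weight matrices `W` and bias vectors `b`.
#' @param x Numeric matrix of inputs, one row per sample.
#' @param y Numeric 0/1 labels.
#' @return List with `loss`, `grads` (same shapes as `params`), and
#'   `prob`.
#' @export
mlp_loss_grads <- function(params, x, y) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  fw <- mlp_forward(params, x)
  p <- pmin(pmax(fw$prob, 1e-12), 1 - 1e-12)
  loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
  n_layers <- length(params$W)
  gW <- vector("list", n_layers)
  gb <- vector("list", n_layers)
  delta <- matrix((fw$prob - y) / n, ncol = 1L)
  for (l in rev(seq_len(n_layers))) {
    a_prev <- fw$activations[[l]]
    gW[[l]] <- crossprod(a_prev, delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(params$W[[l]])) *
        (fw$activations[[l]] > 0)
    }
  }
  list(loss = loss, grads = list(W = gW, b = gb), prob = fw$prob)
}

#' Train the MLP correctness classifier
#'
#' Full-batch Adam on binary cross-entropy for the configured number of
#' epochs. Training is deterministic given the config seed.
#'
#' @param features Numeric matrix (or coercible), one row per trace, with
#'   `layer_sizes[1]` columns.
#' @param labels 0/1 vector (1 = correct answer); both classes must be
#'   present.
#' @param config An [mlp_config()].
#' @return An object of class `mlp_model`: `params`, `config`,
#'   `loss_trace`.
#' @export
train_mlp <- function(features, labels, config = mlp_config()) {
  stopifnot(inherits(config, "mlp_config"))
  x <- as.matrix(features)
  y <- as.numeric(labels)
  if (ncol(x) != config$layer_sizes[1L]) {
    stop("feature vectors must have length ", config$layer_sizes[1L])
  }
  if (length(y) != nrow(x)) stop("labels must match the number of rows")
  if (length(unique(y)) < 2) {
    stop("both classes must be present in the training labels")
  }
  params <- .mlp_init(config$layer_sizes, config$seed)
  m <- lapply(params, function(part) lapply(part, function(p) p * 0))
  v <- m
  loss_trace <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    lg <- mlp_loss_grads(params, x, y)
    loss_trace[epoch] <- lg$loss
    t_adam <- epoch
    for (part in c("W", "b")) {
      for (l in seq_along(params[[part]])) {
        g <- lg$grads[[part]][[l]]
        m[[part]][[l]] <- config$beta1 * m[[part]][[l]] +
          (1 - config$beta1) * g
        v[[part]][[l]] <- config$beta2 * v[[part]][[l]] +
          (1 - config$beta2) * g^2
        m_hat <- m[[part]][[l]] / (1 - config$beta1^t_adam)
        v_hat <- v[[part]][[l]] / (1 - config$beta2^t_adam)
        params[[part]][[l]] <- params[[part]][[l]] -
          config$learning_rate * m_hat / (sqrt(v_hat) + config$epsilon)
      }
    }
  }
  structure(
    list(params = params, config = config, loss_trace = loss_trace),
    class = "mlp_model"
  )
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> %s, final loss %.4f after %d epochs\n",
              paste(x$config$layer_sizes, collapse = "-"),
              x$loss_trace[length(x$loss_trace)], x$config$epochs))
  invisible(x)
}

#' Predict correctness probabilities and labels
#'
#' @param object A trained [train_mlp()] model.
#' @param features Numeric matrix or vector of inputs with the model's
#'   input width.
#' @param ... Unused.
#' @return Data frame with `prob` and `label` (probability >= 0.5 maps to
#'   label 1, the fixed tie convention).
#' @export
predict.mlp_model <- function(object, features, ...) {
  x <- features
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != object$config$layer_sizes[1L]) {
    stop("feature vectors must have length ",
         object$config$layer_sizes[1L])
  }
  prob <- mlp_forward(object$params, x)$prob
  data.frame(prob = prob, label = as.integer(prob >= 0.5))
}

#' Stratified k-fold cross-validation of the MLP
#'
#' Samples are shuffled within each class (seeded) and dealt round-robin
#' into `k` folds, so every fold contains both classes; each fold is held
#' out once while the MLP trains on the remainder. Fold accuracies are
#' aggregated as mean and population SD.
#'
#' @param features Numeric matrix, one row per trace.
#' @param labels 0/1 vector.
#' @param k Number of folds (default 4).
#' @param config An [mlp_config()].
#' @param seed Seed for the fold shuffling.
#' @return An object of class `cv_result`: `fold_accuracies`, `mean`,
#'   `popsd`, `fold_sizes`.
#' @export
kfold_cv <- function(features, labels, k = 4L, config = mlp_config(),
                     seed = 1L) {
  x <- as.matrix(features)
  y <- as.numeric(labels)
  n <- nrow(x)
  if (n < k) stop("need at least k samples")
  set.seed(seed)
  fold <- integer(n)
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  for (f in seq_len(k)) {
    if (length(unique(y[fold == f])) < 2) {
      stop("fold ", f, " does not contain both classes; ",
           "too few samples per class for ", k, " folds")
    }
  }
  acc <- numeric(k)
  for (f in seq_len(k)) {
    train <- fold != f
    model <- train_mlp(x[train, , drop = FALSE], y[train], config)
    pred <- predict(model, x[!train, , drop = FALSE])
    acc[f] <- mean(pred$label == y[!train])
  }
  ms <- mean_and_popsd(acc)
  structure(
    list(fold_accuracies = acc, mean = ms[["mean"]], popsd = ms[["sd"]],
         fold_sizes = as.integer(table(fold))),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> folds: %s | mean %.2f, popsd %.2f\n",
              paste(sprintf("%.2f", x$fold_accuracies), collapse = " "),
              x$mean, x$popsd))
  invisible(x)
}
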