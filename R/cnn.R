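# A small 1-D convolutional classifier whose weights live in one flat
# vector so a metaheuristic can train them in place of backpropagation.

#' Specify the classifier architecture
#'
#' A fixed small net: 1-D convolution (`conv_filters` filters of width
#' `kernel`, stride 1) over the input feature vector, ReLU, max-pooling of
#' width `pool`, one ReLU dense layer of width `hidden`, and a dense
#' softmax output over `classes` classes.
#'
#' @param input_len Length of the input feature vector (default 10: five
#'   GLCM statistics for each of the LL and HL subbands).
#' @param conv_filters,kernel Convolution filter count and width.
#' @param pool Max-pool width (and stride).
#' @param hidden Width of the dense hidden layer.
#' @param classes Number of output classes.
#' @return An object of class `network_spec`; `n_weights(spec)` gives the
#'   total parameter count.
#' @export
network_spec <- function(input_len = 10, conv_filters = 4, kernel = 3,
                         pool = 2, hidden = 8, classes = 2) {
  conv_out <- input_len - kernel + 1
  if (conv_out < pool)
    stop("input too short for this kernel/pool combination", call. = FALSE)
  pooled <- conv_out %/% pool
  flat <- pooled * conv_filters
  structure(list(
    input_len = input_len, conv_filters = conv_filters, kernel = kernel,
    pool = pool, hidden = hidden, classes = classes,
    conv_out = conv_out, pooled = pooled, flat = flat
  ), class = "network_spec")
}

#' @rdname network_spec
#' @param spec A `network_spec`.
#' @export
n_weights <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  with(spec, kernel * conv_filters + conv_filters +   # conv W + b
         flat * hidden + hidden +                     # dense1 W + b
         hidden * classes + classes)                  # dense2 W + b
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf(
    "<network_spec> %d -> conv(%d x %d) -> relu -> pool(%d) -> dense(%d) -> dense(%d) [%d weights]\n",
    x$input_len, x$conv_filters, x$kernel, x$pool, x$hidden, x$classes,
    n_weights(x)))
  invisible(x)
}

# split the flat weight vector into the layer tensors
unflatten_weights <- function(spec, weights) {
  if (length(weights) != n_weights(spec))
    stop("weight vector length does not match the architecture", call. = FALSE)
  pos <- 0
  take <- function(n) {
    out <- weights[pos + seq_len(n)]; pos <<- pos + n; out
  }
  list(
    Wc = matrix(take(spec$kernel * spec$conv_filters), spec$kernel),
    bc = take(spec$conv_filters),
    W1 = matrix(take(spec$flat * spec$hidden), spec$flat),
    b1 = take(spec$hidden),
    W2 = matrix(take(spec$hidden * spec$classes), spec$hidden),
    b2 = take(spec$classes)
  )
}

flatten_weights <- function(layers) {
  c(as.vector(layers$Wc), layers$bc, as.vector(layers$W1), layers$b1,
    as.vector(layers$W2), layers$b2)
}

relu <- function(x) pmax(x, 0)

#' Forward pass of the classifier
#'
#' Convolution, ReLU, max-pooling, dense ReLU layer, dense output layer
#' and row-wise softmax `z_j = exp(f_j) / sum_i exp(f_i)` (computed with
#' the max-subtraction trick). Vectorized over samples.
#'
#' @param spec A [network_spec()].
#' @param weights Flat numeric weight vector of length `n_weights(spec)`.
#' @param x A single feature vector or an `n x input_len` matrix.
#' @return An `n x classes` matrix of class probabilities; every row sums
#'   to 1.
#' @export
cnn_forward <- function(spec, weights, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != spec$input_len)
    stop("feature length does not match `spec$input_len`", call. = FALSE)
  ly <- unflatten_weights(spec, weights)
  n <- nrow(x)

  # conv: one small matmul per output position
  conv <- array(0, c(n, spec$conv_out, spec$conv_filters))
  for (p in seq_len(spec$conv_out)) {
    conv[, p, ] <- x[, p:(p + spec$kernel - 1), drop = FALSE] %*% ly$Wc +
      matrix(ly$bc, n, spec$conv_filters, byrow = TRUE)
  }
  conv <- relu(conv)

  # max-pool along positions
  pooled <- array(0, c(n, spec$pooled, spec$conv_filters))
  for (p in seq_len(spec$pooled)) {
    seg <- conv[, ((p - 1) * spec$pool + 1):(p * spec$pool), , drop = FALSE]
    pooled[, p, ] <- apply(seg, c(1, 3), max)
  }

  flat <- matrix(pooled, n, spec$flat)
  h <- relu(flat %*% ly$W1 + matrix(ly$b1, n, spec$hidden, byrow = TRUE))
  logits <- h %*% ly$W2 + matrix(ly$b2, n, spec$classes, byrow = TRUE)
  z <- exp(logits - apply(logits, 1, max))
  z / rowSums(z)
}

# targets: factor/integer labels or one-hot matrix -> one-hot matrix
as_one_hot <- function(targets, classes) {
  if (is.matrix(targets)) {
    if (ncol(targets) != classes) stop("one-hot width mismatch", call. = FALSE)
    return(targets)
  }
  idx <- if (is.factor(targets)) as.integer(targets) else as.integer(targets)
  Y <- matrix(0, length(idx), classes)
  Y[cbind(seq_along(idx), idx)] <- 1
  Y
}

#' Penalized cross-entropy loss
#'
#' `L = sum_j sum_i -d log z + (rho / 2) * sum W^2`. Probabilities are
#' clipped at `1e-12` before the log. Reported as a training diagnostic;
#' the optimizer minimizes [mse_fitness()].
#'
#' @param probabilities `n x classes` probability matrix.
#' @param targets One-hot matrix, or integer/factor labels.
#' @param weights Optional flat weight vector for the penalty term.
#' @param rho Weight-penalty coefficient (>= 0).
#' @return The scalar loss (natural-log convention); non-negative for
#'   `rho >= 0`.
#' @export
cross_entropy <- function(probabilities, targets, weights = NULL, rho = 0) {
  Y <- as_one_hot(targets, ncol(probabilities))
  p <- pmax(probabilities, 1e-12)
  loss <- -sum(Y * log(p))
  if (rho > 0 && !is.null(weights)) loss <- loss + rho / 2 * sum(weights^2)
  loss
}

#' Mean-squared-error fitness of a weight vector
#'
#' The training objective handed to the optimizer:
#' `(1 / N) * sum_samples sum_classes (z - d)^2` where `z` is the softmax
#' output and `d` the one-hot target.
#'
#' @param spec A [network_spec()].
#' @param weights Flat weight vector.
#' @param x `n x input_len` feature matrix.
#' @param targets One-hot matrix or labels.
#' @return The mean squared error (scalar, >= 0).
#' @export
mse_fitness <- function(spec, weights, x, targets) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  Y <- as_one_hot(targets, spec$classes)
  Z <- cnn_forward(spec, weights, x)
  sum((Z - Y)^2) / nrow(x)
}

#' Train the classifier with the advanced thermal-exchange optimizer
#'
#' Treats the flat weight vector as the optimizer's search position inside
#' the symmetric box `[-bound, bound]^W` and minimizes [mse_fitness()] on
#' the training set, replacing backpropagation. Elitism guarantees the
#' training-MSE history is non-increasing.
#'
#' @param x `n x input_len` training feature matrix.
#' @param labels Integer (1-based), factor labels, or one-hot matrix.
#' @param spec A [network_spec()] (default matches `ncol(x)`).
#' @param config A [teo_config()]; bounds are overridden by `bound`. The
#'   default uses a fixed population of 150 and a 2e4-evaluation budget.
#' @param bound Half-width of the weight box (default 5).
#' @param seed Optional seed for the training run.
#' @return An object of class `ateo_cnn`: list with `spec`, `weights`,
#'   `fit` (the underlying `ateo_fit`), `levels` (class labels).
#' @export
train_with_ateo <- function(x, labels, spec = NULL, config = NULL,
                            bound = 5, seed = NULL) {
  x <- as.matrix(x)
  if (is.null(spec)) spec <- network_spec(input_len = ncol(x))
  lv <- if (is.factor(labels)) levels(labels) else
    as.character(sort(unique(labels)))
  Y <- as_one_hot(if (is.factor(labels)) labels else
    factor(labels, levels = lv), spec$classes)
  W <- n_weights(spec)
  if (is.null(config))
    config <- teo_config(pop_size = 150, max_fes = 2e4)
  config$lower <- -bound; config$upper <- bound
  if (!is.null(seed)) config$seed <- seed

  objective <- function(P) {
    apply(P, 1, function(w) mse_fitness(spec, w, x, Y))
  }
  attr(objective, "vectorized") <- TRUE
  fit <- run_ateo(objective, d = W, config = config)
  structure(list(spec = spec, weights = fit$best_position, fit = fit,
                 levels = lv), class = "ateo_cnn")
}

#' @export
print.ateo_cnn <- function(x, ...) {
  cat(sprintf("<ateo_cnn> %d weights, training MSE %.4g after %d evaluations\n",
              n_weights(x$spec), x$fit$best_cost, x$fit$fe_count))
  invisible(x)
}

#' Predict classes with a trained classifier
#'
#' Argmax of the softmax output; exact probability ties resolve to the
#' first (benign/negative) class.
#'
#' @param object An `ateo_cnn` from [train_with_ateo()].
#' @param newdata Feature matrix.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @return A factor of class labels, or the probability matrix.
#' @export
predict.ateo_cnn <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  Z <- cnn_forward(object$spec, object$weights, as.matrix(newdata))
  if (type == "prob") return(Z)
  idx <- max.col(Z, ties.method = "first")
  factor(object$levels[idx], levels = object$levels)
}

#' @method tidy ateo_cnn
#' @export
tidy.ateo_cnn <- function(x, ...) x$fit$history

#' @method glance ateo_cnn
#' @export
glance.ateo_cnn <- function(x, ...) {
  tibble::tibble(n_weights = n_weights(x$spec),
                 training_mse = x$fit$best_cost,
                 fe_count = x$fit$fe_count,
                 iterations = x$fit$iterations)
}

#' Confusion counts of a binary prediction
#'
#' @param truth,prediction Vectors of class labels.
#' @param positive The positive-class label (default `"malignant"`).
#' @return A named list with integer `tp`, `tn`, `fp`, `fn`; they sum to
#'   the number of samples.
#' @export
confusion_counts <- function(truth, prediction, positive = "malignant") {
  truth_pos <- truth == positive
  pred_pos <- prediction == positive
  list(tp = sum(truth_pos & pred_pos), tn = sum(!truth_pos & !pred_pos),
       fp = sum(!truth_pos & pred_pos), fn = sum(truth_pos & !pred_pos))
}

#' Accuracy, sensitivity and specificity (percent)
#'
#' `accuracy = (TP + TN) / (TP + FP + FN + TN)`,
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (FP + TN)`, each
#' multiplied by 100. An empty denominator raises an error rather than
#' silently reporting 0.
#'
#' @param counts List with `tp`, `tn`, `fp`, `fn` (see
#'   [confusion_counts()]).
#' @return A one-row tibble with `accuracy`, `sensitivity`, `specificity`
#'   in percent.
#' @export
evaluate_metrics <- function(counts) {
  with(counts, {
    total <- tp + tn + fp + fn
    if (total == 0) stop("no samples", call. = FALSE)
    if (tp + fn == 0)
      stop("sensitivity undefined: no positive samples", call. = FALSE)
    if (tn + fp == 0)
      stop("specificity undefined: no negative samples", call. = FALSE)
    tibble::tibble(
      accuracy = 100 * (tp + tn) / total,
      sensitivity = 100 * tp / (tp + fn),
      specificity = 100 * tn / (fp + tn)
    )
  })
}
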