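# Classifier forward pass, losses, metaheuristic training, and metrics.

test_that("weight vector length and flatten/unflatten bijection hold", {
  spec <- network_spec()
  # conv 3x4+4, dense 16x8+8, dense 8x2+2
  expect_equal(n_weights(spec), 12 + 4 + 128 + 8 + 16 + 2)

  set.seed(41)
  for (rep in 1:100) {
    w <- rnorm(n_weights(spec))
    expect_identical(
      ateopipe:::flatten_weights(ateopipe:::unflatten_weights(spec, w)), w)
  }
  expect_error(ateopipe:::unflatten_weights(spec, rnorm(5)), "length")
})

test_that("zero weights give exact chance; softmax rows always normalize", {
  spec <- network_spec()
  p0 <- cnn_forward(spec, rep(0, n_weights(spec)), runif(10))
  expect_equal(as.numeric(p0), c(0.5, 0.5))

  set.seed(42)
  X <- matrix(rnorm(50), 5, 10)
  w <- rnorm(n_weights(spec))
  P <- cnn_forward(spec, w, X)
  expect_equal(rowSums(P), rep(1, 5), tolerance = 1e-12)
  expect_true(all(P >= 0))
  expect_error(cnn_forward(spec, w, rnorm(7)), "length")
})

test_that("a hand-computed tiny network matches the forward pass", {
  spec <- network_spec(input_len = 4, conv_filters = 1, kernel = 3,
                       pool = 2, hidden = 1, classes = 2)
  # weights: conv (3) + bias (1) + dense1 (1x1 + 1) + dense2 (1x2 + 2)
  w <- c(1, -1, 0.5, 0.1,   0.7, -0.2,   2, -2, 0.3, -0.3)
  x <- c(0.2, 0.4, 0.6, 0.8)
  # conv position 1: 0.2 - 0.4 + 0.3 + 0.1 = 0.2; position 2: 0.4 - 0.6 + 0.4 + 0.1 = 0.3
  # relu -> (0.2, 0.3); pool(2) -> 0.3; dense1: relu(0.3*0.7 - 0.2) = 0.01
  # logits: (0.01*2 + 0.3, 0.01*(-2) - 0.3) = (0.32, -0.32)
  manual <- exp(c(0.32, -0.32)); manual <- manual / sum(manual)
  expect_equal(as.numeric(cnn_forward(spec, w, x)), manual,
               tolerance = 1e-12)
})

test_that("cross-entropy handles perfect, uniform, and penalized cases", {
  perfect <- matrix(c(1, 0), 1, 2)
  expect_equal(cross_entropy(perfect, matrix(c(1, 0), 1, 2)), 0)

  unif <- matrix(0.5, 1, 2)
  expect_equal(cross_entropy(unif, matrix(c(1, 0), 1, 2)), log(2))

  w <- c(1, 2, 3)
  base <- cross_entropy(unif, matrix(c(1, 0), 1, 2))
  pen <- cross_entropy(unif, matrix(c(1, 0), 1, 2), weights = w, rho = 0.4)
  expect_equal(pen - base, 0.4 / 2 * sum(w^2))
  expect_gte(cross_entropy(matrix(c(0, 1), 1, 2), matrix(c(1, 0), 1, 2)), 0)
})

test_that("MSE fitness equals a loop-based recomputation", {
  spec <- network_spec()
  set.seed(43)
  X <- matrix(rnorm(80), 8, 10)
  y <- rep(1:2, 4)
  w <- rnorm(n_weights(spec))

  got <- mse_fitness(spec, w, X, y)
  # independent re-accumulation, one sample at a time
  acc <- 0
  for (i in 1:8) {
    z <- cnn_forward(spec, w, X[i, ])
    d <- c(0, 0); d[y[i]] <- 1
    acc <- acc + sum((z - d)^2)
  }
  expect_equal(got, acc / 8, tolerance = 1e-12)

  # uniform outputs against one-hot targets: 0.5 per sample
  expect_equal(mse_fitness(spec, rep(0, n_weights(spec)), X, y), 0.5)
})

test_that("metaheuristic training is elitist, deterministic, and learns", {
  spec <- network_spec()
  set.seed(44)
  x1 <- matrix(rnorm(10), 1, 10)
  cfg <- teo_config(pop_size = 30, max_fes = 600)
  m1 <- train_with_ateo(x1, 2L, spec = NULL, config = cfg, seed = 7)
  h <- m1$fit$history$best_cost
  expect_false(is.unsorted(rev(h)))
  expect_lte(h[length(h)], h[1])

  m1b <- train_with_ateo(x1, 2L, config = cfg, seed = 7)
  expect_identical(m1$weights, m1b$weights)
})

test_that("two separated Gaussian classes are learned to high accuracy", {
  set.seed(45)
  n <- 200
  X <- rbind(matrix(rnorm(n / 2 * 10, -1, 1), n / 2, 10),
             matrix(rnorm(n / 2 * 10, +1, 1), n / 2, 10))
  y <- factor(rep(c("benign", "malignant"), each = n / 2))
  test_idx <- sample.int(n, 60)

  model <- train_with_ateo(X[-test_idx, ], droplevels(y[-test_idx]),
                           config = teo_config(pop_size = 150,
                                               max_fes = 2e4),
                           seed = 46)
  train_acc <- mean(predict(model, X[-test_idx, ]) == y[-test_idx])
  expect_gte(train_acc, 0.95)
  held_acc <- mean(predict(model, X[test_idx, ]) == y[test_idx])
  expect_gte(held_acc, 0.9)
})

test_that("confusion metrics follow the percentage formulas exactly", {
  expect_equal(as.numeric(evaluate_metrics(list(tp = 5, tn = 5, fp = 0, fn = 0))),
               c(100, 100, 100))
  expect_equal(as.numeric(evaluate_metrics(list(tp = 3, tn = 1, fp = 1, fn = 0))),
               c(80, 100, 50))

  set.seed(47)
  for (rep in 1:20) {
    cts <- as.list(rpois(4, 5) + 1)
    names(cts) <- c("tp", "tn", "fp", "fn")
    m <- evaluate_metrics(cts)
    expect_equal(m$accuracy,
                 100 * (cts$tp + cts$tn) / (cts$tp + cts$tn + cts$fp + cts$fn))
    expect_equal(m$sensitivity, 100 * cts$tp / (cts$tp + cts$fn))
    expect_equal(m$specificity, 100 * cts$tn / (cts$tn + cts$fp))
  }
  expect_error(evaluate_metrics(list(tp = 0, tn = 2, fp = 1, fn = 0)),
               "sensitivity")
  expect_error(evaluate_metrics(list(tp = 1, tn = 0, fp = 0, fn = 1)),
               "specificity")

  truth <- c("benign", "malignant", "malignant", "benign")
  pred <- c("benign", "malignant", "benign", "malignant")
  cc <- confusion_counts(truth, pred)
  expect_equal(cc, list(tp = 1L, tn = 1L, fp = 1L, fn = 1L))
  expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, 4L)
})
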