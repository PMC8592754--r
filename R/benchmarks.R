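# Analytic test functions and the multi-run statistical harness used to
# evaluate the optimizer (mean/std of final errors over independent runs).

bench_defs <- list(
  sphere = list(
    fn = function(X) rowSums(X^2),
    xopt = function(d) rep(0, d)
  ),
  bent_cigar = list(
    fn = function(X) X[, 1]^2 + 1e6 * rowSums(X[, -1, drop = FALSE]^2),
    xopt = function(d) rep(0, d)
  ),
  rastrigin = list(
    fn = function(X) rowSums(X^2 - 10 * cos(2 * pi * X) + 10),
    xopt = function(d) rep(0, d)
  ),
  rosenbrock = list(
    fn = function(X) {
      a <- X[, -ncol(X), drop = FALSE]
      b <- X[, -1, drop = FALSE]
      rowSums(100 * (b - a^2)^2 + (1 - a)^2)
    },
    xopt = function(d) rep(1, d)
  ),
  ackley = list(
    fn = function(X) {
      d <- ncol(X)
      -20 * exp(-0.2 * sqrt(rowSums(X^2) / d)) -
        exp(rowSums(cos(2 * pi * X)) / d) + 20 + exp(1)
    },
    xopt = function(d) rep(0, d)
  ),
  griewank = list(
    fn = function(X) {
      d <- ncol(X)
      prod_term <- apply(cos(sweep(X, 2, sqrt(seq_len(d)), `/`)), 1, prod)
      rowSums(X^2) / 4000 - prod_term + 1
    },
    xopt = function(d) rep(0, d)
  ),
  schwefel_12 = list(
    fn = function(X) {
      # double-sum: sum_i (sum_{j<=i} x_j)^2
      rowSums(t(apply(X, 1, cumsum))^2)
    },
    xopt = function(d) rep(0, d)
  ),
  exp_griewank_rosenbrock = list(
    fn = function(X) {
      Z <- X + 1  # shift so the optimum sits at the origin
      Zn <- cbind(Z[, -1, drop = FALSE], Z[, 1])
      r <- 100 * (Z^2 - Zn)^2 + (Z - 1)^2
      rowSums(r^2 / 4000 - cos(r) + 1)
    },
    xopt = function(d) rep(0, d)
  )
)

#' Analytic benchmark functions
#'
#' A small suite of unshifted analytic test functions (sphere, bent cigar,
#' Rastrigin, Rosenbrock, Ackley, Griewank, Schwefel double-sum, expanded
#' Griewank-Rosenbrock) on the symmetric box `[-100, 100]^d`, each with a
#' known optimum of value 0. `benchmark_suite()` lists the available names.
#'
#' @param name Function name, one of `benchmark_suite()`.
#' @param dimension Problem dimension (>= 2 for the coupled functions).
#' @param bound Half-width of the symmetric box (default 100).
#' @return An object of class `benchmark_function`: list with `name`,
#'   `dimension`, `lower`, `upper`, `xopt`, `fopt` (= 0) and `fn`, the
#'   vectorized evaluator over row-matrices of candidates.
#' @export
#' @examples
#' f <- benchmark_function("sphere", 10)
#' evaluate_benchmark(f, rep(0, 10))  # 0 at the optimum
benchmark_function <- function(name, dimension, bound = 100) {
  name <- match.arg(name, names(bench_defs))
  if (dimension < 2 && name %in% c("rosenbrock", "exp_griewank_rosenbrock",
                                   "bent_cigar"))
    stop(sprintf("`%s` needs dimension >= 2", name), call. = FALSE)
  def <- bench_defs[[name]]
  fn <- def$fn
  attr(fn, "vectorized") <- TRUE
  structure(list(
    name = name, dimension = as.integer(dimension),
    lower = rep(-bound, dimension), upper = rep(bound, dimension),
    xopt = def$xopt(dimension), fopt = 0, fn = fn
  ), class = "benchmark_function")
}

#' @rdname benchmark_function
#' @export
benchmark_suite <- function() names(bench_defs)

#' Evaluate a benchmark function
#'
#' @param f A [benchmark_function()].
#' @param x A length-`dimension` vector or a row-matrix of candidates.
#' @return The function value(s); the error of a value is
#'   `value - f$fopt`.
#' @export
evaluate_benchmark <- function(f, x) {
  stopifnot(inherits(f, "benchmark_function"))
  if (is.null(dim(x))) {
    if (length(x) != f$dimension)
      stop("dimension mismatch", call. = FALSE)
    x <- matrix(x, nrow = 1)
  } else if (ncol(x) != f$dimension) {
    stop("dimension mismatch", call. = FALSE)
  }
  drop(f$fn(x))
}

#' Repeated independent optimizer runs on one benchmark function
#'
#' Runs an algorithm `n_runs` times with per-run seeds, records each run's
#' final error (best cost minus the known optimum), floors errors below
#' `error_floor` to exactly 0, and summarizes with mean and standard
#' deviation.
#'
#' @param algorithm `"ateo"`, `"teo"`, or a function
#'   `(objective, d, config) -> ateo_fit`.
#' @param f A [benchmark_function()].
#' @param n_runs Number of independent runs.
#' @param max_fes Evaluation budget per run.
#' @param error_floor Errors at or below this are recorded as 0.
#' @param seeds Integer vector of per-run seeds (default `1:n_runs`).
#' @param config Optional [teo_config()] template; bounds, budget, floor
#'   and seed are overwritten per run.
#' @return A one-row tibble: `algorithm`, `fname`, `dimension`, `mean`,
#'   `std`, `n_runs`, plus a list-column `errors` of the per-run finals.
#' @export
run_trials <- function(algorithm, f, n_runs, max_fes = 1e4,
                       error_floor = 1e-8, seeds = seq_len(n_runs),
                       config = NULL) {
  stopifnot(inherits(f, "benchmark_function"), n_runs >= 1,
            length(seeds) == n_runs)
  alg_name <- if (is.character(algorithm)) algorithm else "custom"
  runner <- if (is.function(algorithm)) {
    algorithm
  } else if (identical(algorithm, "ateo")) {
    run_ateo
  } else if (identical(algorithm, "teo")) {
    run_teo
  } else stop("unknown algorithm: ", algorithm, call. = FALSE)

  if (is.null(config)) config <- teo_config()
  errors <- vapply(seq_len(n_runs), function(i) {
    cfg <- config
    cfg$lower <- f$lower; cfg$upper <- f$upper
    cfg$max_fes <- max_fes; cfg$error_floor <- error_floor
    cfg$seed <- seeds[i]
    fit <- runner(f$fn, f$dimension, cfg)
    err <- fit$best_cost - f$fopt
    if (err <= error_floor) 0 else err
  }, numeric(1))

  tibble::tibble(
    algorithm = alg_name, fname = f$name, dimension = f$dimension,
    mean = mean(errors), std = if (n_runs > 1) stats::sd(errors) else 0,
    n_runs = as.integer(n_runs), errors = list(errors)
  )
}

#' Benchmark table over the whole suite
#'
#' Applies [run_trials()] to every requested function for one or more
#' algorithms and binds the rows, mirroring the usual
#' function-by-(Mean, Std) comparison table.
#'
#' @param algorithms Character vector, subset of `c("ateo", "teo")`.
#' @param functions Character vector of suite names
#'   (default: all of [benchmark_suite()]).
#' @param dimension Problem dimension.
#' @inheritParams run_trials
#' @return A tibble with one row per (algorithm, function).
#' @export
run_benchmark <- function(algorithms = c("ateo", "teo"),
                          functions = benchmark_suite(),
                          dimension = 20, n_runs = 10, max_fes = 1e5,
                          error_floor = 1e-8, seeds = seq_len(n_runs),
                          config = NULL) {
  rows <- purrr::map(functions, function(fname) {
    f <- benchmark_function(fname, dimension)
    purrr::map(algorithms, function(alg) {
      run_trials(alg, f, n_runs, max_fes, error_floor, seeds, config)
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}
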