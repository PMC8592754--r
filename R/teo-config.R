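#' Control settings for the thermal-exchange optimizer
#'
#' Bundles every tunable of [run_teo()] / [run_ateo()]. The defaults follow
#' the ranges customary in the thermal-exchange literature; all of them can
#' be overridden per run.
#'
#' @param lower,upper Box bounds of the search space. Scalars are recycled
#'   to the problem dimension when the optimizer starts.
#' @param alpha1,alpha2 Environmental-temperature control variables in
#'   `[0, 1]`; they damp the paired environment temperature as
#'   `(1 - (alpha1 + alpha2 * (1 - t)) * delta)`.
#' @param gamma Exchange coefficient (> 0) scaling the difference vector in
#'   the worst-member exchange step.
#' @param cg Crossover constant in `[0, 1]`: per-dimension probability that
#'   the trial vector takes the exchange component.
#' @param pr Component-perturbation probability in `[0, 1]`.
#' @param tm_size Thermal-memory (elite archive) capacity. `NULL` means
#'   `ceiling(PS / 10)` where `PS` is the initial population size.
#' @param pop_size Initial population size. `NULL` means `10 * d`
#'   (the self-adaptive rule's starting point); a fixed value such as 150
#'   reproduces the fixed-population protocol.
#' @param max_fes Budget of objective-function evaluations.
#' @param error_floor Cost value at which the run stops early (treat the
#'   problem as solved).
#' @param perturbation_decay If `TRUE` the perturbed component's offset is
#'   damped by `exp(-zeta * t)`; `FALSE` reproduces the classic
#'   un-damped reset.
#' @param adapt_population If `TRUE` (and the advanced variant is running)
#'   the population size is resized every iteration.
#' @param seed Optional integer seed; when non-`NULL` the run seeds R's RNG
#'   so results are reproducible.
#'
#' @return An object of class `teo_config` (a named list).
#' @export
#' @examples
#' cfg <- teo_config(lower = -5, upper = 5, max_fes = 2000)
#' fit <- run_ateo(function(x) sum(x^2), d = 2, config = cfg)
#' glance(fit)
teo_config <- function(lower = -100, upper = 100,
                       alpha1 = 0.3, alpha2 = 0.3,
                       gamma = 0.5, cg = 0.5, pr = 0.3,
                       tm_size = NULL, pop_size = NULL,
                       max_fes = 10000, error_floor = 0,
                       perturbation_decay = TRUE,
                       adapt_population = TRUE,
                       seed = NULL) {
  chk01 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 || x > 1)
      stop(sprintf("`%s` must be a single value in [0, 1]", nm), call. = FALSE)
  }
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("bounds must be finite", call. = FALSE)
  if (any(lower >= upper))
    stop("each lower bound must be strictly below its upper bound", call. = FALSE)
  chk01(alpha1, "alpha1"); chk01(alpha2, "alpha2")
  chk01(cg, "cg"); chk01(pr, "pr")
  if (!is.numeric(gamma) || gamma < 0)
    stop("`gamma` must be a non-negative number", call. = FALSE)
  if (!is.null(tm_size) && (tm_size < 1 || tm_size != round(tm_size)))
    stop("`tm_size` must be a positive integer", call. = FALSE)
  if (!is.null(pop_size) && (pop_size < 2 || pop_size != round(pop_size)))
    stop("`pop_size` must be an integer >= 2", call. = FALSE)
  if (max_fes < 1) stop("`max_fes` must be positive", call. = FALSE)
  if (error_floor < 0) stop("`error_floor` must be >= 0", call. = FALSE)
  structure(list(
    lower = lower, upper = upper,
    alpha1 = alpha1, alpha2 = alpha2,
    gamma = gamma, cg = cg, pr = pr,
    tm_size = tm_size, pop_size = pop_size,
    max_fes = max_fes, error_floor = error_floor,
    perturbation_decay = perturbation_decay,
    adapt_population = adapt_population,
    seed = seed
  ), class = "teo_config")
}

#' @export
print.teo_config <- function(x, ...) {
  cat("<teo_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-20s %s\n", nm,
                if (is.null(v)) "<auto>" else paste(format(v), collapse = ", ")))
  }
  invisible(x)
}

# expand scalar-or-vector bounds to dimension d
expand_bounds <- function(config, d) {
  lower <- rep_len(config$lower, d)
  upper <- rep_len(config$upper, d)
  if (any(lower >= upper)) stop("invalid bounds after recycling", call. = FALSE)
  list(lower = lower, upper = upper)
}
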