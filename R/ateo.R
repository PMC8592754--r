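# Thermal Exchange Optimization (TEO) and its Advanced variant (ATEO).
#
# Candidates are "temperatures": each iteration the population is sorted,
# split into a better (environment) and a worse (cooling) half, and every
# cooling object relaxes toward its paired environment object following
# Newton's law of cooling. The advanced variant adds a best-guided exchange
# vector for the worst member and a self-adaptive population size.

# evaluate a matrix of candidates (rows); objectives may declare
# attr(obj, "vectorized") <- TRUE to receive the whole matrix at once
eval_batch <- function(objective, X) {
  costs <- if (isTRUE(attr(objective, "vectorized"))) {
    objective(X)
  } else {
    apply(X, 1, objective)
  }
  costs <- as.numeric(costs)
  if (length(costs) != nrow(X))
    stop("objective returned wrong number of costs", call. = FALSE)
  bad <- which(!is.finite(costs))
  if (length(bad)) {
    stop(sprintf(
      "objective returned a non-finite cost for candidate [%s]",
      paste(signif(X[bad[1], ], 4), collapse = ", ")), call. = FALSE)
  }
  costs
}

#' Initialize a random optimizer population
#'
#' Draws the initial "temperatures" uniformly inside the box bounds:
#' each component is `lower_j + theta * (upper_j - lower_j)` with
#' `theta ~ U[0, 1]`. The population size is `config$pop_size`, defaulting
#' to `10 * d`. All candidates are evaluated, so the returned state has
#' `fe_count` equal to the population size. Randomness comes from R's
#' global RNG; seed it (or set `config$seed`) for reproducibility.
#'
#' @param objective Function mapping a length-`d` numeric vector to a
#'   finite cost (or, if it carries `attr(, "vectorized") = TRUE`, a
#'   row-matrix of candidates to a cost vector).
#' @param d Problem dimension (>= 1).
#' @param config A [teo_config()].
#' @return An optimizer state: list with `positions` (PS x d matrix),
#'   `costs`, `fe_count`, `iteration`, `best` (list of `position`, `cost`)
#'   and an empty thermal memory.
#' @export
init_population <- function(objective, d, config) {
  stopifnot(d >= 1)
  b <- expand_bounds(config, d)
  ps <- if (is.null(config$pop_size)) 10L * as.integer(d) else as.integer(config$pop_size)
  theta <- matrix(runif(ps * d), ps, d)
  positions <- sweep(sweep(theta, 2, b$upper - b$lower, `*`), 2, b$lower, `+`)
  costs <- eval_batch(objective, positions)
  ib <- which.min(costs)
  list(
    positions = positions, costs = costs,
    fe_count = ps, iteration = 0L,
    best = list(position = positions[ib, ], cost = costs[ib]),
    tm_positions = NULL, tm_costs = NULL,
    lower = b$lower, upper = b$upper
  )
}

#' Cooling factor of a candidate
#'
#' The dimensionless cooling rate `zeta` of a candidate is the ratio of its
#' cost to the worst (largest) cost in the population. A degenerate
#' population whose worst cost is exactly zero returns 0 for every member.
#'
#' @param cost Cost value(s) of the candidate(s).
#' @param worst_cost Worst cost in the current population.
#' @return `cost / worst_cost`, or 0 when `worst_cost == 0`.
#' @export
cooling_factor <- function(cost, worst_cost) {
  if (worst_cost == 0) return(rep(0, length(cost)))
  cost / worst_cost
}

#' Normalized iteration time
#'
#' @param iteration Current iteration (0-based).
#' @param max_iteration Total number of iterations (>= 1).
#' @return `iteration / max_iteration`, in `[0, 1]`.
#' @export
time_value <- function(iteration, max_iteration) {
  if (max_iteration < 1) stop("`max_iteration` must be >= 1", call. = FALSE)
  if (iteration < 0 || iteration > max_iteration)
    stop("`iteration` must lie in [0, max_iteration]", call. = FALSE)
  iteration / max_iteration
}

#' Pair cooling objects with environment objects
#'
#' Sorts the population by cost and pairs rank `i` of the better half with
#' rank `n/2 + i` of the worse half, mutually: the best member is the
#' environment for the first member of the worse half and vice versa. Odd
#' populations are padded by duplicating the best member (with a message).
#'
#' @param state An optimizer state (see [init_population()]).
#' @param quiet Suppress the padding message (used inside the run loop,
#'   where the `ps` history column records any padding).
#' @return List with the (possibly padded) sorted `state` and `pairs`, a
#'   tibble with integer columns `cooling` and `environment`; every rank
#'   appears exactly once as a cooling object.
#' @export
pair_objects <- function(state, quiet = FALSE) {
  n <- length(state$costs)
  if (n < 2) stop("population too small to pair (need >= 2)", call. = FALSE)
  ord <- order(state$costs)
  state$positions <- state$positions[ord, , drop = FALSE]
  state$costs <- state$costs[ord]
  if (n %% 2 == 1) {
    if (!quiet)
      message("odd population size; padding with a duplicate of the best member")
    state$positions <- rbind(state$positions, state$positions[1, ])
    state$costs <- c(state$costs, state$costs[1])
    n <- n + 1L
  }
  half <- n %/% 2L
  pairs <- tibble::tibble(
    cooling = seq_len(n),
    environment = c(seq_len(half) + half, seq_len(half))
  )
  list(state = state, pairs = pairs)
}

#' Updated environment temperature
#'
#' Damps the paired environment object's position to encourage global
#' search: `(1 - (alpha1 + alpha2 * (1 - t)) * delta) * prev_env`.
#'
#' @param prev_env Environment position (numeric vector).
#' @param alpha1,alpha2 Control variables in `[0, 1]`.
#' @param t Normalized time in `[0, 1]`.
#' @param delta Random draw in `[0, 1]`.
#' @return The damped environment vector.
#' @export
env_temperature <- function(prev_env, alpha1, alpha2, t, delta) {
  (1 - (alpha1 + alpha2 * (1 - t)) * delta) * prev_env
}

#' Newton-cooling position update
#'
#' Moves a candidate toward its (damped) environment temperature:
#' `t_env + (t_old - t_env) * exp(-zeta * t)`, clamped to the bounds.
#'
#' @param t_old Current position.
#' @param t_env Environment position (after [env_temperature()]).
#' @param zeta Cooling factor (>= 0), see [cooling_factor()].
#' @param t Normalized time.
#' @param lower,upper Bound vectors.
#' @return The new, clamped position.
#' @export
update_position <- function(t_old, t_env, zeta, t, lower, upper) {
  clamp(t_env + (t_old - t_env) * exp(-zeta * t), lower, upper)
}

#' Random single-component perturbation
#'
#' With probability `pr` one uniformly chosen dimension `j` is reset to
#' `lower_j + delta * (upper_j - lower_j) * exp(-zeta * t)` with
#' `delta ~ U[0, 1]` (the `exp` damping can be switched off to recover the
#' classic un-damped reset), then clamped.
#'
#' @param position Candidate position vector.
#' @param lower,upper Bound vectors.
#' @param pr Perturbation probability.
#' @param zeta Cooling factor of the candidate.
#' @param t Normalized time.
#' @param decay Apply the `exp(-zeta * t)` damping? Default `TRUE`.
#' @return List with the (possibly modified) `position` and `changed` flag.
#' @export
component_perturbation <- function(position, lower, upper, pr, zeta, t,
                                   decay = TRUE) {
  if (runif(1) >= pr) return(list(position = position, changed = FALSE))
  d <- length(position)
  j <- if (d == 1) 1L else sample.int(d, 1L)
  delta <- runif(1)
  damp <- if (decay) exp(-zeta * t) else 1
  position[j] <- clamp(lower[j] + delta * (upper[j] - lower[j]) * damp,
                       lower[j], upper[j])
  list(position = position, changed = TRUE)
}

#' Exchange vector for the worst member
#'
#' Builds the best-guided exchange vector
#' `best + gamma * (pos_r1 - pos_r2)` with `r1 != r2` drawn uniformly from
#' the population, clamped to the bounds.
#'
#' @param best_position Best position found so far this iteration.
#' @param positions Population matrix (rows are candidates).
#' @param gamma Exchange coefficient.
#' @param lower,upper Bound vectors.
#' @return The clamped exchange vector, or `NULL` when the population has
#'   fewer than 3 members (exchange skipped).
#' @export
ateo_exchange <- function(best_position, positions, gamma, lower, upper) {
  n <- nrow(positions)
  if (n < 3) return(NULL)
  r <- sample.int(n, 2L)
  clamp(best_position + gamma * (positions[r[1], ] - positions[r[2], ]),
        lower, upper)
}

#' Binomial crossover with greedy acceptance
#'
#' Builds a trial vector taking the exchange component where
#' `rand_j < cg` and the worst member's component otherwise; the trial
#' replaces the worst member only if its cost is lower. With `cg = 0` the
#' trial equals the worst member and no evaluation is spent.
#'
#' @param worst_position,worst_cost The worst member and its cost.
#' @param exchange Exchange vector (see [ateo_exchange()]).
#' @param cg Crossover constant in `[0, 1]`.
#' @param objective Cost function (scalar form).
#' @return List with `position`, `cost`, `accepted` flag and `evaluated`
#'   flag (whether an objective evaluation was spent).
#' @export
crossover_accept <- function(worst_position, worst_cost, exchange, cg,
                             objective) {
  if (cg <= 0) {
    return(list(position = worst_position, cost = worst_cost,
                accepted = FALSE, evaluated = FALSE))
  }
  mask <- runif(length(worst_position)) < cg
  trial <- ifelse(mask, exchange, worst_position)
  if (!any(mask)) {
    return(list(position = worst_position, cost = worst_cost,
                accepted = FALSE, evaluated = FALSE))
  }
  cost <- eval_batch(objective, matrix(trial, nrow = 1))
  if (cost < worst_cost) {
    list(position = trial, cost = cost, accepted = TRUE, evaluated = TRUE)
  } else {
    list(position = worst_position, cost = worst_cost,
         accepted = FALSE, evaluated = TRUE)
  }
}

#' Self-adaptive population resize
#'
#' Draws `rnd ~ U[-0.5, 0.5]` and sets the new size to
#' `round(PS + rnd * PS)`. Growth appends fresh uniform candidates
#' (evaluated immediately); shrinkage keeps the lowest-cost members. The
#' size never falls below the problem dimension `d`.
#'
#' @param state Optimizer state.
#' @param d Problem dimension.
#' @param objective Cost function (needed when the population grows).
#' @param rnd Optional override of the random draw (used in tests).
#' @param max_new Cap on how many fresh candidates may be appended (the
#'   run loop passes its remaining evaluation budget).
#' @return The resized state.
#' @export
adapt_population_size <- function(state, d, objective = NULL, rnd = NULL,
                                  max_new = Inf) {
  ps <- length(state$costs)
  if (is.null(rnd)) rnd <- runif(1, -0.5, 0.5)
  ps_new <- round(ps + rnd * ps)
  if (ps_new < d) ps_new <- as.integer(d)
  ps_new <- max(ps_new, 2L)
  if (ps_new > ps) ps_new <- ps + min(ps_new - ps, max_new)
  if (ps_new == ps) return(state)
  if (ps_new < ps) {
    keep <- order(state$costs)[seq_len(ps_new)]
    state$positions <- state$positions[keep, , drop = FALSE]
    state$costs <- state$costs[keep]
  } else {
    extra <- ps_new - ps
    theta <- matrix(runif(extra * ncol(state$positions)), extra,
                    ncol(state$positions))
    fresh <- sweep(sweep(theta, 2, state$upper - state$lower, `*`),
                   2, state$lower, `+`)
    if (is.null(objective))
      stop("`objective` is required when the population grows", call. = FALSE)
    fc <- eval_batch(objective, fresh)
    state$positions <- rbind(state$positions, fresh)
    state$costs <- c(state$costs, fc)
    state$fe_count <- state$fe_count + extra
    ib <- which.min(fc)
    if (fc[ib] < state$best$cost)
      state$best <- list(position = fresh[ib, ], cost = fc[ib])
  }
  state
}

# merge the thermal memory into the population: elites replace an equal
# number of worst members (no evaluations spent)
tm_merge <- function(state) {
  k <- if (is.null(state$tm_costs)) 0L else length(state$tm_costs)
  if (k == 0) return(state)
  n <- length(state$costs)
  worst <- order(state$costs, decreasing = TRUE)[seq_len(min(k, n))]
  state$positions[worst, ] <- state$tm_positions[seq_along(worst), , drop = FALSE]
  state$costs[worst] <- state$tm_costs[seq_along(worst)]
  state
}

# refresh the thermal memory with the current population's elites
tm_update <- function(state, tm_size) {
  pos <- rbind(state$tm_positions, state$positions)
  cst <- c(state$tm_costs, state$costs)
  keep <- order(cst)[seq_len(min(tm_size, length(cst)))]
  state$tm_positions <- pos[keep, , drop = FALSE]
  state$tm_costs <- cst[keep]
  state
}

#' Run the thermal-exchange optimizer
#'
#' `run_ateo()` runs the Advanced variant: the base cooling updates plus
#' thermal-memory elitism, a best-guided exchange vector replacing the
#' worst member, and a self-adaptive population size. `run_teo()` runs the
#' plain algorithm (no exchange step, fixed population size); it is the
#' advanced code path with those extensions switched off, so the two agree
#' bitwise under a shared seed when the extensions are disabled.
#'
#' Each iteration: sort, inject thermal memory, pair cooling/environment
#' objects, damp the environment temperatures, relax every candidate toward
#' its environment (Newton cooling with per-candidate cooling factor),
#' randomly perturb single components, evaluate, then (advanced only)
#' exchange-and-crossover the worst member and resize the population. The
#' run stops when the evaluation budget is exhausted or the best cost
#' reaches the error floor.
#'
#' @param objective Cost function: length-`d` vector to finite scalar, or a
#'   batched form with `attr(, "vectorized") = TRUE`.
#' @param d Problem dimension.
#' @param config A [teo_config()].
#' @param advanced Run the advanced extensions? (`run_teo()` sets `FALSE`.)
#' @return An object of class `ateo_fit`: list with `best_position`,
#'   `best_cost`, `fe_count`, `iterations`, `history` (tibble with columns
#'   `iteration`, `fe_count`, `best_cost`, `ps`), `d`, `advanced`, `config`.
#'   The `best_cost` column of `history` is monotone non-increasing.
#' @export
#' @examples
#' fit <- run_ateo(function(x) sum(x^2), d = 2,
#'                 teo_config(lower = -5, upper = 5, max_fes = 3000, seed = 1))
#' fit$best_cost
run_ateo <- function(objective, d, config, advanced = TRUE) {
  stopifnot(inherits(config, "teo_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  state <- init_population(objective, d, config)
  ps0 <- length(state$costs)
  tm_size <- if (is.null(config$tm_size)) ceiling(ps0 / 10) else config$tm_size
  tm_size <- max(1L, min(tm_size, ps0 - 1L))
  state <- tm_update(state, tm_size)

  do_resize <- advanced && isTRUE(config$adapt_population)
  per_iter <- function(ps) ps + as.integer(advanced && config$cg > 0)
  est_total_iter <- function(iter, ps) {
    iter + max(1, ceiling((config$max_fes - state$fe_count) / per_iter(ps)))
  }

  hist_it <- integer(0); hist_fe <- integer(0)
  hist_bc <- numeric(0); hist_ps <- integer(0)
  record <- function(state) {
    hist_it[length(hist_it) + 1L] <<- state$iteration
    hist_fe[length(hist_fe) + 1L] <<- state$fe_count
    hist_bc[length(hist_bc) + 1L] <<- state$best$cost
    hist_ps[length(hist_ps) + 1L] <<- length(state$costs)
  }
  record(state)

  while (state$fe_count + length(state$costs) <= config$max_fes &&
         state$best$cost > config$error_floor) {
    state$iteration <- state$iteration + 1L
    max_iter <- est_total_iter(state$iteration, length(state$costs))
    t <- min(1, state$iteration / max_iter)

    state <- tm_merge(state)
    pr <- pair_objects(state, quiet = TRUE)
    state <- pr$state
    env_idx <- pr$pairs$environment
    n <- length(state$costs)

    worst_cost <- max(state$costs)
    zeta <- cooling_factor(state$costs, worst_cost)

    # damped environment temperatures (one random delta per candidate)
    delta <- runif(n)
    damp <- 1 - (config$alpha1 + config$alpha2 * (1 - t)) * delta
    env <- state$positions[env_idx, , drop = FALSE] * damp

    # Newton-cooling relaxation toward the environment, clamped
    decay <- exp(-zeta * t)
    newpos <- env + (state$positions - env) * decay
    newpos <- pmin(pmax(newpos, matrix(state$lower, n, d, byrow = TRUE)),
                   matrix(state$upper, n, d, byrow = TRUE))

    # single-component perturbation before evaluation
    r <- runif(n)
    hit <- which(r < config$pr)
    for (i in hit) {
      j <- if (d == 1) 1L else sample.int(d, 1L)
      dl <- runif(1)
      dmp <- if (isTRUE(config$perturbation_decay)) exp(-zeta[i] * t) else 1
      newpos[i, j] <- clamp(
        state$lower[j] + dl * (state$upper[j] - state$lower[j]) * dmp,
        state$lower[j], state$upper[j])
    }

    costs <- eval_batch(objective, newpos)
    state$positions <- newpos
    state$costs <- costs
    state$fe_count <- state$fe_count + n
    ib <- which.min(costs)
    if (costs[ib] < state$best$cost)
      state$best <- list(position = newpos[ib, ], cost = costs[ib])

    if (advanced && config$cg > 0 && n >= 3 &&
        state$fe_count < config$max_fes) {
      iw <- which.max(state$costs)
      ibb <- which.min(state$costs)
      exch <- ateo_exchange(state$positions[ibb, ], state$positions,
                            config$gamma, state$lower, state$upper)
      if (!is.null(exch)) {
        res <- crossover_accept(state$positions[iw, ], state$costs[iw],
                                exch, config$cg, objective)
        if (res$evaluated) state$fe_count <- state$fe_count + 1L
        if (res$accepted) {
          state$positions[iw, ] <- res$position
          state$costs[iw] <- res$cost
          if (res$cost < state$best$cost)
            state$best <- list(position = res$position, cost = res$cost)
        }
      }
    }

    state <- tm_update(state, tm_size)
    if (do_resize) {
      # growth appends fresh uniform candidates, so allowing the population
      # to outgrow its initial size only replays initialization sampling
      # late in the run; the size therefore wanders within [d, initial PS]
      cap <- min(config$max_fes - state$fe_count,
                 max(0L, ps0 - length(state$costs)))
      state <- adapt_population_size(state, d, objective, max_new = cap)
    }
    record(state)
  }

  structure(list(
    best_position = state$best$position,
    best_cost = state$best$cost,
    fe_count = state$fe_count,
    iterations = state$iteration,
    history = tibble::tibble(iteration = hist_it, fe_count = hist_fe,
                             best_cost = hist_bc, ps = hist_ps),
    d = d, advanced = advanced, config = config
  ), class = "ateo_fit")
}

#' @rdname run_ateo
#' @export
run_teo <- function(objective, d, config) {
  run_ateo(objective, d, config, advanced = FALSE)
}

#' @export
print.ateo_fit <- function(x, ...) {
  cat(sprintf("<ateo_fit> %s, d = %d\n",
              if (x$advanced) "advanced (ATEO)" else "plain (TEO)", x$d))
  cat(sprintf("  best cost %.6g after %d evaluations (%d iterations)\n",
              x$best_cost, x$fe_count, x$iterations))
  invisible(x)
}

#' Tidy the convergence history of an optimizer run
#'
#' @param x An `ateo_fit`.
#' @param ... Unused.
#' @return The per-iteration history tibble (`iteration`, `fe_count`,
#'   `best_cost`, `ps`).
#' @method tidy ateo_fit
#' @export
tidy.ateo_fit <- function(x, ...) x$history

#' One-row summary of an optimizer run
#'
#' @param x An `ateo_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `best_cost`, `fe_count`, `iterations`,
#'   `final_ps`, `advanced`.
#' @method glance ateo_fit
#' @export
glance.ateo_fit <- function(x, ...) {
  tibble::tibble(
    best_cost = x$best_cost, fe_count = x$fe_count,
    iterations = x$iterations,
    final_ps = utils::tail(x$history$ps, 1), advanced = x$advanced
  )
}

#' Convergence plot of an optimizer run
#'
#' @param object An `ateo_fit`.
#' @param ... Unused.
#' @return A ggplot of best cost versus evaluations (log-10 cost axis when
#'   all costs are positive).
#' @method autoplot ateo_fit
#' @export
autoplot.ateo_fit <- function(object, ...) {
  h <- object$history
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$fe_count, y = .data$best_cost)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "objective evaluations", y = "best cost",
                  title = if (object$advanced) "ATEO convergence" else "TEO convergence")
  if (all(h$best_cost > 0)) p <- p + ggplot2::scale_y_log10()
  p
}
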