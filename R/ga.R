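#' Genetic-algorithm settings
#'
#' Robust defaults for box-bounded calibration of ODE models with around
#' ten parameters: real-coded individuals, tournament selection (size 3),
#' blend (BLX-alpha) crossover, per-gene Gaussian mutation scaled to the
#' box width, and a small elite carried over unchanged.
#'
#' @param pop_size Population size (>= 4).
#' @param generations Maximum number of generations.
#' @param tournament Tournament size for selection.
#' @param crossover_rate Probability a pair is crossed (BLX-alpha).
#' @param blx_alpha Blend-crossover expansion factor.
#' @param mutation_rate Per-gene mutation probability.
#' @param mutation_sd Gaussian mutation SD as a fraction of the box width.
#' @param elitism Number of best individuals copied unchanged.
#' @param stall_generations Stop early after this many generations without
#'   improvement of the best cost.
#' @param seed Integer seed; identical seed and config give an identical
#'   optimization trajectory.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(pop_size = 100L, generations = 300L, tournament = 3L,
                      crossover_rate = 0.9, blx_alpha = 0.5,
                      mutation_rate = 0.2, mutation_sd = 0.05,
                      elitism = 2L, stall_generations = 50L, seed = 1L) {
  stopifnot(pop_size >= 4, generations >= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            mutation_sd > 0, elitism >= 0, elitism < pop_size)
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 tournament = as.integer(tournament),
                 crossover_rate = crossover_rate, blx_alpha = blx_alpha,
                 mutation_rate = mutation_rate, mutation_sd = mutation_sd,
                 elitism = as.integer(elitism),
                 stall_generations = as.integer(stall_generations),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Evaluate a population of candidates
#'
#' Applies the objective to each row of a candidate matrix. Evaluation is
#' side-effect-free, so candidates may be evaluated in any order (or
#' concurrently) with identical results; non-finite objective values
#' (solver failures) are mapped to `Inf` so such candidates can never be
#' selected.
#'
#' @param candidates Numeric matrix, one candidate per row.
#' @param objective Function of a numeric vector returning scalar cost.
#' @return Numeric vector of costs aligned with the rows.
#' @export
evaluate_population <- function(candidates, objective) {
  costs <- apply(candidates, 1, function(x) {
    v <- suppressWarnings(objective(x))
    if (!is.finite(v)) Inf else v
  })
  as.numeric(costs)
}

#' Minimize an objective over a box with a real-coded genetic algorithm
#'
#' Candidates outside the box are clipped to it; candidates for which the
#' objective is non-finite (e.g. the forward solver failed) receive
#' infinite cost and are rejected by selection. The best-so-far cost is
#' monotone non-increasing and the returned optimum always lies inside
#' the box.
#'
#' @param objective Function of a numeric vector returning a scalar cost
#'   (may return `Inf`/`NA` for infeasible points).
#' @param lower,upper Numeric vectors of finite box bounds (named vectors
#'   name the result).
#' @param config A [ga_config()].
#' @param init Optional matrix (or vector) of initial individuals included
#'   in the starting population.
#' @return An object of class `ga_fit`: list with `theta` (best
#'   parameters), `cost`, `history` (tibble of per-generation best cost),
#'   `n_evals`, and `n_rejected`.
#' @export
#' @examples
#' fit <- ga_optimize(function(x) sum((x - 0.3)^2), c(-1, -1), c(1, 1),
#'                    ga_config(pop_size = 20, generations = 30, seed = 1))
#' fit$theta
ga_optimize <- function(objective, lower, upper, config = ga_config(),
                        init = NULL) {
  stopifnot(length(lower) == length(upper),
            all(is.finite(lower)), all(is.finite(upper)),
            all(upper > lower))
  d <- length(lower)
  nms <- names(lower)
  width <- upper - lower
  clip <- function(x) pmin(pmax(x, lower), upper)

  with_seed(config$seed, {
    n <- config$pop_size
    pop <- matrix(stats::runif(n * d), nrow = n) *
      rep(width, each = n) + rep(lower, each = n)
    if (!is.null(init)) {
      init <- matrix(init, ncol = d)
      k <- min(nrow(init), n)
      pop[seq_len(k), ] <- t(apply(init[seq_len(k), , drop = FALSE], 1, clip))
    }
    costs <- evaluate_population(pop, objective)
    n_evals <- n
    n_rejected <- sum(!is.finite(costs))
    if (all(!is.finite(costs))) {
      # one resampling attempt before giving up
      pop <- matrix(stats::runif(n * d), nrow = n) *
        rep(width, each = n) + rep(lower, each = n)
      costs <- evaluate_population(pop, objective)
      n_evals <- n_evals + n
      n_rejected <- n_rejected + sum(!is.finite(costs))
      if (all(!is.finite(costs))) {
        stop("objective infeasible for the entire initial population; ",
             "revise the parameter bounds")
      }
    }

    history <- numeric(config$generations)
    best_cost <- min(costs)
    stall <- 0L
    gen_done <- 0L
    for (gen in seq_len(config$generations)) {
      ord <- order(costs)
      elite_idx <- ord[seq_len(config$elitism)]
      # tournament selection of parents
      select1 <- function() {
        idx <- sample.int(n, config$tournament, replace = TRUE)
        idx[which.min(costs[idx])]
      }
      n_child <- n - config$elitism
      children <- matrix(NA_real_, nrow = n_child, ncol = d)
      i <- 1L
      while (i <= n_child) {
        p1 <- pop[select1(), ]; p2 <- pop[select1(), ]
        if (stats::runif(1) < config$crossover_rate) {
          lo <- pmin(p1, p2); hi <- pmax(p1, p2)
          span <- hi - lo
          c1 <- stats::runif(d, lo - config$blx_alpha * span,
                             hi + config$blx_alpha * span)
          c2 <- stats::runif(d, lo - config$blx_alpha * span,
                             hi + config$blx_alpha * span)
        } else {
          c1 <- p1; c2 <- p2
        }
        for (child in list(c1, c2)) {
          if (i > n_child) break
          mut <- stats::runif(d) < config$mutation_rate
          child[mut] <- child[mut] +
            stats::rnorm(sum(mut), 0, config$mutation_sd * width[mut])
          children[i, ] <- clip(child)
          i <- i + 1L
        }
      }
      child_costs <- evaluate_population(children, objective)
      n_evals <- n_evals + n_child
      n_rejected <- n_rejected + sum(!is.finite(child_costs))
      pop <- rbind(pop[elite_idx, , drop = FALSE], children)
      costs <- c(costs[elite_idx], child_costs)

      new_best <- min(costs)
      if (new_best < best_cost - 1e-15) {
        best_cost <- new_best
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      history[gen] <- best_cost
      gen_done <- gen
      if (stall >= config$stall_generations) break
    }

    best <- pop[which.min(costs), ]
    if (!is.null(nms)) names(best) <- nms
    structure(list(theta = best, cost = min(costs),
                   history = tibble::tibble(
                     generation = seq_len(gen_done),
                     best_cost = history[seq_len(gen_done)]),
                   n_evals = n_evals, n_rejected = n_rejected,
                   config = config),
              class = "ga_fit")
  })
}

#' @export
print.ga_fit <- function(x, ...) {
  cat("<ga_fit> best cost", format(x$cost, digits = 6), "after",
      nrow(x$history), "generations (", x$n_evals, "evaluations,",
      x$n_rejected, "rejected )\n")
  print(round(x$theta, 6))
  invisible(x)
}

#' @export
tidy.ga_fit <- function(x, ...) {
  tibble::tibble(parameter = names(x$theta) %||% paste0("x", seq_along(x$theta)),
                 estimate = unname(x$theta))
}

#' @export
glance.ga_fit <- function(x, ...) {
  tibble::tibble(best_cost = x$cost, generations = nrow(x$history),
                 n_evals = x$n_evals, n_rejected = x$n_rejected)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
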