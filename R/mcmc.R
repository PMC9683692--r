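#' Ensemble MCMC settings
#'
#' Affine-invariant ensemble ("stretch move") sampler settings. The walker
#' count stays at 32 even for low-dimensional targets; ensemble validity
#' requires at least twice the number of free parameters.
#'
#' @param n_walkers Number of walkers (default 32).
#' @param n_steps Number of steps per walker (default 5000).
#' @param burn_in Steps discarded as dependent on the initialization
#'   (default 2500).
#' @param a Stretch-move scale parameter (default 2).
#' @param sigma_init_rel Relative SD of the Gaussian perturbation used to
#'   initialize walkers around the optimum (default 0.01).
#' @param seed Integer seed; identical seed gives bit-identical chains.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_walkers = 32L, n_steps = 5000L, burn_in = 2500L,
                        a = 2, sigma_init_rel = 0.01, seed = 1L) {
  stopifnot(n_walkers >= 2, n_steps >= 2, burn_in >= 0, burn_in < n_steps,
            a > 1, sigma_init_rel > 0)
  structure(list(n_walkers = as.integer(n_walkers),
                 n_steps = as.integer(n_steps),
                 burn_in = as.integer(burn_in), a = a,
                 sigma_init_rel = sigma_init_rel, seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Log-posterior of free parameters under a uniform box prior
#'
#' Uniform prior on the physiological box, Gaussian likelihood
#' `-0.5 * cost`: outside the box, or when the forward solver fails, the
#' log-posterior is `-Inf` (rejection).
#'
#' @param theta Named numeric vector of free-parameter values.
#' @param problem A [calibration_problem()].
#' @return Scalar log-posterior.
#' @export
log_posterior <- function(theta, problem) {
  idx <- match(names(theta), problem$parameters$name)
  stopifnot(!anyNA(idx))
  lower <- problem$parameters$min[idx]
  upper <- problem$parameters$max[idx]
  if (any(theta < lower | theta > upper)) return(-Inf)
  -0.5 * problem$cost(theta)
}

#' Initialize ensemble walkers around an optimum
#'
#' Each walker is drawn as `theta_star + eps`, with
#' `eps ~ N(0, diag(sigma_init_rel * theta_star))`, and redrawn until it
#' lies inside the box and has finite log-posterior.
#'
#' @param theta_star Named vector strictly inside the bounds.
#' @param log_post Function of a named vector returning the log-posterior.
#' @param lower,upper Box bounds aligned with `theta_star`.
#' @param config An [mcmc_config()] (uses `n_walkers`, `sigma_init_rel`).
#' @param max_tries Redraw budget per walker.
#' @return Matrix `n_walkers x n_par` with column names from `theta_star`.
#' @export
init_walkers <- function(theta_star, log_post, lower, upper,
                         config = mcmc_config(), max_tries = 100L) {
  d <- length(theta_star)
  out <- matrix(NA_real_, nrow = config$n_walkers, ncol = d,
                dimnames = list(NULL, names(theta_star)))
  sd0 <- config$sigma_init_rel * abs(theta_star)
  for (w in seq_len(config$n_walkers)) {
    ok <- FALSE
    for (k in seq_len(max_tries)) {
      cand <- theta_star + stats::rnorm(d, 0, sd0)
      if (any(cand < lower | cand > upper)) next
      names(cand) <- names(theta_star)
      if (is.finite(log_post(cand))) {
        out[w, ] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not initialize walker ", w,
                  " with finite log-posterior")
  }
  out
}

#' Run the affine-invariant ensemble sampler
#'
#' At each step every walker proposes a stretch move against a partner
#' drawn from the complementary half of the ensemble: with
#' `z ~ g(z) \eqn{\propto} 1/sqrt(z)` on `[1/a, a]`, the proposal is
#' `Y = X_partner + z (X - X_partner)`, accepted with probability
#' `min(1, z^(d-1) exp(logp(Y) - logp(X)))`, which leaves the posterior
#' invariant.
#'
#' @param log_post Function of a named parameter vector returning the
#'   log-posterior (`-Inf` allowed).
#' @param init Initial walker matrix (`n_walkers x d`), e.g. from
#'   [init_walkers()].
#' @param config An [mcmc_config()]. The RNG seed makes runs bit-identical.
#' @param progress Print a progress line every 200 steps.
#' @return An object of class `chain_set`: list with `samples` (array
#'   `n_walkers x n_steps x d`), `log_post` (matrix), `acceptance` (per
#'   walker), `burn_in`, `parameters`, and `config`.
#' @export
run_ensemble <- function(log_post, init, config = mcmc_config(),
                         progress = FALSE) {
  n <- config$n_walkers
  stopifnot(nrow(init) == n)
  d <- ncol(init)
  if (n < 2 * d) {
    warning("fewer than 2 walkers per free parameter; ensemble moves may mix poorly")
  }
  pnames <- colnames(init)

  with_seed(config$seed, {
    lp <- apply(init, 1, function(x) log_post(stats::setNames(x, pnames)))
    if (all(!is.finite(lp))) stop("all walkers start at -Inf log-posterior")

    samples <- array(NA_real_, dim = c(n, config$n_steps, d),
                     dimnames = list(NULL, NULL, pnames))
    lp_store <- matrix(NA_real_, nrow = n, ncol = config$n_steps)
    accepts <- integer(n)
    x <- init
    half <- n %/% 2
    groups <- list(seq_len(half), (half + 1):n)

    for (step in seq_len(config$n_steps)) {
      for (g in 1:2) {
        active <- groups[[g]]
        other <- groups[[3 - g]]
        partners <- other[sample.int(length(other), length(active),
                                     replace = TRUE)]
        z <- ((config$a - 1) * stats::runif(length(active)) + 1)^2 / config$a
        for (k in seq_along(active)) {
          i <- active[k]
          y <- x[partners[k], ] + z[k] * (x[i, ] - x[partners[k], ])
          lpy <- log_post(stats::setNames(y, pnames))
          logr <- (d - 1) * log(z[k]) + lpy - lp[i]
          if (is.finite(lpy) && log(stats::runif(1)) < logr) {
            x[i, ] <- y
            lp[i] <- lpy
            accepts[i] <- accepts[i] + 1L
          }
        }
      }
      samples[, step, ] <- x
      lp_store[, step] <- lp
      if (progress && step %% 200 == 0) {
        message("step ", step, "/", config$n_steps,
                " mean acceptance ", round(mean(accepts) / step, 3))
      }
    }

    structure(list(samples = samples, log_post = lp_store,
                   acceptance = accepts / config$n_steps,
                   burn_in = config$burn_in, parameters = pnames,
                   config = config),
              class = "chain_set")
  })
}

#' Flatten post-burn-in posterior samples
#'
#' @param chains A `chain_set`.
#' @return Tibble with one column per parameter plus `log_post`; rows are
#'   the `n_walkers * (n_steps - burn_in)` retained samples, step-major
#'   (walkers interleaved within each step).
#' @export
posterior_samples <- function(chains) {
  keep <- (chains$burn_in + 1):dim(chains$samples)[2]
  d <- dim(chains$samples)[3]
  cols <- lapply(seq_len(d), function(j) {
    as.numeric(chains$samples[, keep, j])
  })
  names(cols) <- chains$parameters
  cols$log_post <- as.numeric(chains$log_post[, keep])
  tibble::as_tibble(cols)
}

#' @export
print.chain_set <- function(x, ...) {
  dm <- dim(x$samples)
  cat("<chain_set>", dm[1], "walkers x", dm[2], "steps x", dm[3],
      "parameters; burn-in", x$burn_in, "\n")
  cat("  mean acceptance:", round(mean(x$acceptance), 3), "\n")
  invisible(x)
}

#' @export
tidy.chain_set <- function(x, conf_level = 0.95, ...) {
  ps <- posterior_samples(x)
  alpha <- (1 - conf_level) / 2
  purrr::map_dfr(x$parameters, function(nm) {
    v <- ps[[nm]]
    tibble::tibble(parameter = nm, mean = mean(v), sd = stats::sd(v),
                   median = stats::median(v),
                   conf_low = stats::quantile(v, alpha, names = FALSE),
                   conf_high = stats::quantile(v, 1 - alpha, names = FALSE))
  })
}

#' @export
glance.chain_set <- function(x, ...) {
  dm <- dim(x$samples)
  tibble::tibble(n_walkers = dm[1], n_steps = dm[2], n_parameters = dm[3],
                 burn_in = x$burn_in,
                 mean_acceptance = mean(x$acceptance),
                 retained_samples = dm[1] * (dm[2] - x$burn_in))
}

#' Geweke convergence diagnostic
#'
#' Compares the mean of an early segment of a chain with the mean of a
#' late segment via `Z = (m1 - m2) / sqrt(v1 + v2)`, where each segment's
#' variance of the mean is estimated from its spectral density at zero
#' frequency (autoregressive-model estimate, order chosen by AIC), so
#' autocorrelation within the chain is accounted for. Under convergence
#' `Z` is approximately standard normal.
#'
#' For a `chain_set` the post-burn-in samples of each parameter are
#' summarised per step by their ensemble mean before computing `Z`: the
#' segment means are identical to those of the flattened walker-interleaved
#' series, but the spectral variance estimate then correctly reflects the
#' between-step autocorrelation of the ensemble rather than the artificial
#' short-range structure that interleaving walkers creates.
#'
#' @param x Numeric vector (a single-parameter chain) or a `chain_set`
#'   (applied per parameter to the post-burn-in samples).
#' @param first Fraction of the series forming the early segment.
#' @param last Fraction forming the late segment.
#' @param ... Unused.
#' @return A tibble of class `geweke_result` with columns `parameter`,
#'   `z`, `p_value`, and attributes `first`, `last`, `pass`
#'   (all p-values > 0.05).
#' @export
geweke <- function(x, first = 0.1, last = 0.5, ...) UseMethod("geweke")

#' @rdname geweke
#' @export
geweke.default <- function(x, first = 0.1, last = 0.5, ...) {
  stopifnot(is.numeric(x), first > 0, last > 0, first + last <= 1)
  n <- length(x)
  if (n < 100) stop("series too short for the Geweke diagnostic")
  x1 <- x[seq_len(floor(first * n))]
  x2 <- x[(n - floor(last * n) + 1):n]
  if (stats::var(x1) == 0 || stats::var(x2) == 0) {
    stop("degenerate (zero-variance) chain segment")
  }
  v1 <- spectrum0_var(x1)
  v2 <- spectrum0_var(x2)
  z <- (mean(x1) - mean(x2)) / sqrt(v1 + v2)
  p <- 2 * stats::pnorm(-abs(z))
  out <- tibble::tibble(parameter = "x", z = z, p_value = p)
  attr(out, "first") <- first
  attr(out, "last") <- last
  attr(out, "pass") <- p > 0.05
  class(out) <- c("geweke_result", class(out))
  out
}

#' @rdname geweke
#' @export
geweke.chain_set <- function(x, first = 0.1, last = 0.5, ...) {
  keep <- (x$burn_in + 1):dim(x$samples)[2]
  rows <- purrr::map_dfr(seq_along(x$parameters), function(j) {
    ensemble_mean <- colMeans(x$samples[, keep, j, drop = FALSE][, , 1])
    g <- geweke.default(ensemble_mean, first = first, last = last)
    g$parameter <- x$parameters[j]
    tibble::as_tibble(g)
  })
  attr(rows, "first") <- first
  attr(rows, "last") <- last
  attr(rows, "pass") <- all(rows$p_value > 0.05)
  class(rows) <- c("geweke_result", class(rows))
  rows
}

# variance of the sample mean from the spectral density at frequency zero,
# estimated from an AR model with AIC-selected order
spectrum0_var <- function(x) {
  fit <- try(stats::ar(x, aic = TRUE,
                       order.max = min(20L, length(x) - 1L)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(stats::var(x) / length(x))
  }
  s0 <- fit$var.pred / (1 - sum(fit$ar))^2
  max(s0, .Machine$double.eps) / length(x)
}
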