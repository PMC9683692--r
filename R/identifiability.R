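#' Settings for the structural-identifiability reduction
#'
#' @param t_i Parameter-importance threshold: parameters with importance
#'   `delta < t_i` are candidates for fixing. Default 0.1.
#' @param t_c Collinearity threshold: parameter pairs with collinearity
#'   `gamma > t_c` are candidates for fixing (the lower-importance member).
#'   Default 10, within the 5-20 range where the collinearity index is
#'   generally considered critical.
#' @param t_u Optional prediction-uncertainty threshold; reported against
#'   the final credible-interval half-width but never gates the reduction.
#' @param fd_rel_step Relative finite-difference step for the sensitivity
#'   matrix. Default `1e-3`, balancing truncation error against solver
#'   noise.
#' @param max_iterations Cap on reduction iterations.
#' @return A list of class `reduction_config`.
#' @export
reduction_config <- function(t_i = 0.1, t_c = 10, t_u = NULL,
                             fd_rel_step = 1e-3, max_iterations = 12L) {
  stopifnot(t_i >= 0, t_c > 1, fd_rel_step > 0, max_iterations >= 1)
  structure(list(t_i = t_i, t_c = t_c, t_u = t_u,
                 fd_rel_step = fd_rel_step,
                 max_iterations = as.integer(max_iterations)),
            class = "reduction_config")
}

#' Normalized finite-difference sensitivity matrix
#'
#' First-order forward finite differences of a vector-valued model around
#' an expansion point, normalized by the parameter value and the
#' measurement standard deviation:
#' `S[k, l] = (f_k(theta + h_l e_l) - f_k(theta)) / h_l * theta_l / sigma_k`
#' with `h_l = fd_rel_step * theta_l`.
#'
#' If the model fails at a perturbed point (returns `NULL`), the step is
#' halved and retried a few times before erroring.
#'
#' @param fn Function taking a named parameter vector and returning a named
#'   numeric vector of outputs, or `NULL` on solver failure.
#' @param theta Named numeric expansion point (all entries non-zero).
#' @param sigma Named numeric vector of output standard deviations; names
#'   define the row order of `S`.
#' @param rel_step Relative finite-difference step.
#' @return Matrix with `length(sigma)` rows and `length(theta)` columns,
#'   dimnames from `sigma` and `theta`.
#' @export
sensitivity_matrix <- function(fn, theta, sigma, rel_step = 1e-3) {
  stopifnot(!is.null(names(theta)), !is.null(names(sigma)),
            all(is.finite(theta)), all(sigma > 0))
  if (any(theta == 0)) {
    stop("relative normalization undefined for zero-valued parameter(s): ",
         paste(names(theta)[theta == 0], collapse = ", "))
  }
  f0 <- fn(theta)
  if (is.null(f0)) stop("model failed at the expansion point")
  f0 <- f0[names(sigma)]
  if (any(is.na(f0))) stop("model outputs missing for some sigma names")

  S <- matrix(NA_real_, nrow = length(sigma), ncol = length(theta),
              dimnames = list(names(sigma), names(theta)))
  for (l in seq_along(theta)) {
    h <- rel_step * theta[[l]]
    f1 <- NULL
    for (attempt in 1:4) {
      th <- theta
      th[[l]] <- th[[l]] + h
      f1 <- fn(th)
      if (!is.null(f1)) break
      h <- h / 2
    }
    if (is.null(f1)) {
      stop("model failed at perturbations of parameter ", names(theta)[l])
    }
    S[, l] <- (f1[names(sigma)] - f0) / h * theta[[l]] / sigma
  }
  S
}

#' Parameter importance
#'
#' Root-mean-square of each parameter's normalized sensitivity column over
#' all outputs: `delta_l = sqrt(mean(S[, l]^2))`. A large importance means
#' the parameter influences the (noise-scaled) outputs strongly.
#'
#' @param S Sensitivity matrix from [sensitivity_matrix()].
#' @return Named non-negative vector, one entry per column of `S`.
#' @export
parameter_importance <- function(S) {
  stopifnot(is.matrix(S), all(is.finite(S)))
  sqrt(colMeans(S^2))
}

#' Pairwise collinearity index
#'
#' Columns of `S` are normalized to unit Euclidean norm
#' (`S_tilde[, l] = S[, l] / (delta_l sqrt(n_z))`), the 2x2 Gram matrix
#' `N = t(Shat) %*% Shat` of columns `i`, `j` is formed, and the
#' collinearity is `gamma_ij = 1 / sqrt(min eigenvalue of N)`. Orthogonal
#' sensitivity columns give `gamma = 1`; proportional columns give
#' `gamma = Inf` (two parameters that compensate each other exactly).
#'
#' @param S Sensitivity matrix.
#' @param i,j Column indices or names.
#' @param cap Large sentinel replacing an infinite index in reports.
#' @return Scalar collinearity index `>= 1`.
#' @export
collinearity <- function(S, i, j, cap = 1e12) {
  delta <- parameter_importance(S)
  di <- delta[[i]]; dj <- delta[[j]]
  if (di == 0 || dj == 0) {
    return(NA_real_)  # handled by the importance rule instead
  }
  n_z <- nrow(S)
  shat <- cbind(S[, i] / (di * sqrt(n_z)), S[, j] / (dj * sqrt(n_z)))
  N <- crossprod(shat)
  mu <- min(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  if (mu <= 0) return(cap)
  min(1 / sqrt(mu), cap)
}

#' Full collinearity matrix
#'
#' @inheritParams collinearity
#' @return Symmetric matrix of pairwise collinearity indices with unit
#'   diagonal; entries are `NA` where a column has zero importance.
#' @export
collinearity_matrix <- function(S, cap = 1e12) {
  n <- ncol(S)
  G <- diag(1, n)
  dimnames(G) <- list(colnames(S), colnames(S))
  if (n < 2) return(G)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      G[i, j] <- G[j, i] <- collinearity(S, i, j, cap = cap)
    }
  }
  G
}

#' Iterative structural-identifiability reduction
#'
#' Implements the fit-analyse-fix loop: (a) fit the current free parameters
#' with the supplied optimizer; (b) compute the sensitivity matrix at the
#' optimum, parameter importances `delta`, and pairwise collinearities
#' `gamma`, plus their analogues `delta_p`, `gamma_p` with respect to the
#' core predictions; (c) fix the single worst offender - the
#' lower-importance member of the highest-collinearity pair above `t_c`,
#' or else the least important parameter below `t_i` - at its nominal
#' (approximate physiological) value; repeat until no parameter violates
#' the thresholds or `max_iterations` is reached.
#'
#' Before fixing, a candidate must pass the prediction-safety check: it is
#' fixed only if it barely influences the core predictions
#' (`delta_p < t_i`) or is prediction-collinear (`gamma_p >= t_c`) with a
#' parameter that stays free, so that fixing it does not artificially
#' shrink the prediction uncertainty. Candidates failing the check are
#' retained and the next candidate is considered.
#'
#' @param problem A [calibration_problem()].
#' @param config A [reduction_config()].
#' @param ga_config Settings for the genetic-algorithm refits.
#' @param seed Integer seed controlling the optimizer.
#' @param verbose Print per-iteration decisions.
#' @param fit_problem Optional faster variant of `problem` (e.g. relaxed
#'   solver settings) used only for the genetic-algorithm refits; the
#'   sensitivity analysis always uses `problem`.
#' @return A `reduction_report`: list with `iterations` (per-iteration
#'   delta/gamma/decision records), `free` and `fixed` parameter names,
#'   `fixed_values`, `theta_star` (fit over the final free set),
#'   `converged`, and `flag` (`"unsafe-candidates"` when parameters
#'   violating thresholds had to be retained for prediction safety).
#' @export
reduce_parameters <- function(problem, config = reduction_config(),
                              ga_config = cvscalib::ga_config(),
                              seed = 1L, verbose = FALSE,
                              fit_problem = NULL) {
  reduce_parameters_impl(problem, config, ga_config, seed, verbose,
                         fit_problem %||% problem)
}

reduce_parameters_impl <- function(problem, config, ga_config,
                                   seed = 1L, verbose = FALSE,
                                   fit_problem = problem) {
  free <- problem$parameters$name[problem$parameters$status == "free"]
  if (length(free) < 2) stop("need at least 2 free parameters to reduce")
  nominal <- stats::setNames(problem$parameters$value,
                             problem$parameters$name)
  fixed <- character()
  iterations <- list()
  theta_star <- NULL
  converged <- FALSE
  flag <- NA_character_

  for (iter in seq_len(config$max_iterations)) {
    fit <- fit_free_parameters(fit_problem, free, ga_config,
                               seed = seed + iter)
    theta_star <- fit$theta

    sens <- problem_sensitivities(problem, theta_star, config)
    delta <- sens$delta
    gamma <- sens$gamma

    cand <- reduction_candidates(delta, gamma, config)
    if (nrow(cand) == 0) {
      converged <- TRUE
      iterations[[iter]] <- iteration_record(iter, theta_star, fit$cost,
                                             delta, gamma, sens,
                                             fixed_name = NA_character_,
                                             reason = NA_character_,
                                             safety = NULL)
      break
    }

    pick <- NULL
    safety <- list()
    for (k in seq_len(nrow(cand))) {
      ok <- prediction_safe(cand$name[k], free, sens, config)
      safety[[cand$name[k]]] <- ok
      if (ok) { pick <- cand[k, ]; break }
    }

    iterations[[iter]] <- iteration_record(
      iter, theta_star, fit$cost, delta, gamma, sens,
      fixed_name = if (is.null(pick)) NA_character_ else pick$name,
      reason = if (is.null(pick)) NA_character_ else pick$reason,
      safety = safety)

    if (is.null(pick)) {
      # thresholds are violated but nothing can be fixed safely
      flag <- "unsafe-candidates"
      converged <- TRUE
      break
    }
    if (verbose) {
      message(sprintf("iteration %d: fixing %s (%s)", iter, pick$name,
                      pick$reason))
    }
    fixed <- c(fixed, pick$name)
    free <- setdiff(free, pick$name)
    if (length(free) == 0) stop("reduction eliminated all parameters")
    if (length(free) == 1) {
      # a single remaining parameter has no collinearity partner left;
      # further reduction would eliminate the model
      converged <- TRUE
      break
    }
  }
  if (!converged && length(iterations) == config$max_iterations) {
    flag <- "max-iterations"
  }

  structure(list(iterations = iterations, free = free, fixed = fixed,
                 fixed_values = nominal[fixed], theta_star = theta_star,
                 converged = converged, flag = flag, config = config),
            class = "reduction_report")
}

reduction_candidates <- function(delta, gamma, config) {
  cand <- tibble::tibble(name = character(), reason = character(),
                         score = numeric())
  nm <- names(delta)
  # collinear pairs above t_c, worst first; candidate = lower importance,
  # ties broken toward the name sorting later (deterministic)
  if (length(nm) >= 2) {
    pairs <- which(upper.tri(gamma) & !is.na(gamma) & gamma > config$t_c,
                   arr.ind = TRUE)
    if (nrow(pairs) > 0) {
      ord <- order(gamma[pairs], decreasing = TRUE)
      primary <- fallback <- cand
      for (r in ord) {
        i <- nm[pairs[r, 1]]; j <- nm[pairs[r, 2]]
        # preferred victim: the lower-importance member (ties broken
        # toward the later-sorting name); the partner remains a fallback
        # candidate in case the prediction-safety check vetoes the first
        pick <- if (delta[[i]] < delta[[j]]) i
                else if (delta[[j]] < delta[[i]]) j
                else sort(c(i, j))[2]
        other <- setdiff(c(i, j), pick)
        g <- gamma[pairs[r, 1], pairs[r, 2]]
        primary <- dplyr::bind_rows(primary, tibble::tibble(
          name = pick, reason = paste0("collinear-with:", other),
          score = g))
        fallback <- dplyr::bind_rows(fallback, tibble::tibble(
          name = other, reason = paste0("collinear-with:", pick),
          score = g))
      }
      cand <- dplyr::bind_rows(primary, fallback)
    }
  }
  low <- nm[delta < config$t_i | is.na(delta)]
  if (length(low) > 0) {
    low <- low[order(delta[low])]
    cand <- dplyr::bind_rows(cand, tibble::tibble(
      name = low, reason = "low-importance", score = delta[low]))
  }
  cand[!duplicated(cand$name), ]
}

prediction_safe <- function(name, free, sens, config) {
  if (is.null(sens$delta_p)) return(TRUE)  # no core predictions defined
  dp <- sens$delta_p[[name]]
  if (is.na(dp) || dp < config$t_i) return(TRUE)
  others <- setdiff(free, name)
  gp <- sens$gamma_p[name, others]
  any(!is.na(gp) & gp >= config$t_c)
}

problem_sensitivities <- function(problem, theta_star, config) {
  sigma <- stats::setNames(problem$data$sigma, problem$data$name)
  pred <- setdiff(problem$predictions, names(sigma))
  sigma_all <- sigma
  if (length(pred) > 0) {
    f0 <- problem$fn(theta_star)
    if (is.null(f0)) stop("model failed at the expansion point")
    # prediction sensitivities are normalized by the prediction magnitude,
    # making delta_p a dimensionless (relative) influence measure
    sigma_all <- c(sigma, stats::setNames(pmax(abs(f0[pred]), 1e-300), pred))
  }
  S_all <- sensitivity_matrix(problem$fn, theta_star, sigma_all,
                              rel_step = config$fd_rel_step)
  S <- S_all[names(sigma), , drop = FALSE]
  delta <- parameter_importance(S)
  gamma <- collinearity_matrix(S)
  delta_p <- gamma_p <- S_p <- NULL
  if (length(pred) > 0) {
    S_p <- S_all[pred, , drop = FALSE]
    delta_p <- parameter_importance(S_p)
    gamma_p <- collinearity_matrix(S_p)
  }
  list(S = S, delta = delta, gamma = gamma,
       S_p = S_p, delta_p = delta_p, gamma_p = gamma_p)
}

iteration_record <- function(iter, theta_star, cost, delta, gamma, sens,
                             fixed_name, reason, safety) {
  list(iteration = iter, theta_star = theta_star, cost = cost,
       delta = delta, gamma = gamma,
       delta_p = sens$delta_p, gamma_p = sens$gamma_p,
       fixed = fixed_name, reason = reason, safety = safety)
}

#' @export
print.reduction_report <- function(x, ...) {
  cat("<reduction_report>", length(x$free), "free /", length(x$fixed),
      "fixed parameters after", length(x$iterations), "iteration(s)\n")
  for (it in x$iterations) {
    if (!is.na(it$fixed)) {
      cat(sprintf("  iteration %d: fixed %s (%s)\n", it$iteration,
                  it$fixed, it$reason))
    }
  }
  cat("  free:", paste(x$free, collapse = ", "), "\n")
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' @export
tidy.reduction_report <- function(x, ...) {
  purrr::map_dfr(x$iterations, function(it) {
    tibble::tibble(
      iteration = it$iteration,
      parameter = names(it$delta),
      delta = unname(it$delta),
      delta_p = if (is.null(it$delta_p)) NA_real_ else
        unname(it$delta_p[names(it$delta)]),
      max_gamma = vapply(names(it$delta), function(nm) {
        g <- it$gamma[nm, setdiff(names(it$delta), nm)]
        if (length(g) == 0 || all(is.na(g))) NA_real_ else max(g, na.rm = TRUE)
      }, numeric(1)),
      fixed = !is.na(it$fixed) & names(it$delta) == it$fixed,
      reason = ifelse(!is.na(it$fixed) & names(it$delta) == it$fixed,
                      it$reason, NA_character_)
    )
  })
}

#' @export
glance.reduction_report <- function(x, ...) {
  tibble::tibble(
    n_free = length(x$free),
    n_fixed = length(x$fixed),
    n_iterations = length(x$iterations),
    converged = x$converged,
    flag = x$flag,
    final_cost = x$iterations[[length(x$iterations)]]$cost
  )
}

#' Serialize a reduction report to JSON
#'
#' @param x A `reduction_report`.
#' @param path Output path.
#' @export
write_reduction_json <- function(x, path) {
  obj <- list(
    free = x$free, fixed = x$fixed,
    fixed_values = as.list(x$fixed_values),
    converged = x$converged, flag = x$flag,
    iterations = lapply(x$iterations, function(it) {
      list(iteration = it$iteration,
           cost = it$cost,
           theta_star = as.list(it$theta_star),
           delta = as.list(it$delta),
           gamma = as.data.frame(it$gamma),
           delta_p = if (is.null(it$delta_p)) NULL else as.list(it$delta_p),
           fixed = it$fixed, reason = it$reason)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
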