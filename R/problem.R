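#' Define a calibration problem
#'
#' A calibration problem bundles a forward model, a parameter table with
#' bounds and free/fixed status, a measurement set, and the names of the
#' core-prediction outputs. The reduction loop, genetic algorithm, MCMC
#' sampler, and prediction module all operate on this object.
#'
#' `fn` receives a *named* vector holding values for any subset of table
#' parameters (the remaining ones are taken at their table values) and
#' must return a named numeric vector covering at least the measurement
#' names plus the prediction names - or `NULL` when the forward solver
#' fails, which callers treat as rejection.
#'
#' @param fn Forward model function (see Details).
#' @param parameters Parameter table with columns `name`, `value`, `min`,
#'   `max`, `status`.
#' @param data A [measurement_set()].
#' @param predictions Character vector naming the core-prediction outputs
#'   of `fn` (may be empty; then no prediction-safety check is applied).
#' @param simulate_fn Optional richer simulator returning a full
#'   `cvs_outputs` object (used for waveform-level prediction sampling).
#' @return A list of class `calibration_problem`.
#' @export
calibration_problem <- function(fn, parameters, data,
                                predictions = character(),
                                simulate_fn = NULL) {
  stopifnot(is.function(fn), is.data.frame(parameters))
  need <- c("name", "value", "min", "max", "status")
  stopifnot(all(need %in% names(parameters)))
  missing_names <- setdiff(data$name, c(parameters$name, data$name))
  prob <- list(fn = fn, parameters = parameters, data = data,
               predictions = predictions, simulate_fn = simulate_fn)
  class(prob) <- "calibration_problem"
  prob$cost <- function(theta) {
    f <- fn(theta)
    if (is.null(f)) return(Inf)
    sum(((f[data$name] - data$value) / data$sigma)^2)
  }
  prob
}

#' Calibration problem for the packaged cardiovascular model
#'
#' Builds a [calibration_problem()] whose forward model merges the given
#' free-parameter values into the parameter table, simulates the
#' cardiovascular model to a periodic state (warm-started from the fixed
#' nominal steady state, so evaluations stay independent of each other),
#' and returns the 15 measurement observables together with the three
#' middle cerebral pressure summaries as core predictions.
#'
#' @param data A [measurement_set()] (e.g. from [generate_patient()]).
#' @param parameters Parameter table; defaults to [cvs_parameters()].
#' @param config Simulation settings for objective evaluations.
#' @param anchor Optional named parameter vector at which the fixed
#'   warm-start reference state is computed (default: the table values).
#'   Anchoring near the expected optimum shortens every evaluation's
#'   transient without affecting the converged periodic solution.
#' @return A `calibration_problem`.
#' @export
cvs_problem <- function(data, parameters = cvs_parameters(),
                        config = cvs_sim_config(), anchor = NULL) {
  validate_parameter_table(parameters)
  bad <- setdiff(data$name, cvs_observables())
  if (length(bad) > 0) {
    stop("measurement name(s) not simulated by the model: ",
         paste(bad, collapse = ", "))
  }
  anchor_tab <- if (is.null(anchor)) parameters else
    set_parameters(parameters, anchor)
  ref <- simulate_cvs(anchor_tab, config)
  if (!ref$solver_ok) stop("model failed at the anchor parameters")
  ref_state <- ref$final_state
  v0 <- stats::setNames(anchor_tab$value, anchor_tab$name)
  q_un_ref <- c(q_RA = v0[["q_RA_un"]], q_RV = v0[["q_RV_un"]],
                q_LA = v0[["q_LA_un"]], q_LV = v0[["q_LV_un"]])

  v_base <- stats::setNames(parameters$value, parameters$name)
  un_state <- stats::setNames(numeric(length(ref_state)), names(ref_state))
  un_state[names(q_un_ref)] <- q_un_ref
  stressed_ref <- ref_state - un_state

  run <- function(theta) {
    if (!all(names(theta) %in% names(v_base))) {
      stop("unknown parameter(s): ",
           paste(setdiff(names(theta), names(v_base)), collapse = ", "))
    }
    v <- v_base
    v[names(theta)] <- theta
    # the warm-start state must carry the candidate's stressed blood
    # volume: rescale the stressed part of the reference steady state
    init <- if ("q_sbv" %in% names(theta)) {
      un_state + stressed_ref * (theta[["q_sbv"]] / v0[["q_sbv"]])
    } else {
      ref_state
    }
    out <- try(cvs_simulate_values(v, config, init = init, light = TRUE),
               silent = TRUE)
    if (inherits(out, "try-error") || !out$solver_ok) return(NULL)
    out
  }
  fn <- function(theta) {
    out <- run(theta)
    if (is.null(out)) return(NULL)
    c(out$summaries, out$core)
  }
  calibration_problem(fn, parameters, data,
                      predictions = cvs_core_predictions(),
                      simulate_fn = run)
}

# GA fit of a subset of free parameters; the others stay at table values
fit_free_parameters <- function(problem, free, ga_cfg, seed) {
  ptab <- problem$parameters
  idx <- match(free, ptab$name)
  stopifnot(!anyNA(idx))
  lower <- stats::setNames(ptab$min[idx], free)
  upper <- stats::setNames(ptab$max[idx], free)
  nominal <- stats::setNames(ptab$value[idx], free)
  obj <- function(x) {
    names(x) <- free
    problem$cost(x)
  }
  cfg <- ga_cfg
  cfg$seed <- as.integer(seed)
  ga_optimize(obj, lower, upper, cfg, init = rbind(nominal))
}
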