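#' Run the full calibration pipeline
#'
#' End-to-end automated calibration: iterative structural-identifiability
#' reduction (genetic-algorithm refits with importance/collinearity
#' analysis), ensemble MCMC over the reduced free parameter set seeded at
#' the optimum, Geweke convergence testing, and posterior-sampled
#' core-prediction uncertainty for the middle cerebral artery pressure.
#'
#' One global seed deterministically fans out to stage-specific seeds, so
#' a rerun with the same inputs and seed reproduces every artifact,
#' including bit-identical chains.
#'
#' @param data A [measurement_set()] or a `synthetic_patient`.
#' @param parameters Parameter table (defaults to [cvs_parameters()]).
#' @param seed Global integer seed.
#' @param reduction A [reduction_config()].
#' @param ga A [ga_config()] for the reduction refits and final fit.
#' @param mcmc An [mcmc_config()].
#' @param n_predictions Posterior draws for the prediction distribution.
#' @param t_u Optional prediction-uncertainty threshold (kPa half-width),
#'   reported but never enforced.
#' @param sim_config Simulation settings for the reduction stage (kept
#'   accurate because the finite-difference sensitivities divide small
#'   output differences).
#' @param fit_sim_config Slightly relaxed simulation settings for the
#'   MCMC and prediction stages, where a periodicity residual of order
#'   `1e-5` is invisible against measurement uncertainties of 1.5% and
#'   more.
#' @param out_dir Optional directory; when given, all artifacts
#'   (reduction report, chains, Geweke report, prediction distribution,
#'   manifest) are written there.
#' @param geweke_action `"warn"` (default) or `"error"` when the Geweke
#'   test fails; chains are written before an error is raised.
#' @param verbose Print stage progress.
#' @return An object of class `cvs_pipeline`: list with `problem`,
#'   `reduction`, `chains`, `geweke`, `prediction`, `report`
#'   (credible-interval half-widths), `errors` (standardized residuals at
#'   the posterior-best parameters), `theta_best`, `seeds`, `timings`.
#' @export
run_pipeline <- function(data,
                         parameters = cvs_parameters(),
                         seed = 1L,
                         reduction = reduction_config(),
                         ga = ga_config(),
                         mcmc = mcmc_config(),
                         n_predictions = 100L,
                         t_u = NULL,
                         sim_config = cvs_sim_config(),
                         fit_sim_config = cvs_sim_config(
                           rtol = 1e-6, atol = 1e-11,
                           min_cycles = 3, periodicity_tol = 1e-5),
                         out_dir = NULL,
                         geweke_action = c("warn", "error"),
                         verbose = FALSE) {
  geweke_action <- match.arg(geweke_action)
  if (inherits(data, "synthetic_patient")) data <- data$measurements
  stopifnot(inherits(data, "measurement_set"))
  if (mcmc$burn_in >= mcmc$n_steps) stop("burn_in must be below n_steps")
  seeds <- stage_seeds(seed)
  timings <- c()
  tick <- function() Sys.time()
  tock <- function(t0) as.numeric(Sys.time() - t0, units = "secs")

  say <- function(...) if (verbose) message(...)
  problem <- cvs_problem(data, parameters, sim_config)

  say("stage 1/4: structural-identifiability reduction")
  t0 <- tick()
  fast_nominal <- cvs_problem(data, parameters, fit_sim_config)
  red <- reduce_parameters(problem, reduction, ga_config = ga,
                           seed = seeds[["reduce"]], verbose = verbose,
                           fit_problem = fast_nominal)
  timings["reduce"] <- tock(t0)

  # problem for the sampling stages: eliminated parameters stay at their
  # nominal values, evaluations warm-start from the optimum's steady state
  ptab_red <- problem$parameters
  theta_star <- red$theta_star
  fit_problem <- cvs_problem(data, parameters, fit_sim_config,
                             anchor = theta_star)

  say("stage 2/4: ensemble MCMC over ", length(red$free), " parameters")
  t0 <- tick()
  idx <- match(red$free, ptab_red$name)
  lower <- stats::setNames(ptab_red$min[idx], red$free)
  upper <- stats::setNames(ptab_red$max[idx], red$free)
  lp <- function(theta) log_posterior(theta, fit_problem)
  init <- with_seed(seeds[["init"]],
                    init_walkers(theta_star, lp, lower, upper, mcmc))
  mcmc$seed <- seeds[["mcmc"]]
  chains <- run_ensemble(lp, init, mcmc, progress = verbose)
  timings["mcmc"] <- tock(t0)

  say("stage 3/4: Geweke convergence test")
  gw <- geweke(chains)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_reduction_json(red, file.path(out_dir, "reduction.json"))
    write_gamma_csv(red, file.path(out_dir, "collinearity.csv"))
    write_chains(chains, file.path(out_dir, "chains"))
    write_geweke_json(gw, file.path(out_dir, "geweke.json"))
  }
  if (!attr(gw, "pass")) {
    msg <- paste0("Geweke test failed (min p = ",
                  format(min(gw$p_value), digits = 3),
                  "); chains have been retained for inspection")
    if (geweke_action == "error") stop(msg) else warning(msg)
  }

  say("stage 4/4: core-prediction uncertainty (", n_predictions, " draws)")
  t0 <- tick()
  pred <- sample_predictions(chains, fit_problem, n = n_predictions,
                             seed = seeds[["predict"]])
  timings["predict"] <- tock(t0)
  report <- ci_halfwidth_report(pred, t_u = t_u)

  # fit quality at the posterior-best parameter vector
  ps <- posterior_samples(chains)
  best <- as.numeric(ps[which.max(ps$log_post), chains$parameters])
  names(best) <- chains$parameters
  out_best <- fit_problem$simulate_fn(best)
  errors <- standardized_errors(out_best, data)

  result <- structure(
    list(problem = problem, reduction = red, chains = chains,
         geweke = gw, prediction = pred, report = report,
         errors = errors, theta_best = best,
         seeds = seeds, timings = timings),
    class = "cvs_pipeline")

  if (!is.null(out_dir)) {
    write_prediction_json(pred, file.path(out_dir, "prediction.json"))
    write_band_csv(pred, file.path(out_dir, "prediction_band.csv"))
    manifest <- list(
      package = "cvscalib",
      version = as.character(utils::packageVersion("cvscalib")),
      r_version = R.version.string,
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      seed = seed, stage_seeds = as.list(seeds),
      free = red$free, fixed = red$fixed,
      geweke_pass = attr(gw, "pass"),
      timings = as.list(round(timings, 2)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  result
}

# deterministic fan-out of one global seed into stage seeds (all < 2^31)
stage_seeds <- function(seed) {
  stages <- c("synth", "reduce", "init", "mcmc", "predict")
  stats::setNames(
    (as.integer(seed) + 1000003L * seq_along(stages)) %% 2147483562L,
    stages)
}

#' @export
print.cvs_pipeline <- function(x, ...) {
  cat("<cvs_pipeline>\n")
  cat("  free parameters (", length(x$reduction$free), "): ",
      paste(x$reduction$free, collapse = ", "), "\n", sep = "")
  cat("  fixed: ", paste(x$reduction$fixed, collapse = ", "), "\n", sep = "")
  cat("  Geweke min p:", format(min(x$geweke$p_value), digits = 3),
      if (attr(x$geweke, "pass")) "(pass)" else "(FAIL)", "\n")
  cat("  max |standardized residual|:",
      format(max(abs(x$errors$std_error)), digits = 3), "\n")
  print(x$report)
  invisible(x)
}

#' @export
glance.cvs_pipeline <- function(x, ...) {
  tibble::tibble(
    n_free = length(x$reduction$free),
    n_fixed = length(x$reduction$fixed),
    max_abs_std_error = max(abs(x$errors$std_error)),
    geweke_min_p = min(x$geweke$p_value),
    geweke_pass = attr(x$geweke, "pass"),
    max_pmc_halfwidth_mmhg =
      x$report$halfwidth_mmhg[x$report$name == "max(p_MC)"]
  )
}

#' Persist / load an MCMC chain set
#'
#' Chains are stored as a pair of plain-text files: `<prefix>_samples.csv`
#' (columns `walker`, `step`, one per parameter, `log_post`; full
#' double precision) and `<prefix>_meta.json` (parameters, burn-in,
#' acceptance, config). `read_chains()` reconstructs the `chain_set`
#' exactly.
#'
#' @param chains A `chain_set`.
#' @param prefix Path prefix for the two files.
#' @export
write_chains <- function(chains, prefix) {
  dm <- dim(chains$samples)
  grid <- expand.grid(walker = seq_len(dm[1]), step = seq_len(dm[2]))
  cols <- c(list(walker = grid$walker, step = grid$step),
            stats::setNames(lapply(seq_len(dm[3]), function(j) {
              sprintf("%.17g", as.numeric(chains$samples[, , j]))
            }), chains$parameters),
            list(log_post = sprintf("%.17g", as.numeric(chains$log_post))))
  df <- as.data.frame(cols, check.names = FALSE)
  utils::write.csv(df, paste0(prefix, "_samples.csv"), row.names = FALSE,
                   quote = FALSE)
  meta <- list(parameters = chains$parameters, burn_in = chains$burn_in,
               acceptance = chains$acceptance,
               n_walkers = dm[1], n_steps = dm[2],
               config = unclass(chains$config))
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' @rdname write_chains
#' @export
read_chains <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  df <- utils::read.csv(paste0(prefix, "_samples.csv"), check.names = FALSE)
  nw <- meta$n_walkers; ns <- meta$n_steps
  pnames <- meta$parameters
  samples <- array(NA_real_, dim = c(nw, ns, length(pnames)),
                   dimnames = list(NULL, NULL, pnames))
  for (j in seq_along(pnames)) {
    samples[, , j] <- matrix(df[[pnames[j]]], nrow = nw)
  }
  lp <- matrix(df$log_post, nrow = nw)
  cfg <- do.call(mcmc_config, meta$config[setdiff(names(meta$config),
                                                  character(0))])
  structure(list(samples = samples, log_post = lp,
                 acceptance = meta$acceptance, burn_in = meta$burn_in,
                 parameters = pnames, config = cfg),
            class = "chain_set")
}

#' Write the Geweke report as JSON
#' @param gw A `geweke_result`.
#' @param path Output path.
#' @export
write_geweke_json <- function(gw, path) {
  obj <- list(first = attr(gw, "first"), last = attr(gw, "last"),
              pass = attr(gw, "pass"),
              parameters = lapply(seq_len(nrow(gw)), function(i) {
                list(parameter = gw$parameter[i], z = gw$z[i],
                     p_value = gw$p_value[i])
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write the final collinearity matrix as a long-format CSV
#'
#' One row per parameter pair with the collinearity index of the last
#' reduction iteration - ready for a heatmap.
#'
#' @param report A `reduction_report`.
#' @param path Output path.
#' @export
write_gamma_csv <- function(report, path) {
  it <- report$iterations[[length(report$iterations)]]
  g <- it$gamma
  df <- expand.grid(parameter_i = rownames(g), parameter_j = colnames(g),
                    stringsAsFactors = FALSE)
  df$gamma <- as.numeric(g)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
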