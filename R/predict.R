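#' Posterior-sampled core-prediction distribution
#'
#' Draws parameter vectors from the flattened post-burn-in posterior
#' samples (uniformly, without replacement), reruns the forward model for
#' each draw, and collects the middle cerebral artery pressure waveform
#' and its scalar summaries. Waveforms are aligned at cycle start before
#' pointwise statistics. Draws whose forward solve fails are replaced by
#' fresh draws (counted); if more than half of all attempted draws fail
#' the posterior is concentrated on a failure region and an error is
#' raised.
#'
#' @param chains A `chain_set` over the free parameters.
#' @param problem The [calibration_problem()] the chains were sampled
#'   from; must carry a `simulate_fn` returning waveform-level output.
#' @param n Number of posterior draws (default 100).
#' @param seed Integer seed for the draws.
#' @return An object of class `prediction_distribution`: list with
#'   `summaries` (tibble of per-sample `max(p_MC)`, `min(p_MC)`,
#'   `mean(p_MC)` in kPa), `band` (tibble of pointwise time, mean, sd,
#'   2.5/97.5 percentiles of the waveform), `waveforms` (matrix, one row
#'   per sample), `time`, `n`, and `n_failed`.
#' @export
sample_predictions <- function(chains, problem, n = 100L, seed = 1L) {
  stopifnot(inherits(chains, "chain_set"))
  if (is.null(problem$simulate_fn)) {
    stop("problem has no simulate_fn for waveform predictions")
  }
  ps <- posterior_samples(chains)
  pool <- as.matrix(ps[, chains$parameters, drop = FALSE])
  if (nrow(pool) < 1) stop("no post-burn-in samples available")
  n <- min(as.integer(n), nrow(pool))

  with_seed(seed, {
    order_all <- sample.int(nrow(pool))  # draw without replacement
    waves <- NULL
    time <- NULL
    summ <- vector("list", n)
    got <- 0L
    tried <- 0L
    failed <- 0L
    for (idx in order_all) {
      if (got >= n) break
      tried <- tried + 1L
      theta <- stats::setNames(pool[idx, ], chains$parameters)
      out <- problem$simulate_fn(theta)
      if (is.null(out) || !out$solver_ok) {
        failed <- failed + 1L
        if (tried >= 10 && failed / tried > 0.5) {
          stop("more than half of the posterior draws fail the forward ",
               "solve; posterior concentrated on a failure region")
        }
        next
      }
      got <- got + 1L
      if (is.null(waves)) {
        time <- out$waveforms$time
        waves <- matrix(NA_real_, nrow = n, ncol = length(time))
      }
      waves[got, ] <- out$waveforms$p_MC
      summ[[got]] <- out$core
    }
    if (got < n) stop("could only simulate ", got, " of ", n, " draws")

    summaries <- tibble::as_tibble(do.call(rbind, summ))
    band <- tibble::tibble(
      time = time,
      mean = colMeans(waves),
      sd = apply(waves, 2, stats::sd),
      lower = apply(waves, 2, stats::quantile, probs = 0.025, names = FALSE),
      median = apply(waves, 2, stats::median),
      upper = apply(waves, 2, stats::quantile, probs = 0.975, names = FALSE)
    )
    structure(list(summaries = summaries, band = band, waveforms = waves,
                   time = time, n = n, n_failed = failed, seed = seed),
              class = "prediction_distribution")
  })
}

#' Equal-tailed empirical percentile interval
#'
#' Median and the equal-tailed `level` percentile interval of a sample,
#' using the default quantile interpolation (type 7).
#'
#' @param samples Numeric vector (>= 2 values).
#' @param level Interval level in (0, 1); default 0.95.
#' @return Named numeric vector `c(median, lower, upper)`.
#' @export
#' @examples
#' summarize_ci(1:100)  # 2.5th/97.5th percentiles: 3.475, 97.525
summarize_ci <- function(samples, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  stopifnot(length(samples) >= 2)
  alpha <- (1 - level) / 2
  c(median = stats::median(samples),
    lower = stats::quantile(samples, alpha, names = FALSE),
    upper = stats::quantile(samples, 1 - alpha, names = FALSE))
}

#' Credible-interval half-width report for the core predictions
#'
#' Reports the median, the 95% interval, and its half-width
#' `(upper - lower) / 2` for each core-prediction summary, in kPa and
#' mmHg. If a prediction-uncertainty threshold `t_u` is supplied the
#' report includes a pass flag, but nothing is aborted: judging whether
#' the uncertainty is acceptable is left to the user.
#'
#' @param dist A `prediction_distribution`.
#' @param t_u Optional half-width threshold in kPa.
#' @param level Interval level.
#' @return Tibble with one row per summary: `name`, `median_kpa`,
#'   `lower_kpa`, `upper_kpa`, `halfwidth_kpa`, `halfwidth_mmhg`, and
#'   `pass` (if `t_u` given).
#' @export
ci_halfwidth_report <- function(dist, t_u = NULL, level = 0.95) {
  stopifnot(inherits(dist, "prediction_distribution"))
  rows <- purrr::map_dfr(names(dist$summaries), function(nm) {
    ci <- summarize_ci(dist$summaries[[nm]], level)
    hw <- (ci[["upper"]] - ci[["lower"]]) / 2
    tibble::tibble(name = nm,
                   median_kpa = ci[["median"]],
                   lower_kpa = ci[["lower"]],
                   upper_kpa = ci[["upper"]],
                   halfwidth_kpa = hw,
                   halfwidth_mmhg = kpa_to_mmhg(hw))
  })
  if (!is.null(t_u)) rows$pass <- rows$halfwidth_kpa <= t_u
  rows
}

#' Convert between kPa and mmHg
#'
#' Uses 1 mmHg = 0.133322 kPa.
#'
#' @param x Pressure value(s).
#' @return Converted value(s).
#' @export
kpa_to_mmhg <- function(x) x / 0.133322

#' @rdname kpa_to_mmhg
#' @export
mmhg_to_kpa <- function(x) x * 0.133322

#' @export
print.prediction_distribution <- function(x, ...) {
  cat("<prediction_distribution>", x$n, "posterior draws (",
      x$n_failed, "failed and redrawn )\n")
  print(ci_halfwidth_report(x))
  invisible(x)
}

#' @export
tidy.prediction_distribution <- function(x, ...) {
  ci_halfwidth_report(x)
}

#' @export
glance.prediction_distribution <- function(x, ...) {
  tibble::tibble(n = x$n, n_failed = x$n_failed,
                 max_halfwidth_kpa = max(ci_halfwidth_report(x)$halfwidth_kpa))
}

#' Write prediction artifacts
#'
#' `write_prediction_json()` stores per-summary median and interval (kPa
#' primary, mmHg derived); `write_band_csv()` stores the pointwise
#' waveform band.
#'
#' @param dist A `prediction_distribution`.
#' @param path Output path.
#' @export
write_prediction_json <- function(dist, path) {
  rep <- ci_halfwidth_report(dist)
  obj <- lapply(seq_len(nrow(rep)), function(i) {
    list(median = rep$median_kpa[i], ci_lower = rep$lower_kpa[i],
         ci_upper = rep$upper_kpa[i], halfwidth = rep$halfwidth_kpa[i],
         units = "kPa",
         median_mmhg = kpa_to_mmhg(rep$median_kpa[i]),
         halfwidth_mmhg = rep$halfwidth_mmhg[i])
  })
  names(obj) <- rep$name
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_prediction_json
#' @export
write_band_csv <- function(dist, path) {
  utils::write.csv(dist$band, path, row.names = FALSE)
  invisible(path)
}
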