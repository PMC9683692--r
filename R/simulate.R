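#' Solver and output settings for the forward simulation
#'
#' @param rtol,atol Relative/absolute integrator tolerances (lsoda).
#' @param max_cycles Maximum number of cardiac cycles to integrate while
#'   seeking a periodic state.
#' @param min_cycles Minimum number of cycles before the periodicity test
#'   may stop the run.
#' @param periodicity_tol Relative L-infinity change of the cycle-start
#'   state vector below which the run is considered periodic.
#' @param sample_hz Output sampling rate over the final cycle, in Hz.
#' @return A list of class `cvs_sim_config`.
#' @export
cvs_sim_config <- function(rtol = 1e-7, atol = 1e-12, max_cycles = 40,
                           min_cycles = 5, periodicity_tol = 1e-6,
                           sample_hz = 500) {
  stopifnot(rtol > 0, atol > 0, max_cycles >= 2, min_cycles >= 1,
            periodicity_tol > 0, sample_hz > 0)
  structure(list(rtol = rtol, atol = atol, max_cycles = max_cycles,
                 min_cycles = min_cycles, periodicity_tol = periodicity_tol,
                 sample_hz = sample_hz),
            class = "cvs_sim_config")
}

cvs_state_names <- function() {
  c("q_RA", "q_RV", "q_LA", "q_LV", "q_par", "q_pvn", "q_AO", "q_CER",
    paste0("q_", cvs_terminal_beds(), "_T"), "q_vub", "q_vlb")
}

#' Observable names of the packaged model
#'
#' `cvs_observables()` lists the 15 scalar observables of the measurement
#' set (atrial/ventricular volume extrema, brachial pressure summaries,
#' and mean terminal flows); `cvs_core_predictions()` lists the three core
#' prediction summaries of the middle cerebral artery pressure.
#'
#' @return Character vector of observable names, e.g. `"max(q_la)"`.
#' @export
cvs_observables <- function() {
  c("max(q_la)", "min(q_la)", "max(q_lv)", "min(q_lv)", "max(q_ra)",
    "max(p_BR)", "min(p_BR)", "mean(p_BR)",
    paste0("mean(v_", c("LE", "BR", "PC", "EC", "MC", "AC", "TR"), "_T)"))
}

#' @rdname cvs_observables
#' @export
cvs_core_predictions <- function() {
  c("max(p_MC)", "min(p_MC)", "mean(p_MC)")
}

#' Time-varying chamber elastance
#'
#' The pumping action of each heart chamber is modelled with a time-varying
#' elastance `E(t) = (E_A - E_B) e(t) + E_B`, where the activation `e(t)`
#' is a smooth periodic `sin^2` pulse in `[0, 1]` starting at `onset`
#' (fraction of the period) and lasting `duration` (fraction of the period).
#'
#' @param t Time(s) in seconds (vectorised).
#' @param E_A Maximum (active) elastance, MPa/m^3.
#' @param E_B Baseline (diastolic) elastance, MPa/m^3.
#' @param onset Activation onset as a fraction of the period.
#' @param duration Activation duration as a fraction of the period.
#' @param period Heart period in seconds.
#' @return Elastance value(s) in MPa/m^3.
#' @export
#' @examples
#' chamber_elastance(0.15, E_A = 300, E_B = 8, onset = 0, duration = 0.3)
chamber_elastance <- function(t, E_A, E_B, onset = 0, duration = 0.3,
                              period = 1) {
  if (any(t < 0)) stop("t must be non-negative")
  if (E_A < 0 || E_B < 0) stop("elastance parameters must be non-negative")
  stopifnot(duration > 0, period > 0)
  (E_A - E_B) * activation_shape(t, onset, duration, period) + E_B
}

activation_shape <- function(t, onset, duration, period) {
  w <- (t / period - onset) %% 1
  ifelse(w < duration, sin(pi * w / duration)^2, 0)
}

cvs_initial_state <- function(v) {
  if (is.data.frame(v)) v <- stats::setNames(v$value, v$name)
  comp <- c(q_RA = 1 / v[["E_RAb"]], q_RV = 1 / v[["E_RVb"]],
            q_LA = 1 / v[["E_LAb"]], q_LV = 1 / v[["E_LVb"]],
            q_par = v[["C_par"]], q_pvn = v[["C_pvn"]],
            q_AO = v[["C_AO"]], q_CER = v[["C_CER"]],
            stats::setNames(
              vapply(cvs_terminal_beds(),
                     function(b) v[[paste0("C_", b, "_T")]], numeric(1)),
              paste0("q_", cvs_terminal_beds(), "_T")),
            q_vub = v[["f_vub"]] * v[["C_V"]],
            q_vlb = (1 - v[["f_vub"]]) * v[["C_V"]])
  q_un <- c(q_RA = v[["q_RA_un"]], q_RV = v[["q_RV_un"]],
            q_LA = v[["q_LA_un"]], q_LV = v[["q_LV_un"]])
  y0 <- v[["q_sbv"]] * comp / sum(comp)
  y0[names(q_un)] <- y0[names(q_un)] + q_un
  stats::setNames(as.numeric(y0), cvs_state_names())
}

#' Simulate the closed-loop cardiovascular model to a periodic state
#'
#' Integrates the packaged 17-compartment lumped-parameter model over
#' repeated cardiac cycles until the cycle-start state vector changes by
#' less than the periodicity tolerance (or `max_cycles` is reached), then
#' samples the final cycle and computes the named scalar observables and
#' the middle cerebral artery pressure waveform (the core prediction).
#'
#' Integrator failure is not an error: it yields `solver_ok = FALSE` with
#' absent summaries, which callers (genetic algorithm, MCMC) treat as
#' rejection of the parameter set.
#'
#' @param params A parameter table (see [cvs_parameters()]) or a named
#'   numeric vector of values merged onto the default table.
#' @param config A [cvs_sim_config()].
#' @param init Optional named initial state vector (e.g. the `final_state`
#'   of a previous run) used to warm-start the search for the periodic
#'   cycle.
#' @param light If `TRUE`, only the waveform columns required for the
#'   observables are computed (used internally for objective evaluations).
#' @return An object of class `cvs_outputs`: a list with `summaries`
#'   (named vector of the 15 observables), `core` (the three `p_MC`
#'   summaries, kPa), `waveforms` (tibble over the final cycle),
#'   `solver_ok`, `cycles`, `converged`, `final_state`, and
#'   `volume_drift` (relative change of total volume over the run).
#' @export
#' @examples
#' \donttest{
#' out <- simulate_cvs(cvs_parameters())
#' out$summaries[["mean(p_BR)"]]  # mean brachial pressure, kPa
#' }
simulate_cvs <- function(params = cvs_parameters(),
                         config = cvs_sim_config(), init = NULL,
                         light = FALSE) {
  v <- if (is.numeric(params)) {
    ptable <- set_parameters(cvs_parameters(), params)
    stats::setNames(ptable$value, ptable$name)
  } else {
    stats::setNames(params$value, params$name)
  }
  cvs_simulate_values(v, config, init, light)
}

# fast path: `v` is the full named vector of parameter values
cvs_simulate_values <- function(v, config = cvs_sim_config(), init = NULL,
                                light = FALSE) {
  if (!all(is.finite(v))) stop("non-finite parameter value")
  if (any(v < 0)) stop("negative parameter value")

  p <- cvs_parm_from_values(v)
  period <- p[[1]]
  y <- if (is.null(init)) cvs_initial_state(v) else {
    stopifnot(all(cvs_state_names() %in% names(init)))
    init[cvs_state_names()]
  }
  total0 <- sum(y)

  fail <- function(cycles) {
    structure(list(summaries = NULL, core = NULL, waveforms = NULL,
                   solver_ok = FALSE, cycles = cycles, converged = FALSE,
                   final_state = NULL, volume_drift = NA_real_),
              class = "cvs_outputs")
  }

  one_cycle <- function(y, times) {
    out <- try(suppressWarnings(
      deSolve::lsoda(y, times, func = "cvs_derivs", parms = p,
                     dllname = "cvscalib", initfunc = "cvs_initmod",
                     rtol = config$rtol, atol = config$atol,
                     maxsteps = 20000)
    ), silent = TRUE)
    if (inherits(out, "try-error")) return(NULL)
    istate <- attr(out, "istate")
    if (!is.null(istate) && istate[1] < 0) return(NULL)
    if (!all(is.finite(out[nrow(out), -1]))) return(NULL)
    out
  }

  # integrate cycles in chunks (one solver call spans several cycles,
  # with output rows at the cycle boundaries) and test periodicity
  # between consecutive cycle starts; the approach to the limit cycle is
  # dominated by a slow geometric mode, so after each unconverged chunk
  # the cycle map is Aitken-accelerated (the jump is only a better
  # starting point - convergence is still certified by a genuine
  # cycle-to-cycle difference)
  converged <- FALSE
  cycles <- 0L
  chunk <- 3L
  y_hist <- list()
  while (cycles < config$max_cycles && !converged) {
    n_cyc <- min(chunk, config$max_cycles - cycles)
    out <- one_cycle(y, seq(0, n_cyc * period, by = period))
    if (is.null(out)) return(fail(cycles))
    for (r in 2:nrow(out)) {
      y_new <- stats::setNames(as.numeric(out[r, -1]), cvs_state_names())
      cycles <- cycles + 1L
      delta <- max(abs(y_new - y) / pmax(abs(y), 1e-12))
      y <- y_new
      y_hist[[length(y_hist) + 1L]] <- y
      if (cycles >= config$min_cycles && delta < config$periodicity_tol) {
        converged <- TRUE
        break
      }
    }
    n_h <- length(y_hist)
    if (!converged && n_h >= 3) {
      d1 <- y_hist[[n_h - 1]] - y_hist[[n_h - 2]]
      d2 <- y_hist[[n_h]] - y_hist[[n_h - 1]]
      rho2 <- sum(d2^2) / max(sum(d1^2), 1e-300)
      if (rho2 < 0.9) {
        rho <- sqrt(rho2)
        y_jump <- y + d2 * rho / (1 - rho)
        if (all(is.finite(y_jump)) && all(y_jump > 0)) {
          y <- y_jump
          y_hist <- list()
        }
      }
    }
  }

  n_out <- max(16L, round(config$sample_hz * period))
  times <- seq(0, period, length.out = n_out + 1L)
  out <- one_cycle(y, times)
  if (is.null(out)) return(fail(cycles))

  wf <- cvs_waveforms(out, v, light = light)
  final_state <- stats::setNames(as.numeric(out[nrow(out), -1]),
                                 cvs_state_names())
  drift <- abs(sum(final_state) - total0) / total0

  summaries <- extract_observables(wf, cvs_observables())
  core <- extract_observables(wf, cvs_core_predictions())
  structure(list(summaries = summaries, core = core, waveforms = wf,
                 solver_ok = TRUE, cycles = cycles, converged = converged,
                 final_state = final_state, volume_drift = drift),
            class = "cvs_outputs")
}

#' @export
print.cvs_outputs <- function(x, ...) {
  if (!x$solver_ok) {
    cat("<cvs_outputs> solver failed\n")
    return(invisible(x))
  }
  cat("<cvs_outputs> periodic after", x$cycles, "cycles",
      if (!x$converged) "(not converged)" else "", "\n")
  print(round(tibble::tibble(observable = names(x$summaries),
                             value = unname(x$summaries)), 6))
  invisible(x)
}

# derived waveform table over the final cycle (pressures in kPa);
# `v` is the named parameter-value vector;
# light = TRUE computes only the columns the observables need
cvs_waveforms <- function(out, v, light = FALSE) {
  tm <- out[, 1]
  period <- v[["period"]]
  col <- function(nm) out[, nm]

  p_AO <- col("q_AO") / v[["C_AO"]]
  p_CER <- col("q_CER") / v[["C_CER"]]

  beds <- cvs_terminal_beds()
  src <- list(LE = p_AO, BR = p_AO, AC = p_CER, EC = p_CER, MC = p_CER,
              PC = p_CER, TR = p_AO)
  seg <- c(LE = v[["R_seg_LE"]], BR = v[["R_seg_BR"]], AC = 0, EC = 0,
           MC = 0, PC = 0, TR = v[["R_seg_TR"]])
  vflow <- lapply(beds, function(b) {
    p_term <- col(paste0("q_", b, "_T")) / v[[paste0("C_", b, "_T")]]
    (src[[b]] - p_term) / (seg[[b]] + v[[paste0("R_", b, "_T")]])
  })
  names(vflow) <- paste0("v_", beds, "_T")

  # brachial artery pressure: downstream of the brachial segment resistance
  p_BR <- p_AO - vflow$v_BR_T * v[["R_seg_BR"]]

  if (light) {
    cols <- c(list(time = tm,
                   q_la = col("q_LA"), q_lv = col("q_LV"),
                   q_ra = col("q_RA"),
                   p_BR = p_BR * 1000, p_MC = p_CER * 1000),
              vflow)
    return(tibble::new_tibble(cols, nrow = length(tm)))
  }

  p_ch <- function(ch, qn) {
    E <- chamber_elastance(tm, v[[paste0("E_", ch, "a")]],
                           v[[paste0("E_", ch, "b")]],
                           v[[paste0("on_", ch)]], v[[paste0("du_", ch)]],
                           period)
    E * (col(qn) - v[[paste0("q_", ch, "_un")]])
  }
  p_RA <- p_ch("RA", "q_RA"); p_RV <- p_ch("RV", "q_RV")
  p_LA <- p_ch("LA", "q_LA"); p_LV <- p_ch("LV", "q_LV")
  p_par <- col("q_par") / v[["C_par"]]
  p_pvn <- col("q_pvn") / v[["C_pvn"]]
  p_vub <- col("q_vub") / (v[["f_vub"]] * v[["C_V"]])
  p_vlb <- col("q_vlb") / ((1 - v[["f_vub"]]) * v[["C_V"]])

  soft_ramp <- function(dp, k) ifelse(k * dp > 30, dp, log1p(exp(k * dp)) / k)
  k <- v[["k_valve"]]
  v_trv <- soft_ramp(p_RA - p_RV, k) / v[["R_trv"]]
  v_puv <- soft_ramp(p_RV - p_par, k) / v[["R_puv"]]
  v_miv <- soft_ramp(p_LA - p_LV, k) / v[["R_miv"]]
  v_aov <- soft_ramp(p_LV - p_AO, k) / v[["R_aov"]]

  cols <- c(
    list(time = tm,
         q_la = col("q_LA"), q_lv = col("q_LV"), q_ra = col("q_RA"),
         q_rv = col("q_RV"),
         p_BR = p_BR * 1000, p_MC = p_CER * 1000,   # kPa
         p_AO = p_AO * 1000, p_LV = p_LV * 1000, p_RA = p_RA * 1000,
         p_par = p_par * 1000, p_pvn = p_pvn * 1000,
         p_vub = p_vub * 1000, p_vlb = p_vlb * 1000,
         v_trv = v_trv, v_puv = v_puv, v_miv = v_miv, v_aov = v_aov),
    vflow,
    lapply(stats::setNames(cvs_state_names(), cvs_state_names()), col)
  )
  tibble::new_tibble(cols, nrow = length(tm))
}

#' Extract max/min/mean observables from final-cycle waveforms
#'
#' Observable names have the form `"op(var)"` with `op` one of `max`,
#' `min`, `mean` and `var` a waveform column (e.g. `"mean(v_MC_T)"`).
#' Means are computed as the trapezoidal time average over exactly one
#' period; max/min are taken over the sampled grid.
#'
#' @param waveforms Waveform tibble from [simulate_cvs()] (must contain a
#'   `time` column spanning one period).
#' @param names Character vector of observable names.
#' @return Named numeric vector, one entry per requested observable.
#' @export
extract_observables <- function(waveforms, names) {
  stopifnot(is.data.frame(waveforms), "time" %in% colnames(waveforms))
  parsed <- parse_observable_names(names)
  ops <- parsed$ops
  vars <- parsed$vars
  unknown <- setdiff(unique(vars), colnames(waveforms))
  if (length(unknown) > 0) {
    stop("unknown observable variable(s): ",
         paste(unknown, collapse = ", "),
         "; valid variables: ",
         paste(setdiff(colnames(waveforms), "time"), collapse = ", "))
  }
  tm <- waveforms$time
  out <- mapply(function(op, var) {
    x <- waveforms[[var]]
    switch(op,
           max = max(x),
           min = min(x),
           mean = trapz_mean(tm, x))
  }, ops, vars)
  stats::setNames(as.numeric(out), names)
}

# parse "op(var)" observable names, memoised on the name set
parse_observable_names <- function(names) {
  key <- paste(names, collapse = "\r")
  hit <- .cvs_cache$obs_parse[[key]]
  if (!is.null(hit)) return(hit)
  m <- regmatches(names, regexec("^(max|min|mean)\\(([^)]+)\\)$", names))
  bad <- names[vapply(m, length, integer(1)) != 3]
  if (length(bad) > 0) {
    stop("malformed observable name(s): ", paste(bad, collapse = ", "))
  }
  out <- list(ops = vapply(m, `[[`, character(1), 2),
              vars = vapply(m, `[[`, character(1), 3))
  if (is.null(.cvs_cache$obs_parse)) .cvs_cache$obs_parse <- list()
  .cvs_cache$obs_parse[[key]] <- out
  out
}

trapz_mean <- function(t, x) {
  n <- length(t)
  if (n < 2) return(x[1])
  sum(diff(t) * (x[-1] + x[-n]) / 2) / (t[n] - t[1])
}
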