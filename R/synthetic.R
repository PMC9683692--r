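#' Default coefficient-of-variation table for the measurement set
#'
#' Inter-observer coefficients of variation for the 15 observables of the
#' packaged model's measurement set: echocardiographic chamber-volume
#' extrema, brachial cuff pressures, and mean terminal flows. The mean
#' brachial pressure CV (2.25%) is a consolidated estimate derived from
#' the max and min brachial CVs; the arm, leg, and trunk flow CVs are set
#' large so those synthetic flow targets only weakly constrain the fit.
#'
#' @return A tibble with columns `name`, `cv_percent`, `cv` (fraction).
#' @export
#' @examples
#' default_cv_table()
default_cv_table <- function() {
  out <- tibble::tibble(
    name = cvs_observables(),
    cv_percent = c(21.3, 23.5, 12.6, 19.4, 10.0,
                   1.5, 4.0, 2.25,
                   30.0, 30.0, 8.0, 8.0, 8.0, 8.0, 50.0)
  )
  out$cv <- out$cv_percent / 100
  out
}

#' Generate a synthetic patient with known ground truth
#'
#' Simulates the packaged cardiovascular model at a known true parameter
#' vector and applies multiplicative Gaussian noise, `z = f * (1 + CV * xi)`
#' with `xi ~ N(0, 1)`, independently per observable. Draws that would make
#' a measurement non-positive are resampled, keeping all measurements
#' strictly positive without a point mass at zero. Observables listed in
#' `missing` are dropped, emulating patients for whom a measurement was
#' not obtained.
#'
#' @param theta_true Named numeric vector of parameter values defining the
#'   ground truth (merged onto [cvs_parameters()]); default uses the
#'   nominal table unchanged.
#' @param cv_table CV table as from [default_cv_table()]; rows restrict
#'   which observables are measured.
#' @param missing Character vector of observable names to omit.
#' @param seed Integer seed for the noise draws.
#' @param patient_id Identifier stored with the measurement set.
#' @param config Simulation settings.
#' @return An object of class `synthetic_patient`: list with
#'   `measurements` (a [measurement_set()]), `theta_true` (full named
#'   parameter vector), `truth` (the noise-free `cvs_outputs`, including
#'   the middle cerebral pressure waveform), `missing`, and `seed`.
#' @export
#' @examples
#' \donttest{
#' pat <- generate_patient(seed = 1)
#' pat$measurements
#' }
generate_patient <- function(theta_true = NULL,
                             cv_table = default_cv_table(),
                             missing = character(),
                             seed = 1L,
                             patient_id = "synthetic",
                             config = cvs_sim_config()) {
  ptable <- cvs_parameters()
  if (!is.null(theta_true)) ptable <- set_parameters(ptable, theta_true)
  validate_parameter_table(ptable)
  truth <- simulate_cvs(ptable, config)
  if (!truth$solver_ok) stop("forward model failed at theta_true")

  unknown <- setdiff(missing, cv_table$name)
  if (length(unknown) > 0) {
    stop("missing-name(s) not in the CV table: ", paste(unknown, collapse = ", "))
  }
  keep <- cv_table[!cv_table$name %in% missing, ]
  f <- truth$summaries[keep$name]

  noisy <- with_seed(seed, {
    vapply(seq_along(f), function(i) {
      repeat {
        z <- f[[i]] * (1 + keep$cv[i] * stats::rnorm(1))
        if (keep$cv[i] == 0 || z > 0) return(z)
      }
    }, numeric(1))
  })

  # zero-CV observables are exact measurements; they carry a vanishing
  # nominal sigma so the measurement-set invariant sigma > 0 holds
  sigma <- ifelse(keep$cv > 0, NA_real_, abs(noisy) * 1e-12)
  ms <- measurement_set(
    data.frame(name = keep$name, value = noisy, cv = keep$cv,
               sigma = sigma),
    patient_id = patient_id
  )
  theta <- stats::setNames(ptable$value, ptable$name)
  structure(list(measurements = ms,
                 theta_true = theta[ptable$status == "free"],
                 theta_full = theta,
                 truth = truth, missing = missing, seed = seed),
            class = "synthetic_patient")
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat("<synthetic_patient> seed", x$seed, "with", nrow(x$measurements),
      "measurements")
  if (length(x$missing)) cat("; missing:", paste(x$missing, collapse = ", "))
  cat("\n")
  print(x$measurements)
  invisible(x)
}

#' Preset synthetic patients
#'
#' Three measurement-availability patterns seen in clinical practice: a
#' full 15-observable set, a set lacking the minimum left-atrial volume,
#' and a set lacking both left-ventricular volume extrema.
#'
#' @param seed Base seed; patient k uses `seed + k - 1` for its noise.
#' @param noise_free If `TRUE`, all CVs used for the noise draw are zero
#'   (measurement values equal the ground truth) while the stored
#'   uncertainties keep the default CVs.
#' @return List of three `synthetic_patient` objects.
#' @export
preset_patients <- function(seed = 100L, noise_free = FALSE) {
  patterns <- list(
    full = character(),
    no_min_qla = "min(q_la)",
    no_qlv = c("max(q_lv)", "min(q_lv)")
  )
  out <- lapply(seq_along(patterns), function(k) {
    pat <- generate_patient(missing = patterns[[k]],
                            seed = seed + k - 1L,
                            patient_id = names(patterns)[k])
    if (noise_free) {
      truth_vals <- pat$truth$summaries[pat$measurements$name]
      pat$measurements$value <- as.numeric(truth_vals)
      pat$measurements$sigma <- pat$measurements$cv * abs(pat$measurements$value)
    }
    pat
  })
  stats::setNames(out, names(patterns))
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
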