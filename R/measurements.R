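#' Convert a coefficient of variation to a standard deviation
#'
#' The coefficient of variation (CV) of a repeated measurement relates to
#' its standard deviation as `sigma = CV * |value|`. The CV itself can be
#' derived from a repeatability coefficient expressed as a percent of the
#' measurement, `CV = RC% / 2.77`.
#'
#' @param cv Coefficient of variation as a dimensionless fraction.
#' @param value Measurement value (any units).
#' @return Standard deviation in the units of `value`.
#' @export
#' @examples
#' cv_to_sigma(0.08, 100)   # 8
#' rc_to_cv(2.77)           # 1
cv_to_sigma <- function(cv, value) {
  stopifnot(cv >= 0)
  if (any(value == 0)) stop("sigma undefined for value = 0 with CV-specified uncertainty")
  cv * abs(value)
}

#' @rdname cv_to_sigma
#' @param rc_percent Repeatability coefficient as a percent of the
#'   measurement value.
#' @export
rc_to_cv <- function(rc_percent) {
  stopifnot(rc_percent >= 0)
  rc_percent / 2.77
}

#' Build a measurement set
#'
#' A measurement set is a tibble of named scalar observables with values
#' and uncertainties. Exactly one of `cv` (fraction) or `sigma` must be
#' supplied per measurement; the other is derived. Observables a patient
#' does not have are simply absent rows.
#'
#' @param data A data frame with columns `name`, `value`, and one or both
#'   of `cv` (fraction) and `sigma` (with the unsupplied entries `NA`).
#' @param patient_id Optional identifier attached as an attribute.
#' @return A tibble of class `measurement_set` with columns `name`,
#'   `value`, `cv`, `sigma`.
#' @export
measurement_set <- function(data, patient_id = NA_character_) {
  stopifnot(is.data.frame(data), all(c("name", "value") %in% names(data)))
  if (nrow(data) < 1) stop("a measurement set needs at least one measurement")
  if (!"cv" %in% names(data)) data$cv <- NA_real_
  if (!"sigma" %in% names(data)) data$sigma <- NA_real_
  if (anyDuplicated(data$name)) stop("duplicate measurement names")
  if (!all(is.finite(data$value))) stop("measurement values must be finite")
  both_na <- is.na(data$cv) & is.na(data$sigma)
  if (any(both_na)) {
    stop("each measurement needs cv or sigma: ",
         paste(data$name[both_na], collapse = ", "))
  }
  fill_sigma <- is.na(data$sigma)
  data$sigma[fill_sigma] <- cv_to_sigma(data$cv[fill_sigma],
                                        data$value[fill_sigma])
  fill_cv <- is.na(data$cv)
  data$cv[fill_cv] <- data$sigma[fill_cv] / abs(data$value[fill_cv])
  if (any(data$sigma <= 0)) stop("sigma must be positive")
  out <- tibble::as_tibble(data[, c("name", "value", "cv", "sigma")])
  attr(out, "patient_id") <- patient_id
  class(out) <- c("measurement_set", class(out))
  out
}

#' Read / write a measurement CSV
#'
#' Format: header `patient_id,name,value,cv_percent,sigma` with exactly one
#' of `cv_percent` (CV as percent, as printed in clinical tables) or
#' `sigma` non-empty per row.
#'
#' @param path File path.
#' @return A `measurement_set` tibble (CVs stored as fractions).
#' @export
read_measurement_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "name", "value")
  if (!all(need %in% names(df))) {
    stop("measurement CSV requires columns: ", paste(need, collapse = ", "))
  }
  cv <- if ("cv_percent" %in% names(df)) df$cv_percent / 100 else NA_real_
  sigma <- if ("sigma" %in% names(df)) df$sigma else NA_real_
  measurement_set(
    data.frame(name = df$name, value = df$value, cv = cv, sigma = sigma),
    patient_id = as.character(df$patient_id[1])
  )
}

#' @rdname read_measurement_csv
#' @param ms Measurement set to write.
#' @export
write_measurement_csv <- function(ms, path) {
  df <- data.frame(patient_id = attr(ms, "patient_id"),
                   name = ms$name, value = ms$value,
                   cv_percent = ms$cv * 100, sigma = ms$sigma)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Weighted sum-of-squares cost of a simulation against measurements
#'
#' Computes `sum_i ((f_i - z_i) / sigma_i)^2` over the measurements in the
#' set, where `f_i` are the simulated observables. A failed forward
#' simulation (`solver_ok = FALSE`) has infinite cost: the parameter set is
#' rejected rather than raising an error.
#'
#' @param outputs A `cvs_outputs` object from [simulate_cvs()], or a named
#'   numeric vector of observable values.
#' @param data A `measurement_set`.
#' @return Non-negative scalar cost (`Inf` on solver failure).
#' @export
cost <- function(outputs, data) {
  f <- outputs_summaries(outputs)
  if (is.null(f)) return(Inf)
  missing_names <- setdiff(data$name, names(f))
  if (length(missing_names) > 0) {
    stop("measurement(s) not among simulated observables: ",
         paste(missing_names, collapse = ", "))
  }
  sum(((f[data$name] - data$value) / data$sigma)^2)
}

#' Gaussian log-likelihood of a simulation
#'
#' Independent-Gaussian measurement noise makes the log-likelihood (up to
#' an additive constant) `-0.5` times the weighted sum-of-squares [cost()];
#' solver failure maps to `-Inf` (rejection).
#'
#' @inheritParams cost
#' @return Scalar log-likelihood (`-Inf` on solver failure).
#' @export
log_likelihood <- function(outputs, data) {
  -0.5 * cost(outputs, data)
}

#' Standardized and percent residuals of a fit
#'
#' @inheritParams cost
#' @return A tibble with one row per measurement: `name`, `observed`,
#'   `simulated`, `std_error` (residual / sigma), `pct_error`
#'   (residual / observed, `NA` when the observed value is zero).
#' @export
standardized_errors <- function(outputs, data) {
  f <- outputs_summaries(outputs)
  if (is.null(f)) stop("solver failed; no outputs to compare")
  missing_names <- setdiff(data$name, names(f))
  if (length(missing_names) > 0) {
    stop("measurement(s) not among simulated observables: ",
         paste(missing_names, collapse = ", "))
  }
  sim <- as.numeric(f[data$name])
  resid <- sim - data$value
  tibble::tibble(
    name = data$name,
    observed = data$value,
    simulated = sim,
    std_error = resid / data$sigma,
    pct_error = ifelse(data$value == 0, NA_real_, resid / data$value)
  )
}

outputs_summaries <- function(outputs) {
  if (inherits(outputs, "cvs_outputs")) {
    if (!isTRUE(outputs$solver_ok)) return(NULL)
    c(outputs$summaries, outputs$core)
  } else if (is.numeric(outputs) && !is.null(names(outputs))) {
    outputs
  } else {
    stop("outputs must be a cvs_outputs object or a named numeric vector")
  }
}
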