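#' Plot simulated waveforms
#'
#' @param object A `cvs_outputs` object.
#' @param vars Waveform columns to show.
#' @param ... Unused.
#' @return A ggplot object, faceted by variable.
#' @export
autoplot.cvs_outputs <- function(object,
                                 vars = c("p_BR", "p_MC", "q_lv", "v_aov"),
                                 ...) {
  stopifnot(object$solver_ok)
  df <- tidyr::pivot_longer(object$waveforms[, c("time", vars)],
                            -"time", names_to = "variable")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time within cycle [s]", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the genetic-algorithm cost history
#' @param object A `ga_fit`.
#' @param ... Unused.
#' @export
autoplot.ga_fit <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$generation, y = .data$best_cost)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generation", y = "best cost") +
    ggplot2::theme_minimal()
}

#' Trace or density plot of posterior chains
#'
#' @param object A `chain_set`.
#' @param type `"trace"` (per-walker traces) or `"density"` (flattened
#'   post-burn-in marginals).
#' @param parameters Subset of parameter names (default all).
#' @param ... Unused.
#' @export
autoplot.chain_set <- function(object, type = c("trace", "density"),
                               parameters = NULL, ...) {
  type <- match.arg(type)
  pnames <- parameters %||% object$parameters
  if (type == "trace") {
    dm <- dim(object$samples)
    df <- purrr::map_dfr(pnames, function(nm) {
      j <- match(nm, object$parameters)
      tibble::tibble(parameter = nm,
                     walker = rep(seq_len(dm[1]), dm[2]),
                     step = rep(seq_len(dm[2]), each = dm[1]),
                     value = as.numeric(object$samples[, , j]))
    })
    ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$value,
                                     group = .data$walker)) +
      ggplot2::geom_line(alpha = 0.2, linewidth = 0.2) +
      ggplot2::geom_vline(xintercept = object$burn_in, linetype = 2) +
      ggplot2::facet_wrap(~parameter, scales = "free_y") +
      ggplot2::theme_minimal()
  } else {
    ps <- posterior_samples(object)
    df <- tidyr::pivot_longer(ps[, pnames, drop = FALSE],
                              dplyr::everything(),
                              names_to = "parameter")
    ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
      ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
      ggplot2::facet_wrap(~parameter, scales = "free") +
      ggplot2::theme_minimal()
  }
}

#' Plot the core-prediction uncertainty band
#'
#' Pointwise mean and 95% band of the posterior-sampled middle cerebral
#' artery pressure waveform.
#'
#' @param object A `prediction_distribution`.
#' @param ... Unused.
#' @export
autoplot.prediction_distribution <- function(object, ...) {
  ggplot2::ggplot(object$band, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "steelblue") +
    ggplot2::labs(x = "time within cycle [s]",
                  y = "middle cerebral artery pressure [kPa]") +
    ggplot2::theme_minimal()
}

#' Heatmap of the final collinearity matrix
#'
#' @param report A `reduction_report`.
#' @param ... Unused.
#' @export
plot_collinearity <- function(report, ...) {
  it <- report$iterations[[length(report$iterations)]]
  g <- it$gamma
  df <- expand.grid(parameter_i = rownames(g), parameter_j = colnames(g),
                    stringsAsFactors = FALSE)
  df$gamma <- as.numeric(g)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parameter_i,
                                   y = .data$parameter_j,
                                   fill = pmin(.data$gamma, 20))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "gamma (capped at 20)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
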