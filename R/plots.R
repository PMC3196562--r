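#' Plot a simulated study
#'
#' Concentration-time curves by tissue, one line per dataset — the usual
#' first look at multi-tissue bolus data.
#'
#' @param object A `study_data` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.study_data <- function(object, ...) {
  obs <- object$data[object$data$EVID == 0, ]
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$TIME, y = .data$DV,
                                    group = .data$ID)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~TISSUE, scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = "Gd concentration [mM]") +
    ggplot2::theme_bw()
}

#' Trace plots of the typical-rate chains
#'
#' @param object A `pop_fit`.
#' @param ... Unused.
#' @return A ggplot with one facet per transfer constant (log scale).
#' @exportS3Method ggplot2::autoplot
autoplot.pop_fit <- function(object, ...) {
  th <- object$chains[, paste0("theta_", object$rate_names), drop = FALSE]
  df <- tibble(
    sample = rep(seq_len(nrow(th)), times = ncol(th)),
    parameter = rep(sub("^theta_", "", colnames(th)), each = nrow(th)),
    value = as.vector(th)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "retained sample", y = "typical rate [1/s]") +
    ggplot2::theme_bw()
}

#' Conditional-weighted-residual diagnostics plot
#'
#' CWRES against time by tissue with the +/-2 reference band.
#'
#' @param cwres Output of [compute_cwres()].
#' @return A ggplot.
#' @export
plot_cwres <- function(cwres) {
  ggplot2::ggplot(cwres, ggplot2::aes(x = .data$time, y = .data$cwres)) +
    ggplot2::geom_hline(yintercept = c(-2, 0, 2), linetype = c(2, 1, 2),
                        colour = "grey50") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~tissue) +
    ggplot2::labs(x = "time [s]", y = "CWRES") +
    ggplot2::theme_bw()
}

#' Model-comparison bar graph
#'
#' \eqn{\Delta}OFV of each candidate model relative to the reference
#' (reference at zero), annotated with DIC.
#'
#' @param comparison Output of [compare_models()].
#' @return A ggplot.
#' @export
plot_comparison <- function(comparison) {
  ggplot2::ggplot(comparison,
                  ggplot2::aes(x = .data$model, y = .data$delta_ofv)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = expression(Delta * "OFV")) +
    ggplot2::theme_bw()
}

#' Posterior central-compartment curve plot
#'
#' Median and credible band of the model-reconstructed central (plasma)
#' concentration — the arterial-input-function surrogate.
#'
#' @param curve Output of [central_curve()].
#' @return A ggplot.
#' @export
plot_central_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$time, y = .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper), alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [s]", y = "central concentration [mM]") +
    ggplot2::theme_bw()
}
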