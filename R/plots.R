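#' Regression plot of predicted vs measured displacements
#'
#' One panel per RoI x component with the identity line, the fitted
#' regression line and the R-squared annotation — the standard way to
#' inspect full-field displacement agreement.
#'
#' @param object a [validate_displacements()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.spinefe_validation <- function(object, ...) {
  cps <- names(object$config$components)
  idx <- object$config$components
  long <- dplyr::bind_rows(lapply(cps, function(cp) {
    suff <- c("x", "y", "z")[idx[[cp]]]
    tibble::tibble(roi = object$points$roi, component = cp,
                   u_dic = object$points[[paste0("u_dic_", suff)]],
                   u_fem = object$points[[paste0("u_fem_", suff)]])
  }))
  lab <- dplyr::mutate(object$metrics,
                       label = sprintf("R² = %.3f", .data$r_squared))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$u_dic, y = .data$u_fem)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "firebrick") +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$label),
                       x = -Inf, y = Inf, hjust = -0.1, vjust = 1.5,
                       size = 3, inherit.aes = FALSE) +
    ggplot2::facet_grid(roi ~ component, scales = "free") +
    ggplot2::labs(x = "measured displacement (mm)",
                  y = "predicted displacement (mm)")
}

#' Bland-Altman agreement plot
#'
#' @param ba a [bland_altman()] result.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(ba) {
  ggplot2::ggplot(ba$data, ggplot2::aes(x = .data$mean,
                                        y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = ba$bias, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = c(ba$loa_lower, ba$loa_upper),
                        linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "mean of measured and predicted (mm)",
                  y = "difference (mm)")
}

#' Disc-calibration convergence plot
#'
#' @param calibration a [calibrate_disc_modulus()] result.
#' @return A ggplot object.
#' @export
plot_calibration_log <- function(calibration) {
  ggplot2::ggplot(calibration$log,
                  ggplot2::aes(x = .data$iteration, y = .data$force)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "solve", y = "axial reaction (N)")
}
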