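#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.cet_diameter_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$arclength, y = .data$diameter)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$open), size = 1) +
    ggplot2::labs(
      x = "Arclength along path (Å)",
      y = "Tunnel diameter (Å)",
      colour = "Open"
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.cet_hydrophobicity_profile <- function(object, ...) {
  ok <- object[!object$undefined, ]
  p <- ggplot2::ggplot(ok, ggplot2::aes(x = .data$arclength, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "Arclength along path (Å)",
      y = "SASA-weighted hydropathy (Kyte-Doolittle)"
    ) +
    ggplot2::theme_minimal()
  if (any(is.finite(ok$sd))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$value - .data$sd,
        ymax = .data$value + .data$sd
      ),
      alpha = 0.2, na.rm = TRUE
    )
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.power_law_fit <- function(object, ...) {
  dat <- tibble::tibble(
    log_force = object$lm$model$lx,
    log_time = object$lm$model$ly
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$log_force, y = .data$log_time)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      intercept = log(object$A), slope = -object$b, colour = "steelblue"
    ) +
    ggplot2::labs(
      x = "log Force (kcal/mol/Å)",
      y = "log Time (ns)",
      title = sprintf(
        "Time = %.3g × Force^-%.3g  (|r| = %.3f)",
        object$A, object$b, abs(object$r)
      )
    ) +
    ggplot2::theme_minimal()
}

#' Force-time scatter with the fitted power law
#'
#' @param table Replicate force-time table (`force`, `time_ns`).
#' @param fit Optional `power_law_fit` overlay.
#' @return A ggplot.
#' @export
plot_force_time <- function(table, fit = NULL) {
  p <- ggplot2::ggplot(table, ggplot2::aes(x = .data$force, y = .data$time_ns)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Driving force (kcal/mol/Å)", y = "Transfer time (ns)"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    grid <- tibble::tibble(force = exp(seq(
      log(min(table$force)), log(max(table$force)), length.out = 100
    )))
    grid$time_ns <- fit$A * grid$force^(-fit$b)
    p <- p + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  p
}
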