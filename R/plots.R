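# ggplot2 visualisations for fitted objects and reports.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an LRA regression fit
#'
#' Deviation (reference minus optimized) against the optimized value, the
#' fitted line and its confidence band.
#'
#' @param object An `lra_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lra_fit
#' @export
autoplot.lra_fit <- function(object, ...) {
  d <- object$pairs
  d$delta <- d$r_se - d$r_opt
  xr <- range(d$r_opt)
  grid <- data.frame(r_opt = seq(xr[1], xr[2], length.out = 100))
  pr <- stats::predict(object$lm, newdata = grid, interval = "confidence",
                       level = object$conf_level)
  grid <- cbind(grid, as.data.frame(pr))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r_opt)) +
    ggplot2::geom_ribbon(data = grid,
                         ggplot2::aes(ymin = .data$lwr, ymax = .data$upr),
                         alpha = 0.2, fill = "darkgreen") +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit),
                       color = "darkgreen") +
    ggplot2::geom_point(ggplot2::aes(y = .data$delta)) +
    ggplot2::labs(x = "optimized value", y = "reference - optimized",
                  title = sprintf("linear correction: A = %.5g, B = %.5g (n = %d)",
                                  object$A, object$B, object$n)) +
    ggplot2::theme_minimal()
}

#' Plot refinement residuals per isotopologue and axis
#'
#' @param object A `sefit_result`.
#' @param ... Unused.
#' @return A ggplot of inertia-moment residuals.
#' @method autoplot sefit_result
#' @export
autoplot.sefit_result <- function(object, ...) {
  fs <- object$fit_spec
  obs <- fs$observations
  K <- rotational_constant_K()
  pred <- predict_observables(object$structure, fs$isotopologues)
  key <- paste(obs$iso, obs$axis)
  I_hat <- pred$I_amuA2[match(key, paste(pred$iso, pred$axis))]
  d <- tibble::tibble(iso = obs$iso, axis = obs$axis,
                      resid = K / obs$B_se - I_hat)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$iso, y = .data$resid,
                                  fill = .data$axis)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "moment residual (amu Å²)",
                  title = sprintf("weighted RMS %.3g amu Å²",
                                  object$rms)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot predicted vs experimental constants of a pipeline report
#'
#' @param object A `nanolego_report` with experimental constants.
#' @param ... Unused.
#' @return A ggplot of per-axis percentage deviations.
#' @method autoplot nanolego_report
#' @export
autoplot.nanolego_report <- function(object, ...) {
  d <- object$constants
  if (!"percent_dev" %in% names(d)) {
    stop("report has no experimental constants to compare against",
         call. = FALSE)
  }
  ggplot2::ggplot(d, ggplot2::aes(x = toupper(.data$axis),
                                  y = .data$percent_dev)) +
    ggplot2::geom_col(width = 0.5, fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = "rotational constant",
                  y = "deviation from experiment (%)",
                  title = sprintf("MAD%% = %.2f", object$mad_percent)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
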