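#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot one pixel's decay and model fit
#'
#' Semi-log plot of the measured photon counts against the fitted
#' two-component model curve.
#'
#' @param fit A `pixel_fit` from [fit_pixel()].
#' @param decay The counts vector that was fitted.
#' @param irf The IRF kernel used.
#' @param time_axis The time axis used.
#' @return A ggplot object.
#' @export
plot_decay_fit <- function(fit, decay, irf,
                           time_axis = omiflim::time_axis()) {
  stopifnot(inherits(fit, "pixel_fit"))
  yhat <- model_decay(as.list(fit$params), time_axis, irf)
  df <- tibble::tibble(t = time_axis$centers,
                       counts = as.numeric(decay), model = yhat)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$counts),
                        size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$model), colour = "#d55e00") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "time (ns)", y = "photons / bin",
      title = sprintf(
        "tau1 %.2f ns, tau2 %.2f ns, alpha1 %.2f, tau_m %.2f ns (chi2 %.2f)",
        fit$params[["tau1"]], fit$params[["tau2"]],
        fit$params[["alpha1"]], fit$tau_mean, fit$reduced_chi2)
    ) +
    ggplot2::theme_minimal()
}

#' Raster display of a fitted parameter map
#'
#' @param object A `parameter_maps` object.
#' @param map Which map to show: one of `"tau_mean"` (default), `"tau1"`,
#'   `"tau2"`, `"alpha1"`, `"intensity"`, `"chi2"`.
#' @param ... Unused.
#' @return A ggplot object; invalid pixels are blank.
#' @export
autoplot.parameter_maps <- function(object, map = "tau_mean", ...) {
  map <- match.arg(map, c("tau_mean", "tau1", "tau2", "alpha1",
                          "intensity", "chi2"))
  m <- object[[map]]
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$value <- m[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey15") +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = map,
                  title = sprintf("%s (%s channel)", map, object$channel)) +
    ggplot2::theme_minimal()
}

#' Cohort endpoint display: dotplot over boxplot, coloured by day
#'
#' One point per macrophage, grouped by a factor, with the boxplot showing
#' median and quartiles (whiskers at 1.5 IQR) — the standard display for
#' per-cell optical endpoints.
#'
#' @param cohort_table Cell-record tibble.
#' @param outcome Endpoint column name.
#' @param group Grouping column name (default `"tnfa_status"`).
#' @return A ggplot object.
#' @export
plot_cohort_endpoint <- function(cohort_table, outcome,
                                 group = "tnfa_status") {
  df <- cohort_table[!is.na(cohort_table[[outcome]]) &
                       !is.na(cohort_table[[group]]), , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[group]],
                                        y = .data[[outcome]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5,
                          colour = "grey30", fill = NA)
  if ("day_id" %in% names(df)) {
    p <- p + ggplot2::geom_jitter(ggplot2::aes(colour = .data$day_id),
                                  width = 0.15, size = 1, alpha = 0.7)
  } else {
    p <- p + ggplot2::geom_jitter(width = 0.15, size = 1, alpha = 0.7)
  }
  p + ggplot2::labs(x = NULL, y = outcome, colour = "day") +
    ggplot2::theme_minimal()
}

#' Estimated group means with 95% confidence intervals
#'
#' @param object An `omi_glm` from [fit_glm()].
#' @param ... Unused.
#' @return A ggplot object of the estimated means and cluster-robust CIs.
#' @export
autoplot.omi_glm <- function(object, ...) {
  ggplot2::ggplot(object$means,
                  ggplot2::aes(x = .data$group, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf_low,
                                          ymax = .data$conf_high)) +
    ggplot2::labs(
      x = NULL,
      y = sprintf("%s%s", object$spec$outcome,
                  if (object$spec$log_transform) " (back-transformed)"
                  else ""),
      title = sprintf("Estimated means, 95%% CI (cluster-robust, %d df)",
                      object$df)
    ) +
    ggplot2::theme_minimal()
}
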