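# ggplot2 graphics for fits, sensitivities and projections

#' Trace and density plots of a calibrated fit
#'
#' @param object A `qm_fit` object.
#' @param type `"density"` (default) or `"trace"`.
#' @param pars Parameters to show; default all.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qm_fit <- function(object, type = c("density", "trace"),
                            pars = NULL, ...) {
  type <- match.arg(type)
  if (is.null(pars)) pars <- object$par_names
  long <- posterior_draws(object) |>
    dplyr::select(dplyr::all_of(c("chain", "iteration", pars))) |>
    tidyr::pivot_longer(dplyr::all_of(pars), names_to = "parameter") |>
    dplyr::mutate(chain = factor(.data$chain))
  if (type == "trace") {
    ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$value,
                                       colour = .data$chain)) +
      ggplot2::geom_line(alpha = 0.6, linewidth = 0.2) +
      ggplot2::facet_wrap(~parameter, scales = "free_y") +
      ggplot2::labs(x = "iteration", y = NULL)
  } else {
    ggplot2::ggplot(long, ggplot2::aes(.data$value, colour = .data$chain)) +
      ggplot2::geom_density() +
      ggplot2::facet_wrap(~parameter, scales = "free") +
      ggplot2::labs(x = NULL, y = "posterior density")
  }
}

#' Plot observed and fitted SOC trajectories
#'
#' Observations with the best-RMSE trajectory and the envelope of parameter
#' sets within the 95 % RMSE quantile, one panel per site.
#'
#' @param report A `qm_fit_report` from [report_fit()].
#' @return A ggplot object.
#' @export
plot_fit <- function(report) {
  stopifnot(inherits(report, "qm_fit_report"))
  ggplot2::ggplot(report$trajectories, ggplot2::aes(.data$time_y)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$best), colour = "red") +
    ggplot2::geom_point(data = report$observations,
                        ggplot2::aes(y = .data$soc_stock), shape = 5) +
    ggplot2::facet_wrap(~site_id, scales = "free") +
    ggplot2::labs(x = "years since start",
                  y = expression(SOC~stock~(Mg~C~ha^-1)))
}

#' Plot projected stocks with credible intervals
#'
#' @param projection A tibble from [project_stocks()].
#' @return A ggplot object.
#' @export
plot_projection <- function(projection) {
  ggplot2::ggplot(projection,
                  ggplot2::aes(.data$horizon_y, .data$median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~site_id, scales = "free_y") +
    ggplot2::labs(x = "projection horizon (years)",
                  y = expression(SOC~stock~(Mg~C~ha^-1)))
}

#' Plot HSY sensitivity: behavioral vs non-behavioral parameter CDFs
#'
#' @param partition A `qm_hsy` object.
#' @param parameters Parameters to show; default as in [ks_sensitivity()].
#' @return A ggplot object.
#' @export
plot_hsy <- function(partition, parameters = NULL) {
  stopifnot(inherits(partition, "qm_hsy"))
  ks <- ks_sensitivity(partition, parameters)
  long <- partition$elements |>
    dplyr::select(dplyr::all_of(c(ks$parameter, "behavioral"))) |>
    tidyr::pivot_longer(dplyr::all_of(ks$parameter),
                        names_to = "parameter")
  ggplot2::ggplot(long, ggplot2::aes(.data$value,
                                     colour = .data$behavioral)) +
    ggplot2::stat_ecdf() +
    ggplot2::facet_wrap(~parameter, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "empirical CDF")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
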