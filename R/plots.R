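# ggplot2 views of the cohort results and of individual kinetic fits.

#' Spaghetti plot of parameter trajectories
#'
#' One panel per parameter, one line per patient across the imaging
#' timepoints, with the cohort median marked — the standard way to show
#' per-patient on-treatment trajectories.
#'
#' @param records Records tibble (as from [run_pipeline()]).
#' @param parameters Parameters to plot (default: all present).
#' @return A ggplot object.
#' @export
plot_parameter_trajectories <- function(records,
                                        parameters = intersect(
                                          COHORT_PARAMETERS, names(records))) {
  long <- records |>
    dplyr::select(dplyr::all_of(c("patient", "timepoint", parameters))) |>
    tidyr::pivot_longer(dplyr::all_of(parameters), names_to = "parameter",
                        values_to = "value") |>
    dplyr::mutate(timepoint = factor(.data$timepoint,
                                     levels = TIMEPOINT_LEVELS),
                  parameter = factor(.data$parameter, levels = parameters))
  med <- long |>
    dplyr::group_by(.data$parameter, .data$timepoint) |>
    dplyr::summarise(value = median(.data$value, na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(.data$timepoint, .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$patient,
                                    colour = .data$patient),
                       alpha = 0.7, na.rm = TRUE) +
    ggplot2::geom_point(data = med, shape = 8, size = 3, na.rm = TRUE) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, colour = "patient") +
    ggplot2::theme_minimal()
}

#' Plot of a cohort change summary
#'
#' Median percentage change with min-max range per parameter and interval;
#' intervals whose exact signed-rank p falls below `alpha` are highlighted.
#'
#' @param summary Tibble from [change_summary()].
#' @param alpha Highlight threshold (default 0.05).
#' @return A ggplot object.
#' @export
plot_change_summary <- function(summary, alpha = 0.05) {
  summary <- dplyr::mutate(summary,
                           significant = !is.na(.data$p_value) &
                             .data$p_value < alpha)
  ggplot2::ggplot(summary,
                  ggplot2::aes(.data$parameter, .data$median_pct,
                               colour = .data$significant)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$min_pct,
                                          ymax = .data$max_pct)) +
    ggplot2::facet_wrap(~interval, ncol = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "% change from first timepoint",
                  colour = paste0("p < ", alpha)) +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a 2CXM fit
#'
#' Observed tissue concentrations and the fitted model curve.
#'
#' @param object A `twocxm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot twocxm_fit
#' @export
autoplot.twocxm_fit <- function(object, ...) {
  df <- tibble::tibble(time_s = object$times, observed = object$observed,
                       fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 0.8,
                        alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "concentration (a.u.)",
                  subtitle = sprintf(
                    "PF %.3g, PV %.3g, ve %.3g, PS %.3g (Ktrans %.3g /min)",
                    object$params$PF, object$params$PV, object$params$ve,
                    object$params$PS, object$params$Ktrans)) +
    ggplot2::theme_minimal()
}
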