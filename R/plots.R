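#' Plot a simulation trace
#'
#' Time course of the node pressures (default), compartment volumes or edge
#' flows, one panel per group, mirroring the waveform-and-hierarchy view of
#' the model's cerebrovascular and CSF pressures.
#'
#' @param object an `icp_trace` from [simulate_icp()].
#' @param what `"pressures"`, `"volumes"` or `"flows"`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot icp_trace
#' @export
autoplot.icp_trace <- function(object, what = c("pressures", "volumes",
                                                "flows"), ...) {
  what <- match.arg(what)
  cols <- switch(what,
    pressures = c("p_ao", "p_arl", "p_c", "p_v", "icp_ven", "icp_br",
                  "icp_sas", "p_spi", "p_sss"),
    volumes = .compartments,
    flows = .edges)
  long <- tidyr::pivot_longer(object[, c("time", cols)], -"time",
                              names_to = "series", values_to = "value")
  long$series <- factor(long$series, levels = cols)
  ylab <- switch(what, pressures = "pressure [mmHg]",
                 volumes = "volume [ml]", flows = "flow [ml/s]")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [s]", y = ylab, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a steady-state report as volume shifts from baseline
#'
#' @param object an `icp_steady` from [solve_steady_state()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot icp_steady
#' @export
autoplot.icp_steady <- function(object, ...) {
  d <- object$deltas
  d$compartment <- factor(d$compartment, levels = .compartments)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$compartment, y = .data$delta)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "volume change from baseline [ml]") +
    ggplot2::theme_minimal()
}

#' Plot a bolus pressure-volume curve
#'
#' @param curve a tibble from [bolus_pv_curve()].
#' @return A ggplot object showing the exponential-like rise of peak ICP
#'   with injected volume.
#' @export
plot_pv_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$volume,
                                      y = .data$peak_icp_br)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "injected volume [ml]", y = "peak ICP_BR [mmHg]") +
    ggplot2::theme_minimal()
}

#' Plot the pathological compartment-shift table
#'
#' One panel per output quantity, one bar per condition — the compartment
#' redistribution signature that separates hydrocephalus from cerebral
#' edema.
#'
#' @param report a tibble from [pathology_report()].
#' @return A ggplot object.
#' @export
plot_pathology_report <- function(report) {
  long <- tidyr::pivot_longer(
    report[, c("condition", "d_brain", "d_ventricles", "d_sas", "d_blood")],
    -"condition", names_to = "quantity", values_to = "delta")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$delta,
                                     fill = .data$condition)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "change from baseline [ml]") +
    ggplot2::theme_minimal()
}
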