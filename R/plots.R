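#' Plot pooled firing-rate kinetics
#'
#' Draws the pooled I(t) with a bootstrap standard-error ribbon, in
#' Mb^-1 min^-1 (the display unit customary for replication kinetics).
#'
#' @param object An [ensemble_kinetics()] table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ensemble_kinetics <- function(object, ...) {
  d <- object[!is.na(object$i), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = kb_to_mb(.data$i))) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = kb_to_mb(.data$i - 2 * .data$i_se),
                   ymax = kb_to_mb(.data$i + 2 * .data$i_se)),
      alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)",
                  y = expression(I(t) ~ (Mb^-1 ~ min^-1))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the normalized state variables of an ensemble
#'
#' Normalized potential-origin density over unreplicated DNA
#' (`rho(t)/rho0`) and normalized free-factor count (`NFD(t)/NFD*`) against
#' time, with a horizontal guide at 1 marking the critical threshold.
#'
#' @param kinetics An [ensemble_kinetics()] table.
#' @return A ggplot object.
#' @export
plot_state_variables <- function(kinetics) {
  d <- tidyr::pivot_longer(
    as_tibble(kinetics)[c("time", "rho_norm", "nfd_norm")],
    c("rho_norm", "nfd_norm"),
    names_to = "series", values_to = "value")
  d <- d[!is.na(d$value), ]
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotdash") +
    ggplot2::scale_colour_discrete(
      labels = c(nfd_norm = expression(N[FD](t) / N[FD]^"*"),
                 rho_norm = expression(rho(t) / rho[0]))) +
    ggplot2::labs(x = "time (min)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the replication-time distribution of an ensemble
#'
#' @param ensemble A `replication_ensemble`.
#' @param binwidth Histogram bin width in min.
#' @return A ggplot object.
#' @export
plot_replication_times <- function(ensemble, binwidth = 1) {
  d <- tibble(t = replication_times(ensemble))
  ggplot2::ggplot(d, ggplot2::aes(.data$t)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey60",
                            colour = "white") +
    ggplot2::labs(x = "replication time (min)", y = "runs") +
    ggplot2::theme_minimal()
}
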