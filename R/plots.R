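#' Plot surprise, dissipation and free energy versus batch size
#'
#' @param tbl Tibble from [run_bayes_batches()].
#' @return A ggplot.
#' @export
plot_bayes_batches <- function(tbl) {
  long <- tidyr::pivot_longer(tbl, c("delta_f", "surprise", "u_diss"),
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$b, y = .data$value,
                                     colour = .data$quantity)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "batch size b", y = "nats (beta = 1)",
                  colour = NULL,
                  title = "Surprise and dissipation grow with batch size") +
    ggplot2::theme_minimal()
}

#' Plot the quasi-static dissipation curve
#'
#' @param tbl Tibble from [quasistatic_curve()] / [run_lag_curve()].
#' @return A ggplot.
#' @export
plot_quasistatic <- function(tbl) {
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$N, y = .data$u_diss)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "protocol steps N", y = "dissipated utility",
                  title = "Dissipation vanishes in the quasi-static limit") +
    ggplot2::theme_minimal()
}

#' Plot forward and backward hysteresis trajectories
#'
#' @param res Result of [run_hysteresis()].
#' @param reps Which replicate(s) to show.
#' @return A ggplot.
#' @export
plot_hysteresis <- function(res, reps = 1) {
  tr <- dplyr::filter(res$trajectories, .data$rep %in% reps)
  tr <- dplyr::mutate(
    tr, trial_fwd = ifelse(.data$direction == "forward", .data$trial,
                           max(.data$trial) - .data$trial))
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$trial_fwd, y = .data$x,
                                   colour = .data$direction)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mu), colour = "grey40",
                       linetype = 2) +
    ggplot2::labs(x = "trial (forward time)", y = "action x",
                  title = "Adaptation trajectories under forward and reversed protocols") +
    ggplot2::theme_minimal()
}

#' Plot net utility, free energy and dissipation over a (beta, k) grid
#'
#' @param grid Grid tibble from [run_episodic()] or [run_langevin()].
#' @return A ggplot.
#' @export
plot_deliberation_grid <- function(grid) {
  long <- tidyr::pivot_longer(grid, c("mean_u_net", "delta_f", "mean_u_diss"),
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value,
                                     colour = factor(.data$beta))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "deliberation budget k", colour = "beta") +
    ggplot2::theme_minimal()
}

#' Plot convergence of the Jarzynski estimate
#'
#' @param conv Convergence tibble from [run_episodic()] or [run_langevin()].
#' @return A ggplot.
#' @export
plot_jarzynski_convergence <- function(conv) {
  ggplot2::ggplot(conv, ggplot2::aes(x = .data$n_traj, y = .data$jarz_mean,
                                     colour = factor(.data$k))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$target),
                        linetype = 2, colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "trajectories", y = "empirical <exp(beta U_net)>",
                  colour = "k") +
    ggplot2::theme_minimal()
}
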