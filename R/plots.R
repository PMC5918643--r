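#' Plot the institutional stock-flow trajectories
#'
#' Capacity stocks, remaining fund, and the controller output over time;
#' stage boundaries are implicit in the time axis (stages are contiguous).
#'
#' @param sim A `hybrid_sim`.
#'
#' @return A ggplot object.
#' @export
plot_sd_trace <- function(sim) {
  stopifnot(inherits(sim, "hybrid_sim"))
  long <- tidyr::pivot_longer(
    sim$sd_trace[c("t", "s1", "s2", "rho", "z_cog")],
    -"t",
    names_to = "series", values_to = "value"
  )
  labels <- c(
    s1 = "COASF stock", s2 = "CSSHF stock",
    rho = "remaining fund", z_cog = "controller output"
  )
  long$series <- factor(labels[long$series], levels = unname(labels))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$series), scales = "free_y") +
    ggplot2::labs(x = "time (units)", y = NULL,
      title = "Institutional stock-flow trajectories")
}

#' Plot the per-agent membership fans
#'
#' One line per agent for a given linguistic variable and term; with
#' heterogeneous constants the lines fan out, showing how differently
#' agents perceive the same intervention signal.
#'
#' @param sim A `hybrid_sim`.
#' @param variable Linguistic variable index (1 = COASF, 2 = CSSHF).
#' @param term Trace column to draw (default the socially updated Low).
#'
#' @return A ggplot object.
#' @export
plot_membership_fan <- function(sim, variable = 1,
                                term = c("mu_low_social", "mu_low_geometric",
                                         "mu_medium", "mu_high")) {
  stopifnot(inherits(sim, "hybrid_sim"))
  term <- match.arg(term)
  dat <- sim$agent_trace[sim$agent_trace$variable == variable, ]
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$t, y = .data[[term]], group = .data$agent_id
  )) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::labs(
      x = "time (units)", y = term,
      title = sprintf("Membership fan, variable %d", variable)
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Default plot for a simulation run
#'
#' @param object A `hybrid_sim`.
#' @param ... Unused.
#' @return A ggplot object (the stock-flow trajectories).
#' @export
autoplot.hybrid_sim <- function(object, ...) {
  plot_sd_trace(object)
}

#' Plot closed-form membership trajectories
#'
#' @param spec A [trajectory_spec()].
#' @param params A [term_params()].
#' @param n Number of grid points.
#' @return A ggplot object with one line per linguistic term.
#' @export
plot_membership_trajectory <- function(spec, params, n = 400) {
  traj <- membership_trajectory(seq(0, spec$t4, length.out = n), spec, params)
  long <- tidyr::pivot_longer(traj[c("t", "low", "medium", "high")],
    -"t",
    names_to = "term", values_to = "membership"
  )
  long$term <- factor(long$term, levels = c("low", "medium", "high"))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$t, y = .data$membership, colour = .data$term
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (units)", y = "degree of membership")
}
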