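#' Plot a trace
#'
#' @param trace A trace tibble.
#' @param ylab Y-axis label.
#' @return A ggplot.
#' @export
plot_trace <- function(trace, ylab = "value") {
  ggplot2::ggplot(as_trace(trace), ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot arena trajectories
#'
#' @param traj A trajectory tibble (`fly_id`, `frame`, `x_cm`, `y_cm`).
#' @param arena An [arena_config()]; draws the boundary and marks the active
#'   port.
#' @return A ggplot.
#' @export
plot_trajectories <- function(traj, arena = arena_config()) {
  th <- seq(0, 2 * pi, length.out = 200)
  boundary <- tibble::tibble(
    x_cm = arena$radius_cm * cos(th),
    y_cm = arena$radius_cm * sin(th)
  )
  port <- arena$port_positions[arena$active_port, ]
  ggplot2::ggplot(traj, ggplot2::aes(.data$x_cm, .data$y_cm,
                                     group = .data$fly_id,
                                     colour = factor(.data$fly_id))) +
    ggplot2::geom_path(data = boundary, inherit.aes = FALSE,
                       ggplot2::aes(.data$x_cm, .data$y_cm)) +
    ggplot2::geom_path(alpha = 0.7, show.legend = FALSE) +
    ggplot2::annotate("point", x = port[1], y = port[2], shape = 17, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)") +
    ggplot2::theme_minimal()
}

#' Plot postpulse kinetics group statistics
#'
#' @param group_stats Output of [kinetics_group_stats()].
#' @return A ggplot: mean +/- SEM radial velocity per window and stratum.
#' @export
plot_kinetics <- function(group_stats) {
  ggplot2::ggplot(
    group_stats,
    ggplot2::aes(.data$window, .data$mean_v_cm_s, fill = .data$stratum)
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_v_cm_s - .data$sem_v_cm_s,
        ymax = .data$mean_v_cm_s + .data$sem_v_cm_s
      ),
      position = ggplot2::position_dodge(0.9), width = 0.25
    ) +
    ggplot2::labs(x = "window after odor offset",
                  y = "radial velocity away from port (cm/s)") +
    ggplot2::theme_minimal()
}

#' Plot a binned mean-distance timecourse
#'
#' @param timecourse Output of [mean_distance_timecourse()].
#' @return A ggplot with a mean +/- SEM ribbon.
#' @export
plot_mean_distance <- function(timecourse) {
  ggplot2::ggplot(timecourse, ggplot2::aes(.data$time_s, .data$mean_distance_cm)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mean_distance_cm - .data$sem_cm,
        ymax = .data$mean_distance_cm + .data$sem_cm
      ),
      alpha = 0.3
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "mean distance from port (cm)") +
    ggplot2::theme_minimal()
}
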