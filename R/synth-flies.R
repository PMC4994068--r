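#' Simulate walking flies in a circular odor arena
#'
#' Random-walk-with-drift simulation of a group of flies in a circular arena
#' with an odorized boundary port. Every frame each fly diffuses its heading,
#' walks at its base speed, and acquires a radial drift toward or away from
#' the port whose signed magnitude is `drift_gain(c)` at the concentration it
#' currently senses. The sensed concentration is the local PID waveform at
#' the fly's distance from the port (distance-dependent peak and decay via
#' `profile`), delayed by the sensing latency; with `persistence_s > 0` the
#' drive holds the maximum sensed concentration over the trailing persistence
#' window, so directed movement outlasts the local odor decline. Boundaries
#' reflect.
#'
#' @param n Number of flies (>= 1).
#' @param arena An [arena_config()].
#' @param bp A [behavior_params()].
#' @param pulse An [odor_pulse_spec()] describing the odor schedule at the
#'   port.
#' @param total_s Simulated duration, seconds.
#' @param profile Distance profile for the local waveform, as in
#'   [arena_pid()].
#' @param dropout_prob Per-frame probability that a fly is missed in the
#'   detection table (tracker stress-testing).
#' @param detection_noise_sd Isotropic position noise added to detections, cm.
#' @param seed Integer RNG seed; the simulation is deterministic given it.
#'
#' @return A list with `trajectories` (tibble: `fly_id`, `frame`, `x_cm`,
#'   `y_cm` — ground truth) and `detections` (tibble: `frame`, `x_cm`,
#'   `y_cm` — possibly degraded, identity-free).
#' @export
simulate_flies <- function(n, arena, bp, pulse, total_s = 10,
                           profile = arena_decay_profile(),
                           dropout_prob = 0, detection_noise_sd = 0,
                           seed = 1) {
  stopifnot(n >= 1, inherits(arena, "arena_config"),
            inherits(bp, "behavior_params"), inherits(pulse, "odor_pulse_spec"))
  fr <- arena$frame_rate
  dt <- 1 / fr
  n_frames <- floor(total_s * fr) + 1
  port <- arena$port_positions[arena$active_port, ]
  radius <- arena$radius_cm

  # local concentration lookup: distance grid x frame grid
  d_grid <- seq(0, 2 * radius, by = 0.25)
  conc <- vapply(d_grid, function(d) {
    arena_pid(d, pulse, profile, total_s = total_s, sample_rate = fr)$value[seq_len(n_frames)]
  }, numeric(n_frames))
  local_conc <- function(dist, frame) {
    di <- pmin(length(d_grid), pmax(1, round(dist / 0.25) + 1))
    conc[cbind(frame, di)]
  }

  lag_frames <- round(bp$sensing_latency_s * fr)
  persist_frames <- max(1L, round(bp$persistence_s * fr) + 1L)

  with_seed(seed, {
    rr <- radius * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    x <- rr * cos(th)
    y <- rr * sin(th)
    heading <- stats::runif(n, 0, 2 * pi)
    sensed <- matrix(0, n, n_frames)

    traj_x <- matrix(0, n, n_frames)
    traj_y <- matrix(0, n, n_frames)
    traj_x[, 1] <- x
    traj_y[, 1] <- y

    for (f in seq_len(n_frames)) {
      dist <- sqrt((x - port[1])^2 + (y - port[2])^2)
      f_sense <- f - lag_frames
      sensed[, f] <- if (f_sense >= 1) local_conc(dist, rep(f_sense, n)) else 0
      if (f == n_frames) break

      w0 <- max(1L, f - persist_frames + 1L)
      c_eff <- apply(sensed[, w0:f, drop = FALSE], 1, max)
      v_drift <- vapply(c_eff, bp$drift_gain, numeric(1))

      heading <- heading + stats::rnorm(n, 0, sqrt(bp$heading_diffusion * dt))
      ux <- (port[1] - x) / pmax(dist, 1e-9)
      uy <- (port[2] - y) / pmax(dist, 1e-9)
      x_new <- x + dt * (bp$base_speed * cos(heading) + v_drift * ux)
      y_new <- y + dt * (bp$base_speed * sin(heading) + v_drift * uy)

      r_new <- sqrt(x_new^2 + y_new^2)
      hit <- r_new > radius
      if (any(hit)) {
        scale <- pmax(2 * radius - r_new[hit], 0) / r_new[hit]
        x_new[hit] <- x_new[hit] * scale
        y_new[hit] <- y_new[hit] * scale
        heading[hit] <- heading[hit] + pi
        # very large excursions (should not happen at walking speeds): clamp
        r_chk <- sqrt(x_new[hit]^2 + y_new[hit]^2)
        bad <- r_chk > radius
        if (any(bad)) {
          idx <- which(hit)[bad]
          x_new[idx] <- x_new[idx] * radius / r_chk[bad]
          y_new[idx] <- y_new[idx] * radius / r_chk[bad]
        }
      }
      x <- x_new
      y <- y_new
      traj_x[, f + 1] <- x
      traj_y[, f + 1] <- y
    }

    trajectories <- tibble::tibble(
      fly_id = rep(seq_len(n), each = n_frames),
      frame = rep(seq_len(n_frames), n),
      x_cm = as.vector(t(traj_x)),
      y_cm = as.vector(t(traj_y))
    )

    det <- trajectories[c("frame", "x_cm", "y_cm")]
    if (detection_noise_sd > 0) {
      det$x_cm <- det$x_cm + stats::rnorm(nrow(det), 0, detection_noise_sd)
      det$y_cm <- det$y_cm + stats::rnorm(nrow(det), 0, detection_noise_sd)
    }
    if (dropout_prob > 0) {
      det <- det[stats::runif(nrow(det)) >= dropout_prob, ]
    }
    det <- dplyr::arrange(det, .data$frame)

    list(trajectories = trajectories, detections = tibble::as_tibble(det))
  })
}
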