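# internal: constant-velocity Kalman matrices for one 2-D target
kf_matrices <- function(dt, q_process, r_meas) {
  FF <- diag(4)
  FF[1, 3] <- dt
  FF[2, 4] <- dt
  # white-acceleration process noise, per axis
  q2 <- matrix(c(dt^3 / 3, dt^2 / 2, dt^2 / 2, dt), 2, 2) * q_process
  Q <- matrix(0, 4, 4)
  Q[c(1, 3), c(1, 3)] <- q2
  Q[c(2, 4), c(2, 4)] <- q2
  H <- matrix(0, 2, 4)
  H[1, 1] <- 1
  H[2, 2] <- 1
  R <- diag(2) * r_meas^2
  list(FF = FF, Q = Q, H = H, R = R)
}

#' Track flies across frames with a constant-velocity Kalman filter
#'
#' Per frame: every live track is predicted one step ahead, detections are
#' assigned to predicted positions by greedy nearest neighbor within a gate
#' (distance ties broken by the lower track id), assigned tracks are updated,
#' unassigned tracks coast up to `max_missed` frames before terminating, and
#' unassigned detections seed new tracks. A new track must accrue
#' `min_hits` consecutive detections before it is confirmed and reported.
#'
#' @param detections A tibble of per-frame detections: `frame`, `x_cm`,
#'   `y_cm` (identity-free).
#' @param frame_rate Frames per second. Default 30.
#' @param q_process Process-noise intensity (white acceleration), cm^2/s^3.
#' @param r_meas Measurement noise SD, cm.
#' @param gate_cm Assignment gate radius, cm.
#' @param max_missed Coasting frames before a track terminates. Default 2.
#' @param min_hits Consecutive detections required to confirm a track.
#'   Default 3.
#'
#' @return A trajectory tibble: `fly_id`, `frame`, `x_cm`, `y_cm` (filtered
#'   estimates), `x_obs`, `y_obs` (assigned detection, `NA` while coasting).
#' @export
kalman_track <- function(detections, frame_rate = 30, q_process = 10,
                         r_meas = 0.05, gate_cm = 0.5, max_missed = 2,
                         min_hits = 3) {
  stopifnot(all(c("frame", "x_cm", "y_cm") %in% names(detections)))
  mats <- kf_matrices(1 / frame_rate, q_process, r_meas)
  FF <- mats$FF; Q <- mats$Q; H <- mats$H; R <- mats$R

  tracks <- list()
  finished <- list()
  next_id <- 1L
  frames <- seq(min(detections$frame), max(detections$frame))

  for (f in frames) {
    dets <- detections[detections$frame == f, c("x_cm", "y_cm"), drop = FALSE]
    n_det <- nrow(dets)

    # predict
    for (k in seq_along(tracks)) {
      tr <- tracks[[k]]
      tr$state <- FF %*% tr$state
      tr$P <- FF %*% tr$P %*% t(FF) + Q
      tracks[[k]] <- tr
    }

    # greedy nearest-neighbor assignment within the gate
    det_taken <- rep(FALSE, n_det)
    trk_assigned <- rep(FALSE, length(tracks))
    if (n_det > 0 && length(tracks) > 0) {
      pred <- t(vapply(tracks, function(tr) tr$state[1:2, 1], numeric(2)))
      dd <- sqrt(outer(pred[, 1], dets$x_cm, "-")^2 +
                 outer(pred[, 2], dets$y_cm, "-")^2)
      ids <- vapply(tracks, function(tr) tr$id, integer(1))
      pairs <- which(dd <= gate_cm, arr.ind = TRUE)
      if (nrow(pairs) > 0) {
        ord <- order(dd[pairs], ids[pairs[, 1]])
        for (p in ord) {
          ti <- pairs[p, 1]; di <- pairs[p, 2]
          if (trk_assigned[ti] || det_taken[di]) next
          trk_assigned[ti] <- TRUE
          det_taken[di] <- TRUE
          tr <- tracks[[ti]]
          z <- matrix(c(dets$x_cm[di], dets$y_cm[di]), 2, 1)
          S <- H %*% tr$P %*% t(H) + R
          K <- tr$P %*% t(H) %*% solve(S)
          tr$state <- tr$state + K %*% (z - H %*% tr$state)
          tr$P <- (diag(4) - K %*% H) %*% tr$P
          tr$missed <- 0L
          tr$hits <- tr$hits + 1L
          tr$history <- rbind(tr$history,
            c(f, tr$state[1], tr$state[2], z[1], z[2]))
          tracks[[ti]] <- tr
        }
      }
    }

    # unassigned tracks: coast or terminate; unconfirmed tracks die on a miss
    drop <- logical(length(tracks))
    for (k in seq_along(tracks)) {
      if (trk_assigned[k]) next
      tr <- tracks[[k]]
      if (tr$hits < min_hits) {
        drop[k] <- TRUE
        next
      }
      tr$missed <- tr$missed + 1L
      if (tr$missed > max_missed) {
        finished[[length(finished) + 1]] <- tr
        drop[k] <- TRUE
      } else {
        tr$history <- rbind(tr$history, c(f, tr$state[1], tr$state[2], NA, NA))
        tracks[[k]] <- tr
      }
    }
    tracks <- tracks[!drop]

    # unassigned detections seed new tracks
    if (n_det > 0) {
      for (di in which(!det_taken)) {
        tr <- list(
          id = next_id,
          state = matrix(c(dets$x_cm[di], dets$y_cm[di], 0, 0), 4, 1),
          P = diag(c(r_meas^2 + 1e-4, r_meas^2 + 1e-4, 4, 4)),
          missed = 0L, hits = 1L,
          history = matrix(c(f, dets$x_cm[di], dets$y_cm[di],
                             dets$x_cm[di], dets$y_cm[di]), 1, 5)
        )
        next_id <- next_id + 1L
        tracks[[length(tracks) + 1]] <- tr
      }
    }
  }
  finished <- c(finished, tracks)
  confirmed <- Filter(function(tr) tr$hits >= min_hits, finished)
  if (!length(confirmed)) {
    return(tibble::tibble(fly_id = integer(0), frame = integer(0),
                          x_cm = numeric(0), y_cm = numeric(0),
                          x_obs = numeric(0), y_obs = numeric(0)))
  }
  out <- purrr::map_dfr(confirmed, function(tr) {
    h <- tr$history
    tibble::tibble(
      fly_id = tr$id, frame = as.integer(h[, 1]),
      x_cm = h[, 2], y_cm = h[, 3], x_obs = h[, 4], y_obs = h[, 5]
    )
  })
  # drop trailing coasted samples of terminated tracks, renumber ids densely
  out <- dplyr::arrange(out, .data$fly_id, .data$frame)
  out$fly_id <- as.integer(factor(out$fly_id))
  out
}

resolve_port <- function(port) {
  if (inherits(port, "arena_config")) {
    unname(port$port_positions[port$active_port, ])
  } else {
    stopifnot(is.numeric(port), length(port) == 2)
    unname(port)
  }
}

#' Distance of each trajectory sample from the odor port
#'
#' @param traj A trajectory tibble (`fly_id`, `frame`, `x_cm`, `y_cm`).
#' @param port Either an [arena_config()] (its active port is used) or a
#'   numeric `c(x_cm, y_cm)` on the arena boundary.
#'
#' @return The trajectory tibble with a `distance_cm` column appended.
#' @export
distance_to_port <- function(traj, port) {
  p <- resolve_port(port)
  dplyr::mutate(tibble::as_tibble(traj),
    distance_cm = sqrt((.data$x_cm - p[1])^2 + (.data$y_cm - p[2])^2)
  )
}

#' Displacement toward the odor port since odor onset
#'
#' Computes `delta_d = d0 - d_t` per fly, where `d0` is the distance from
#' the port at the odor-onset frame: positive values reflect movement toward
#' the port (attraction), negative values movement away (avoidance).
#'
#' @param traj_dist A trajectory tibble with a `distance_cm` column (see
#'   [distance_to_port()]).
#' @param onset_frame Frame index of odor onset.
#'
#' @return The tibble with `d0_cm` and `delta_d_cm` columns appended.
#' @export
delta_d <- function(traj_dist, onset_frame) {
  stopifnot("distance_cm" %in% names(traj_dist))
  grp <- if ("fly_id" %in% names(traj_dist)) "fly_id" else character(0)
  traj_dist |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(
      d0_cm = .data$distance_cm[.data$frame == onset_frame][1],
      delta_d_cm = .data$d0_cm - .data$distance_cm
    ) |>
    dplyr::ungroup()
}

#' Binned mean distance from the odor port over time
#'
#' Samples each fly's distance from the port every `bin_s` seconds (15 frames
#' at 30 fps) for `total_s` seconds — 70 bins for the standard 35 s analysis
#' of 10 s odor pulses — and averages over flies per bin.
#'
#' @param traj A trajectory tibble.
#' @param port As in [distance_to_port()].
#' @param bin_s Bin width, seconds. Default 0.5.
#' @param total_s Analysis span, seconds. Default 35.
#' @param frame_rate Frames per second. Default 30.
#' @param start_frame Frame of the first bin sample. Default 1.
#'
#' @return A tibble: `bin`, `time_s`, `mean_distance_cm`, `sem_cm`, `n_flies`.
#' @export
mean_distance_timecourse <- function(traj, port, bin_s = 0.5, total_s = 35,
                                     frame_rate = 30, start_frame = 1) {
  n_bins <- floor(total_s / bin_s)
  step <- round(bin_s * frame_rate)
  bin_frames <- start_frame + (seq_len(n_bins) - 1) * step
  have <- bin_frames <= max(traj$frame)
  if (!all(have)) {
    warning("trajectories cover only ", sum(have), " of ", n_bins,
            " bins; truncating", call. = FALSE)
    bin_frames <- bin_frames[have]
  }
  td <- distance_to_port(traj, port)
  td <- td[td$frame %in% bin_frames, ]
  td$bin <- match(td$frame, bin_frames)
  td |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      time_s = (bin_frames[.data$bin[1]] - start_frame) / frame_rate,
      mean_distance_cm = mean(.data$distance_cm),
      sem_cm = stats::sd(.data$distance_cm) / sqrt(dplyr::n()),
      n_flies = dplyr::n(),
      .groups = "drop"
    )
}

#' Signed radial velocity relative to the odor port
#'
#' Radial displacement over a time window divided by its length; positive
#' values mean movement away from the port. Pure tangential motion scores 0.
#' Path speed along the trajectory is available as an alternative.
#'
#' @param traj A trajectory tibble (one or more flies).
#' @param port As in [distance_to_port()].
#' @param window `c(t0, t1)` in seconds, with `t = (frame - 1) / frame_rate`.
#' @param frame_rate Frames per second. Default 30.
#' @param measure `"radial"` (default) or `"path"` (path length / duration,
#'   always >= 0).
#'
#' @return A tibble with one row per fly: `fly_id`, `v_cm_s`.
#' @export
radial_velocity <- function(traj, port, window, frame_rate = 30,
                            measure = c("radial", "path")) {
  measure <- match.arg(measure)
  if (diff(window) <= 0) stop("window must have positive length", call. = FALSE)
  f0 <- round(window[1] * frame_rate) + 1
  f1 <- round(window[2] * frame_rate) + 1
  td <- distance_to_port(traj, port)
  if (!("fly_id" %in% names(td))) td$fly_id <- 1L
  if (!all(c(f0, f1) %in% td$frame)) {
    stop("window falls outside the trajectory frames", call. = FALSE)
  }
  td |>
    dplyr::filter(.data$frame >= f0, .data$frame <= f1) |>
    dplyr::group_by(.data$fly_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::summarise(
      v_cm_s = if (measure == "radial") {
        (.data$distance_cm[dplyr::n()] - .data$distance_cm[1]) /
          ((f1 - f0) / frame_rate)
      } else {
        sum(sqrt(diff(.data$x_cm)^2 + diff(.data$y_cm)^2)) /
          ((f1 - f0) / frame_rate)
      },
      .groups = "drop"
    )
}

#' Postpulse kinetics stratified by initial distance
#'
#' For 1 s pulse experiments: each fly's signed radial velocity in successive
#' postpulse windows (default 0-1, 1-2, 2-3 and 3-4 s after odor offset),
#' stratified by the fly's distance from the port at odor onset (near:
#' `<= strata_cm`, default 3 cm; far otherwise).
#'
#' @param traj A trajectory tibble covering onset to onset + `track_span_s`.
#' @param port As in [distance_to_port()].
#' @param pulse An [odor_pulse_spec()].
#' @param windows List of `c(t0, t1)` windows in seconds after odor offset.
#' @param strata_cm Initial-distance stratification threshold, cm. Default 3.
#' @param frame_rate Frames per second. Default 30.
#' @param track_span_s Required trajectory span after onset, seconds.
#'   Default 4.5.
#'
#' @return A tibble with one row per fly per window: `fly_id`, `d0_cm`,
#'   `stratum` (`"near"`/`"far"`), `window`, `t0_s`, `t1_s`, `v_cm_s`
#'   (positive = away from the port).
#' @export
postpulse_kinetics <- function(traj, port, pulse,
                               windows = list(c(0, 1), c(1, 2), c(2, 3), c(3, 4)),
                               strata_cm = 3, frame_rate = 30,
                               track_span_s = 4.5) {
  offset_s <- pulse$onset_s + pulse$duration_s
  need_end <- (pulse$onset_s + track_span_s) * frame_rate + 1
  if (max(traj$frame) < floor(need_end) - 1) {
    stop("trajectories must span onset to onset + ", track_span_s, " s",
         call. = FALSE)
  }
  onset_frame <- round(pulse$onset_s * frame_rate) + 1
  d0 <- traj |>
    distance_to_port(port) |>
    dplyr::filter(.data$frame == onset_frame) |>
    dplyr::select("fly_id", d0_cm = "distance_cm")
  purrr::map_dfr(seq_along(windows), function(i) {
    w <- windows[[i]]
    v <- radial_velocity(traj, port,
                         window = offset_s + w, frame_rate = frame_rate)
    v$window <- paste0(w[1], "-", w[2], " s")
    v$t0_s <- offset_s + w[1]
    v$t1_s <- offset_s + w[2]
    v
  }) |>
    dplyr::inner_join(d0, by = "fly_id") |>
    dplyr::mutate(stratum = ifelse(.data$d0_cm <= strata_cm, "near", "far")) |>
    dplyr::select("fly_id", "d0_cm", "stratum", "window", "t0_s", "t1_s",
                  "v_cm_s")
}

#' Group statistics for a kinetics table
#'
#' Mean, SEM and n per stratum and window. Strata absent from the table
#' appear with `n = 0` and `NA` statistics so missing groups are explicit.
#'
#' @param kinetics Output of [postpulse_kinetics()].
#' @return A tibble: `stratum`, `window`, `n`, `mean_v_cm_s`, `sem_v_cm_s`.
#' @export
kinetics_group_stats <- function(kinetics) {
  stats_tbl <- kinetics |>
    dplyr::group_by(.data$stratum, .data$window) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_v_cm_s = mean(.data$v_cm_s),
      sem_v_cm_s = stats::sd(.data$v_cm_s) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  tidyr::complete(stats_tbl,
    stratum = c("near", "far"),
    window = unique(kinetics$window),
    fill = list(n = 0L)
  )
}

#' Net displacement toward the port at the end of a pulse
#'
#' `delta_d` evaluated at the pulse-end frame for every fly, with the group
#' mean and SEM: the net-distance-moved summary for long (10 s) pulses.
#'
#' @param traj A trajectory tibble.
#' @param port As in [distance_to_port()].
#' @param pulse An [odor_pulse_spec()].
#' @param frame_rate Frames per second. Default 30.
#'
#' @return A list: `per_fly` (tibble `fly_id`, `delta_d_cm`) and `group`
#'   (one-row tibble `mean_cm`, `sem_cm`, `n`).
#' @export
net_displacement <- function(traj, port, pulse, frame_rate = 30) {
  onset_frame <- round(pulse$onset_s * frame_rate) + 1
  end_frame <- round((pulse$onset_s + pulse$duration_s) * frame_rate) + 1
  per_fly <- traj |>
    distance_to_port(port) |>
    delta_d(onset_frame) |>
    dplyr::filter(.data$frame == end_frame) |>
    dplyr::select("fly_id", "delta_d_cm")
  group <- tibble::tibble(
    mean_cm = mean(per_fly$delta_d_cm),
    sem_cm = stats::sd(per_fly$delta_d_cm) / sqrt(nrow(per_fly)),
    n = nrow(per_fly)
  )
  list(per_fly = per_fly, group = group)
}
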