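test_that("tracking noiseless well-separated flies is exact with no identity swaps", {
  arena <- arena_config()
  bp <- behavior_params(base_speed = 0.5, heading_diffusion = 1,
                        drift_gain = function(c) 0)
  # seed chosen so the four flies keep a mutual separation > 3x the gate
  sim <- simulate_flies(4, arena, bp, odor_pulse_spec(peak = 1),
                        total_s = 3, seed = 12)
  sep <- sim$trajectories |>
    dplyr::group_by(frame) |>
    dplyr::summarise(ms = min(dist(cbind(x_cm, y_cm))), .groups = "drop")
  expect_gt(min(sep$ms), 3 * 0.5)
  tracks <- kalman_track(sim$detections, r_meas = 1e-3, gate_cm = 0.5)
  expect_equal(length(unique(tracks$fly_id)), 4)
  expect_equal(nrow(tracks), nrow(sim$trajectories))
  # each recovered track reproduces exactly one ground-truth fly
  for (id in unique(tracks$fly_id)) {
    tk <- tracks[tracks$fly_id == id, ]
    gt0 <- sim$trajectories[sim$trajectories$frame == tk$frame[1] &
                            abs(sim$trajectories$x_cm - tk$x_obs[1]) < 1e-12, ]
    gt <- sim$trajectories[sim$trajectories$fly_id == gt0$fly_id[1], ]
    expect_equal(tk$x_obs, gt$x_cm)
    expect_equal(tk$y_obs, gt$y_cm)
    # filtered estimates converge onto the noiseless detections
    expect_lt(max(abs(tk$x_cm - gt$x_cm)), 1e-4)
  }
})

test_that("the filter beats the measurement noise on a static target", {
  set.seed(5)
  sigma <- 0.1
  det <- tibble::tibble(frame = 1:300,
                        x_cm = 1 + rnorm(300, 0, sigma),
                        y_cm = 2 + rnorm(300, 0, sigma))
  tracks <- kalman_track(det, q_process = 0.01, r_meas = sigma, gate_cm = 1)
  est <- tracks[tracks$frame > 100, ]
  rmse <- sqrt(mean((est$x_cm - 1)^2 + (est$y_cm - 2)^2))
  expect_lt(rmse, sigma)
})

test_that("short detection gaps are bridged by coasting", {
  det <- tibble::tibble(frame = 1:30, x_cm = seq(0, 1, length.out = 30), y_cm = 0)
  det <- det[!det$frame %in% c(15, 16), ]
  tracks <- kalman_track(det, r_meas = 0.01, gate_cm = 0.5, max_missed = 2)
  expect_equal(length(unique(tracks$fly_id)), 1)
  expect_equal(nrow(tracks), 30)
  expect_equal(sum(is.na(tracks$x_obs)), 2)
})

test_that("distance to port is plain Euclidean geometry", {
  arena <- arena_config()
  port <- unname(arena$port_positions[1, ])  # (5, 0)
  traj <- tibble::tibble(fly_id = 1, frame = 1:3,
                         x_cm = c(port[1], 0, 1), y_cm = c(port[2], 0, 2))
  d <- distance_to_port(traj, arena)$distance_cm
  expect_equal(d[1], 0)
  expect_equal(d[2], 5)
  expect_equal(d[3], sqrt((5 - 1)^2 + 2^2))
})

test_that("delta_d is d0 minus d_t with attraction positive", {
  traj <- tibble::tibble(fly_id = 1, frame = 1:3, x_cm = c(0, 2, 0),
                         y_cm = 0)
  dd <- delta_d(distance_to_port(traj, c(5, 0)), onset_frame = 1)
  expect_equal(dd$d0_cm, rep(5, 3))
  expect_equal(dd$delta_d_cm, c(0, 2, 0))  # moving toward the port: positive
  # stationary fly: zero everywhere
  still <- tibble::tibble(fly_id = 1, frame = 1:5, x_cm = 1, y_cm = 1)
  expect_equal(delta_d(distance_to_port(still, c(5, 0)), 1)$delta_d_cm, rep(0, 5))
})

test_that("the 35 s distance timecourse has 70 half-second bins", {
  n_frames <- 35 * 30 + 1
  traj <- tibble::tibble(fly_id = 1, frame = 1:n_frames, x_cm = 0, y_cm = 0)
  tc <- mean_distance_timecourse(traj, c(5, 0))
  expect_equal(nrow(tc), 70)
  expect_equal(tc$mean_distance_cm, rep(5, 70))
  # matches direct per-bin averaging over a two-fly population
  traj2 <- dplyr::bind_rows(
    traj,
    tibble::tibble(fly_id = 2, frame = 1:n_frames,
                   x_cm = seq(0, 3, length.out = n_frames), y_cm = 0)
  )
  tc2 <- mean_distance_timecourse(traj2, c(5, 0))
  frames <- 1 + (0:69) * 15
  oracle <- vapply(frames, function(f) {
    rows <- traj2[traj2$frame == f, ]
    mean(sqrt((rows$x_cm - 5)^2 + rows$y_cm^2))
  }, numeric(1))
  expect_equal(tc2$mean_distance_cm, oracle)
  expect_warning(mean_distance_timecourse(traj[1:100, ], c(5, 0)), "truncating")
})

test_that("radial velocity is signed displacement away from the port", {
  fr <- 30
  frames <- 1:61  # 2 s
  # moving radially away from port (5,0) at 1 cm/s starting from the center
  t <- (frames - 1) / fr
  away <- tibble::tibble(fly_id = 1, frame = frames, x_cm = 5 - 5 - t, y_cm = 0)
  v <- radial_velocity(away, c(5, 0), window = c(0, 2), frame_rate = fr)
  expect_equal(v$v_cm_s, 1, tolerance = 1e-9)
  # pure tangential motion on a circle about the port scores zero
  ang <- t / 3
  circ <- tibble::tibble(fly_id = 1, frame = frames,
                         x_cm = 5 - 3 * cos(ang), y_cm = 3 * sin(ang))
  v2 <- radial_velocity(circ, c(5, 0), window = c(0, 2), frame_rate = fr)
  expect_equal(v2$v_cm_s, 0, tolerance = 1e-9)
  expect_error(radial_velocity(away, c(5, 0), window = c(1, 1)), "positive")
})

test_that("postpulse kinetics stratify by initial distance and match direct averaging", {
  arena <- arena_config()
  bp <- behavior_params(drift_gain = function(c) -1.2 * c, persistence_s = 0.5)
  pulse <- odor_pulse_spec(onset_s = 1, duration_s = 1, peak = 3)
  sim <- simulate_flies(30, arena, bp, pulse, total_s = 6, seed = 3)
  kin <- postpulse_kinetics(sim$trajectories, arena, pulse)
  expect_equal(nrow(kin), 30 * 4)
  expect_true(all(kin$stratum[kin$d0_cm <= 3] == "near"))
  expect_true(all(kin$stratum[kin$d0_cm > 3] == "far"))
  # window velocity equals the direct finite-difference oracle
  td <- distance_to_port(sim$trajectories, arena)
  w <- c(3, 4)  # 1-2 s after the 1 s pulse ends at t = 2
  f0 <- round(w[1] * 30) + 1
  f1 <- round(w[2] * 30) + 1
  oracle <- td |>
    dplyr::filter(frame %in% c(f0, f1)) |>
    dplyr::group_by(fly_id) |>
    dplyr::summarise(v = diff(distance_cm) / 1, .groups = "drop")
  got <- kin[kin$window == "1-2 s", ]
  expect_equal(got$v_cm_s[order(got$fly_id)], oracle$v[order(oracle$fly_id)])
  # group statistics aggregate the per-fly rows exactly
  gs <- kinetics_group_stats(kin)
  near12 <- kin$v_cm_s[kin$stratum == "near" & kin$window == "1-2 s"]
  expect_equal(gs$mean_v_cm_s[gs$stratum == "near" & gs$window == "1-2 s"],
               mean(near12))
  expect_equal(gs$n[gs$stratum == "near" & gs$window == "1-2 s"], length(near12))
})

test_that("kinetics are invariant under rotating the arena with its port", {
  arena <- arena_config()
  bp <- behavior_params(drift_gain = function(c) -1.2 * c)
  pulse <- odor_pulse_spec(onset_s = 1, duration_s = 1, peak = 2)
  sim <- simulate_flies(10, arena, bp, pulse, total_s = 6, seed = 5)
  traj <- sim$trajectories
  theta <- 2 * pi / 7
  rot <- traj
  rot$x_cm <- cos(theta) * traj$x_cm - sin(theta) * traj$y_cm
  rot$y_cm <- sin(theta) * traj$x_cm + cos(theta) * traj$y_cm
  port <- arena$port_positions[1, ]
  port_rot <- c(cos(theta) * port[1] - sin(theta) * port[2],
                sin(theta) * port[1] + cos(theta) * port[2])
  dd <- delta_d(distance_to_port(traj, port), 31)
  dd_rot <- delta_d(distance_to_port(rot, port_rot), 31)
  expect_equal(dd_rot$delta_d_cm, dd$delta_d_cm, tolerance = 1e-10)
  v <- radial_velocity(traj, port, c(2, 3))
  v_rot <- radial_velocity(rot, port_rot, c(2, 3))
  expect_equal(v_rot$v_cm_s, v$v_cm_s, tolerance = 1e-10)
})

test_that("net displacement at pulse end summarizes per-fly delta_d", {
  pulse <- odor_pulse_spec(onset_s = 1, duration_s = 2, peak = 1)
  still <- tidyr::expand_grid(fly_id = 1:5, frame = 1:121) |>
    dplyr::mutate(x_cm = fly_id / 2, y_cm = 0)
  nd <- net_displacement(still, c(5, 0), pulse)
  expect_equal(nd$group$mean_cm, 0)
  expect_equal(nd$group$sem_cm, 0)
  # consistency with delta_d at the pulse-end frame
  moving <- tibble::tibble(fly_id = 1, frame = 1:121,
                           x_cm = seq(0, 2, length.out = 121), y_cm = 0)
  nd2 <- net_displacement(moving, c(5, 0), pulse)
  dd <- delta_d(distance_to_port(moving, c(5, 0)), 31)
  expect_equal(nd2$per_fly$delta_d_cm, dd$delta_d_cm[dd$frame == 91])
})
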