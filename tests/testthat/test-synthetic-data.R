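test_that("scripted trajectories have the scripted shape", {
  # zero amplitude degenerates to a constant baseline
  s0 <- motion_script("H-ABD-FR-1", amplitude = 0, baseline_angle = 12)
  t0 <- generate_angle_trajectory(s0, 30)
  expect_true(all(t0$angle_deg == 12))

  # 90 degrees, 0.5 Hz, 5 repetitions at 180 Hz: 5 peaks reaching
  # baseline + amplitude exactly (peaks fall on the sampling grid)
  s <- motion_script("K-FLEX-FR-1", amplitude = 90, frequency = 0.5,
                     n_repetitions = 5, baseline_angle = 10)
  tr <- generate_angle_trajectory(s, 180)
  expect_lt(abs(max(tr$angle_deg) - 100), 1e-9)
  expect_gte(min(tr$angle_deg), 10)
  seg <- detect_peaks(tr)
  expect_length(seg$peaks, 5)

  # the same underlying function sampled at 30 and 180 Hz agrees at the
  # shared timestamps
  lo <- generate_angle_trajectory(s, 30)
  hi <- generate_angle_trajectory(s, 180)
  shared <- match(round(lo$time_s, 9), round(hi$time_s, 9))
  expect_false(anyNA(shared))
  expect_equal(lo$angle_deg, hi$angle_deg[shared], tolerance = 1e-12)

  # sampling below the Nyquist rate of the movement is rejected
  expect_error(generate_angle_trajectory(s, 0.9), class = "kv_below_nyquist")
  expect_error(motion_script("K-FLEX-FR-1", frequency = 2), class = "kv_bad_script")
  expect_error(motion_script("K-FLEX-FR-1", duration = 3), class = "kv_bad_script")
})

test_that("forward kinematics preserves rigid segments and inverts the angle computation", {
  tpl <- default_skeleton_template()
  script <- motion_script("S-FLEX-IN-1", amplitude = 80, baseline_angle = 15)
  traj <- generate_angle_trajectory(script, 30)
  stream <- forward_kinematics(tpl, traj, "S-FLEX-IN")
  df <- as.data.frame(stream)

  seg_len <- function(a, b) {
    pa <- df[df$joint == a, c("x_m", "y_m", "z_m")]
    pb <- df[df$joint == b, c("x_m", "y_m", "z_m")]
    sqrt(rowSums((pa - pb)^2))
  }
  # every segment of the moving chain keeps its template length in every frame
  expect_lt(max(abs(seg_len("shoulder_right", "elbow_right") - 0.28)), 1e-9)
  expect_lt(max(abs(seg_len("elbow_right", "wrist_right") - 0.26)), 1e-9)

  # at the baseline angle 0 the moving vector is parallel to the reference axis
  s0 <- motion_script("S-ABD-FR-1", amplitude = 0, baseline_angle = 0)
  st0 <- forward_kinematics(tpl, generate_angle_trajectory(s0, 30), "S-ABD-FR")
  m <- as.matrix(st0[st0$frame == 0, c("x_m", "y_m", "z_m")])
  rownames(m) <- st0$joint[st0$frame == 0]
  b <- build_body_basis(m, "upper")
  v <- to_body_coords(m["elbow_right", ] - m["shoulder_right", ], b)
  v <- v / sqrt(sum(v^2))
  expect_equal(v, c(0, -1, 0), tolerance = 1e-9)

  # round trip: the computed angle series reproduces the script
  req <- angle_request("shoulder_right", "elbow_right", "sagittal")
  back <- compute_angle_series(stream, req, "upper")
  expect_lt(max(abs(back$angle_deg - traj$angle_deg)), 1e-6)

  expect_error(forward_kinematics(tpl, traj, "K-ABD-FR"),
               class = "kv_unknown_movement")
})

test_that("the virtual camera renders noiseless streams verbatim and noisy ones reproducibly", {
  tpl <- default_skeleton_template()
  traj <- generate_angle_trajectory(motion_script("E-FLEX-FR-1"), 30)
  stream <- forward_kinematics(tpl, traj, "E-FLEX-FR")

  # identity configuration: zero noise, zero orientation
  cfg0 <- simulation_config(position_noise_sd = 0, camera_orientation = 0)
  r0 <- render_sensor_stream(stream, cfg0)
  expect_equal(r0$stream$x_m, stream$x_m)
  expect_equal(r0$stream$y_m, stream$y_m)
  expect_equal(r0$stream$z_m, stream$z_m)
  expect_equal(nrow(r0$rejected), 0)

  # identical seeds give bit-identical noisy streams; different seeds differ
  cfg1 <- simulation_config(position_noise_sd = 0.005, seed = 99)
  ra <- render_sensor_stream(stream, cfg1)
  rb <- render_sensor_stream(stream, cfg1)
  expect_identical(ra$stream$x_m, rb$stream$x_m)
  rc <- render_sensor_stream(stream, simulation_config(position_noise_sd = 0.005,
                                                       seed = 100))
  expect_false(identical(ra$stream$x_m, rc$stream$x_m))

  # a landmark projected to the principal point lies on the optical axis
  k <- default_intrinsics()
  w <- backproject(k$xo, k$yo, 2, k)
  expect_equal(c(w$xw, w$yw), c(0, 0))

  # rendered 2D + depth back-projects onto the rendered 3D joints
  b <- backproject(ra$landmarks$xp, ra$landmarks$yp, ra$depth$z_m, k)
  expect_lt(max(abs(b$xw - ra$stream$x_m)), 1e-6)
  expect_lt(max(abs(b$yw - ra$stream$y_m)), 1e-6)

  # 30-degree orientation is a rigid vertical-axis rotation: angles unchanged
  cfg30 <- simulation_config(position_noise_sd = 0, camera_orientation = 30)
  r30 <- render_sensor_stream(stream, cfg30)
  req <- angle_request("elbow_right", "wrist_right", "sagittal")
  a0 <- compute_angle_series(stream, req, "upper")
  a30 <- compute_angle_series(r30$stream, req, "upper")
  expect_lt(max(abs(a30$angle_deg - a0$angle_deg)), 1e-6)

  # frames with a joint at or behind the camera plane are rejected and logged
  near <- forward_kinematics(tpl, traj, "E-FLEX-FR", root_position = c(0, 0, 0.1))
  rn <- render_sensor_stream(near, simulation_config(position_noise_sd = 0))
  expect_gt(nrow(rn$rejected), 0)
  expect_match(rn$rejected$reason[1], "behind camera")
})

test_that("a 30 Hz sampling keeps one peak per repetition for movements at or below 1 Hz", {
  for (freq in c(0.25, 0.5, 1)) {
    s <- motion_script("H-FLEX-IN-1", frequency = freq, n_repetitions = 5)
    tr <- generate_angle_trajectory(s, 30)
    expect_length(detect_peaks(tr)$peaks, 5)
  }
})
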