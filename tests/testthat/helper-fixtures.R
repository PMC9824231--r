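# Fixtures are built in code; nothing is read from disk except the bundled
# reference tables.

# canonical upright pose facing the camera, in the sensor frame (y down)
canonical_frame <- function(distance = 2.5) {
  tpl <- default_skeleton_template()
  ang <- angle_series(10, rate = 1)
  # a single constant-angle frame through the forward model, then reshape
  st <- forward_kinematics(tpl, ang, "S-ABD-FR", root_position = c(0, 0, distance))
  m <- as.matrix(st[, c("x_m", "y_m", "z_m")])
  rownames(m) <- st$joint
  m
}

# random proper rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_res <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_res)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

apply_rigid <- function(frame, R, t = c(0, 0, 0)) {
  sweep(frame %*% t(R), 2, t, `+`)
}

test_intrinsics <- function() {
  camera_intrinsics(f = 500, xo = 320, yo = 240, width = 640, height = 480)
}

# one dual-rate zero-noise recording passed through the conditioning chain
clean_dual_rate_recording <- function(movement = "S-ABD-FR", amplitude = 60) {
  script <- motion_script(paste0(movement, "-1"), amplitude = amplitude)
  tpl <- default_skeleton_template()
  prof_req <- angle_request("shoulder_right", "elbow_right", "frontal")
  gold <- compute_angle_series(
    forward_kinematics(tpl, generate_angle_trajectory(script, 180), movement),
    prof_req, "upper")
  sens <- compute_angle_series(
    forward_kinematics(tpl, generate_angle_trajectory(script, 30), movement),
    prof_req, "upper")
  list(gold = smooth_series(gold), sensor = smooth_series(sens), script = script)
}
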