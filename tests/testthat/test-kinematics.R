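test_that("the canonical upright pose yields the identity basis up to the image y-flip", {
  frame <- canonical_frame()
  b <- build_body_basis(frame, "upper")
  # sensor y points down, so the longitudinal body axis is (0, -1, 0); the
  # subject faces the camera, so their right is the image's -x
  expect_equal(b$y, c(0, -1, 0), tolerance = 1e-9)
  expect_equal(b$x, c(-1, 0, 0), tolerance = 1e-9)
  expect_equal(b$z, c(0, 0, 1), tolerance = 1e-9)
  # orthonormal and right-handed
  expect_lt(max(abs(crossprod(b$B) - diag(3))), 1e-9)
  expect_gt(det(b$B), 0)
})

test_that("a rigidly rotated skeleton rotates the basis with it and keeps body coordinates", {
  frame <- canonical_frame()
  b0 <- build_body_basis(frame, "upper")
  v_sc <- frame["elbow_right", ] - frame["shoulder_right", ]
  v0 <- to_body_coords(v_sc, b0)
  set.seed(11)
  for (i in 1:10) {
    R <- random_rotation()
    t <- rnorm(3)
    fr <- apply_rigid(frame, R, t)
    br <- build_body_basis(fr, "upper")
    expect_lt(max(abs(br$B - R %*% b0$B)), 1e-9)
    vr <- to_body_coords(as.numeric(R %*% v_sc), br)
    expect_lt(max(abs(vr - v0)), 1e-9)
  }
})

test_that("degenerate landmark configurations are rejected", {
  frame <- canonical_frame()
  # hips collinear with the spine axis: no mediolateral direction left
  frame["hip_left", ] <- frame["spine_mid", ]
  frame["hip_right", ] <- frame["spine_top", ]
  expect_error(build_body_basis(frame, "upper"), class = "kv_degenerate_basis")

  fr2 <- canonical_frame()
  fr2["spine_top", ] <- fr2["spine_mid", ]
  expect_error(build_body_basis(fr2, "upper"), class = "kv_degenerate_basis")

  expect_error(build_body_basis(canonical_frame()[1:3, ], "upper"),
               class = "kv_missing_joint")
})

test_that("change of basis equals the explicit matrix inverse and preserves norms", {
  frame <- canonical_frame()
  b <- build_body_basis(frame, "lower")
  expect_equal(to_body_coords(b$x, b), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(to_body_coords(b$y, b), c(0, 1, 0), tolerance = 1e-12)
  expect_equal(to_body_coords(b$z, b), c(0, 0, 1), tolerance = 1e-12)
  set.seed(4)
  for (i in 1:25) {
    R <- random_rotation()
    fr <- apply_rigid(frame, R)
    br <- build_body_basis(fr, "upper")
    v <- rnorm(3)
    out <- to_body_coords(v, br)
    expect_lt(abs(sqrt(sum(out^2)) - sqrt(sum(v^2))), 1e-9)
    expect_lt(max(abs(out - solve(br$B) %*% v)), 1e-12)
  }
})

test_that("in-plane angles match their geometric definition and respect the tolerance", {
  frame <- canonical_frame()
  b <- build_body_basis(frame, "upper")
  plane <- anatomical_plane("frontal")

  place_arm <- function(v_bc) {
    fr <- frame
    fr["elbow_right", ] <- fr["shoulder_right", ] + 0.28 * as.numeric(b$B %*% v_bc)
    fr
  }
  req <- angle_request("shoulder_right", "elbow_right", plane, tolerance = 5)

  # parallel to the reference axis (-y in body coordinates): zero degrees
  expect_equal(angle_in_plane(req, place_arm(c(0, -1, 0)), b), 0, tolerance = 1e-9)
  # unit vector at 45 degrees in the frontal plane
  v45 <- c(sin(pi / 4), -cos(pi / 4), 0)
  expect_equal(angle_in_plane(req, place_arm(v45), b), 45, tolerance = 1e-9)
  # tilted 10 degrees out of plane with a 5-degree tolerance: rejected
  v_out <- c(sin(pi / 4) * cos(10 * pi / 180), -cos(pi / 4),
             sin(pi / 4) * sin(10 * pi / 180))
  expect_error(angle_in_plane(req, place_arm(v_out), b), class = "kv_out_of_plane")
  # zero-length moving vector
  fr0 <- frame; fr0["elbow_right", ] <- fr0["shoulder_right", ]
  expect_error(angle_in_plane(req, fr0, b), class = "kv_degenerate_vector")

  # equivalence oracle: in-plane angle equals the atan2 planar angle computed
  # in an independent 2-D projection onto (reference, normal x reference)
  set.seed(8)
  third <- c(1, 0, 0)  # normal x reference for the frontal plane
  for (i in 1:50) {
    th <- runif(1, 0, pi)
    v <- cos(th) * c(0, -1, 0) + sin(th) * third
    got <- angle_in_plane(req, place_arm(v), b)
    planar <- atan2(sum(v * third), sum(v * c(0, -1, 0))) * 180 / pi
    expect_equal(got, planar, tolerance = 1e-9)
  }
})

test_that("angles are invariant under rigid motion of the whole skeleton", {
  script <- motion_script("S-ABD-FR-1", amplitude = 60)
  traj <- generate_angle_trajectory(script, 30)
  stream <- forward_kinematics(default_skeleton_template(), traj, "S-ABD-FR")
  req <- angle_request("shoulder_right", "elbow_right", "frontal")
  a0 <- compute_angle_series(stream, req, "upper")
  set.seed(21)
  R <- random_rotation(); t <- rnorm(3)
  df <- as.data.frame(stream)
  xyz <- as.matrix(df[, c("x_m", "y_m", "z_m")]) %*% t(R)
  df[, c("x_m", "y_m", "z_m")] <- sweep(xyz, 2, t, `+`)
  a1 <- compute_angle_series(skeleton_stream(df, rate = 30), req, "upper")
  expect_lt(max(abs(a1$angle_deg - a0$angle_deg)), 1e-6)
  expect_true(all(a0$angle_deg >= 0 & a0$angle_deg <= 180))
})

test_that("per-frame series computation recovers scripts and conserves gaps", {
  tpl <- default_skeleton_template()
  script <- motion_script("K-FLEX-FR-1", amplitude = 75, baseline_angle = 5)
  traj <- generate_angle_trajectory(script, 30)
  stream <- forward_kinematics(tpl, traj, "K-FLEX-FR")
  req <- angle_request("knee_right", "ankle_right", "sagittal")
  a <- compute_angle_series(stream, req, "lower")
  expect_lt(max(abs(a$angle_deg - traj$angle_deg)), 1e-6)

  # constant pose gives a constant series
  const <- generate_angle_trajectory(
    motion_script("K-FLEX-FR-1", amplitude = 0, baseline_angle = 30), 30)
  ac <- compute_angle_series(forward_kinematics(tpl, const, "K-FLEX-FR"), req, "lower")
  expect_lt(diff(range(ac$angle_deg)), 1e-9)

  # one frame pushed far out of plane becomes exactly one gap
  df <- as.data.frame(stream)
  hit <- df$frame == 50 & df$joint == "ankle_right"
  df$x_m[hit] <- df$x_m[hit] + 5   # mediolateral shift = out of the sagittal plane
  strict <- angle_request("knee_right", "ankle_right", "sagittal", tolerance = 20)
  ag <- compute_angle_series(skeleton_stream(df, rate = 30), strict, "lower")
  expect_equal(sum(!ag$valid), 1)
  expect_false(ag$valid[ag$frame == 50])

  # a stream in which no frame works raises an empty-series error
  df_bad <- as.data.frame(stream)
  df_bad <- df_bad[df_bad$joint != "ankle_right", ]
  expect_error(
    compute_angle_series(skeleton_stream(df_bad, rate = 30), req, "lower"),
    class = "kv_empty_series")
})
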