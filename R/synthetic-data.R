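#' Script for one synthetic monoplanar movement recording
#'
#' Describes a repeated monoplanar joint excursion the way such exercises are
#' actually recorded: `n_repetitions` smooth flexion-and-return cycles at a
#' pace of at most 1 Hz, starting and ending at a baseline angle. The
#' trajectory is a raised cosine per repetition, so the signal leaves and
#' returns to baseline smoothly and has exactly one maximum per repetition —
#' the shape the peak-based segmentation downstream relies on.
#'
#' @param movement_code A movement code string such as `"K-FLEX-FR-1"`
#'   (see [parse_movement_code()]); determines which joints move and in
#'   which anatomical plane.
#' @param amplitude Peak excursion above baseline, degrees (>= 0). The
#'   default of 60 degrees is a mid-range executed amplitude across the
#'   knee/hip/elbow/shoulder movements modelled here.
#' @param frequency Repetition frequency in Hz, in (0, 1].
#' @param n_repetitions Number of repetitions (default 5, one recording's
#'   worth).
#' @param baseline_angle Resting angle from the plane's reference axis,
#'   degrees.
#' @param duration Recording length in seconds; must cover
#'   `n_repetitions / frequency`. Defaults to the movement duration plus a
#'   1 s still baseline on each side.
#' @return An object of class `motion_script`.
#' @export
motion_script <- function(movement_code, amplitude = 60, frequency = 0.5,
                          n_repetitions = 5, baseline_angle = 10,
                          duration = NULL) {
  code <- parse_movement_code(movement_code)
  if (!is.numeric(frequency) || frequency <= 0 || frequency > 1) {
    kv_stop("kv_bad_script", "frequency must be in (0, 1] Hz, got %g", frequency)
  }
  if (amplitude < 0) kv_stop("kv_bad_script", "amplitude must be >= 0")
  if (n_repetitions < 1) kv_stop("kv_bad_script", "need at least one repetition")
  movement_s <- n_repetitions / frequency
  duration <- duration %||% (movement_s + 2)
  if (duration < movement_s) {
    kv_stop("kv_bad_script",
            "duration %.2f s cannot hold %d repetitions at %g Hz (%.2f s)",
            duration, n_repetitions, frequency, movement_s)
  }
  structure(list(movement_code = format(code), code = code,
                 amplitude = amplitude, frequency = frequency,
                 n_repetitions = n_repetitions,
                 baseline_angle = baseline_angle, duration = duration),
            class = "motion_script")
}

#' Simulation configuration for a dual-rate virtual recording
#'
#' Bundles the acquisition-side knobs of the synthetic study: a 180 Hz
#' gold-standard stream against 30 Hz sensor streams, isotropic Gaussian
#' position noise on the 3D landmarks (default 5 mm), a per-stream start
#' offset so synchronization is non-trivial, a per-recording dropout
#' probability to exercise loss accounting, the camera orientation of the
#' subject (0 or 30 degrees about the vertical axis) and the subject's
#' distance to the sensor.
#'
#' @param gold_rate,sensor_rate Sampling rates in Hz; `gold_rate` must
#'   exceed `sensor_rate`.
#' @param position_noise_sd Isotropic landmark noise SD in metres.
#' @param start_offset Start offset of the stream in seconds (delay of the
#'   movement onset within the recording).
#' @param dropout_probability Per-recording probability that the recording
#'   is lost outright.
#' @param camera_orientation Subject rotation about the vertical axis in
#'   degrees (the study setups used 0 and 30).
#' @param subject_distance Distance from camera to subject root, metres.
#' @param seed Optional integer fixing all randomness of the stream.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(gold_rate = 180, sensor_rate = 30,
                              position_noise_sd = 0.005, start_offset = 0,
                              dropout_probability = 0.15,
                              camera_orientation = 0,
                              subject_distance = 2.5, seed = NULL) {
  if (gold_rate <= sensor_rate) {
    kv_stop("kv_bad_config", "gold rate (%g) must exceed sensor rate (%g)",
            gold_rate, sensor_rate)
  }
  stopifnot(sensor_rate > 0, position_noise_sd >= 0, start_offset >= 0,
            dropout_probability >= 0, dropout_probability <= 1,
            subject_distance > 0)
  structure(list(gold_rate = gold_rate, sensor_rate = sensor_rate,
                 position_noise_sd = position_noise_sd,
                 start_offset = start_offset,
                 dropout_probability = dropout_probability,
                 camera_orientation = camera_orientation,
                 subject_distance = subject_distance, seed = seed),
            class = "simulation_config")
}

#' Default skeleton template
#'
#' A landmark-level skeleton (trunk, hips, and the right-side limb chains
#' that the monoplanar movements use, plus their left mirrors) with
#' anthropometric segment lengths in metres. Offsets are expressed in the
#' canonical upright pose facing the camera, in the sensor frame (x right in
#' the image, y down, z away from the camera).
#'
#' @return An object of classes `skeleton_template` and `data.frame` with
#'   columns `joint`, `parent`, `dx`, `dy`, `dz`; parents precede children.
#' @export
default_skeleton_template <- function() {
  df <- data.frame(
    joint = c("pelvis", "hip_left", "hip_right", "spine_mid", "spine_top",
              "shoulder_left", "shoulder_right", "elbow_left", "elbow_right",
              "wrist_left", "wrist_right", "knee_left", "knee_right",
              "ankle_left", "ankle_right"),
    parent = c(NA, "pelvis", "pelvis", "pelvis", "spine_mid",
               "spine_top", "spine_top", "shoulder_left", "shoulder_right",
               "elbow_left", "elbow_right", "hip_left", "hip_right",
               "knee_left", "knee_right"),
    dx = c(0, 0.09, -0.09, 0, 0, 0.18, -0.18, 0, 0, 0, 0, 0, 0, 0, 0),
    dy = c(0, 0, 0, -0.25, -0.25, 0, 0, 0.28, 0.28, 0.26, 0.26,
           0.42, 0.42, 0.40, 0.40),
    dz = rep(0, 15),
    stringsAsFactors = FALSE
  )
  validate_template(df)
  structure(df, class = c("skeleton_template", "data.frame"))
}

validate_template <- function(df) {
  stopifnot(all(c("joint", "parent", "dx", "dy", "dz") %in% names(df)))
  if (anyDuplicated(df$joint)) kv_stop("kv_bad_template", "duplicated joint names")
  non_root <- !is.na(df$parent)
  if (sum(!non_root) != 1) kv_stop("kv_bad_template", "template needs exactly one root")
  # parents must be defined before their children: guarantees acyclicity
  seen <- character(0)
  for (i in seq_len(nrow(df))) {
    p <- df$parent[i]
    if (!is.na(p) && !(p %in% seen)) {
      kv_stop("kv_bad_template", "parent '%s' of '%s' not defined earlier", p, df$joint[i])
    }
    seen <- c(seen, df$joint[i])
  }
  len <- sqrt(df$dx^2 + df$dy^2 + df$dz^2)
  if (any(len[non_root] <= 0)) kv_stop("kv_bad_template", "segment lengths must be > 0")
  invisible(df)
}

## Canonical joint positions of the template as a joints x 3 matrix.
skeleton_pose <- function(template, root_position = c(0, 0, 2.5)) {
  pos <- matrix(NA_real_, nrow = nrow(template), ncol = 3,
                dimnames = list(template$joint, c("x", "y", "z")))
  for (i in seq_len(nrow(template))) {
    off <- c(template$dx[i], template$dy[i], template$dz[i])
    if (is.na(template$parent[i])) {
      pos[i, ] <- root_position + off
    } else {
      pos[i, ] <- pos[template$parent[i], ] + off
    }
  }
  pos
}

template_segment_length <- function(template, joint) {
  i <- match(joint, template$joint)
  sqrt(template$dx[i]^2 + template$dy[i]^2 + template$dz[i]^2)
}

template_descendants <- function(template, joint) {
  out <- character(0)
  frontier <- joint
  repeat {
    kids <- template$joint[!is.na(template$parent) & template$parent %in% frontier]
    if (length(kids) == 0) break
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

## Which joints move, and in which plane, for each joint/movement pair.
movement_profile <- function(code) {
  if (is.character(code)) code <- parse_movement_code(code)
  key <- paste(code$joint, code$movement, sep = "-")
  profiles <- list(
    "K-FLEX" = list(proximal = "knee_right", distal = "ankle_right",
                    plane = "sagittal", limb_group = "lower"),
    "H-ABD"  = list(proximal = "hip_right", distal = "knee_right",
                    plane = "frontal", limb_group = "lower"),
    "H-FLEX" = list(proximal = "hip_right", distal = "knee_right",
                    plane = "sagittal", limb_group = "lower"),
    "E-FLEX" = list(proximal = "elbow_right", distal = "wrist_right",
                    plane = "sagittal", limb_group = "upper"),
    "S-ABD"  = list(proximal = "shoulder_right", distal = "elbow_right",
                    plane = "frontal", limb_group = "upper"),
    "S-FLEX" = list(proximal = "shoulder_right", distal = "elbow_right",
                    plane = "sagittal", limb_group = "upper")
  )
  p <- profiles[[key]]
  if (is.null(p)) kv_stop("kv_unknown_movement", "no movement profile for '%s'", key)
  p
}

## Closed-form trajectory: baseline outside [0, n/f], raised cosine inside.
script_angle_at <- function(script, t) {
  f <- script$frequency
  span <- script$n_repetitions / f
  inside <- t >= 0 & t <= span
  out <- rep(script$baseline_angle, length(t))
  out[inside] <- script$baseline_angle +
    script$amplitude / 2 * (1 - cos(2 * pi * f * t[inside]))
  out
}

#' Sample a ground-truth angle trajectory
#'
#' Evaluates the closed-form raised-cosine trajectory of a motion script on
#' a regular sampling grid. The movement is preceded by a still baseline of
#' `lead_in + start_offset` seconds, where `lead_in` centres the movement in
#' the scripted duration; `start_offset` delays the onset further, which is
#' what makes two independently started recordings of the same movement
#' out of phase.
#'
#' @param script A [motion_script()].
#' @param rate Sampling rate in Hz; must be at least twice the script
#'   frequency (sampling theorem).
#' @param start_offset Extra onset delay in seconds.
#' @return An [angle_series()] of `floor(duration * rate) + 1` samples.
#' @export
generate_angle_trajectory <- function(script, rate, start_offset = 0) {
  stopifnot(inherits(script, "motion_script"))
  if (rate < 2 * script$frequency) {
    kv_stop("kv_below_nyquist",
            "rate %g Hz is below twice the movement frequency %g Hz",
            rate, script$frequency)
  }
  lead_in <- (script$duration - script$n_repetitions / script$frequency) / 2
  t <- seq(0, script$duration, by = 1 / rate)
  ang <- script_angle_at(script, t - lead_in - start_offset)
  angle_series(ang, rate = rate, time_s = t,
               movement_code = script$movement_code, source = "truth")
}

#' Forward kinematics: pose a skeleton from a scripted angle trajectory
#'
#' Inverse of the angle computation: places the moving segment of the
#' movement's joint so that, in body coordinates, the distal-minus-proximal
#' vector lies exactly in the movement's anatomical plane at the scripted
#' angle from the plane's reference axis. All other joints stay in the
#' canonical pose; joints distal to the moving one translate rigidly with
#' it, so every segment length is preserved at every frame.
#'
#' @param template A [default_skeleton_template()]-style template.
#' @param angles An [angle_series()] of scripted angles (no gaps).
#' @param movement_code Movement code naming the moving joint and plane.
#' @param root_position Subject root position in the sensor frame (metres).
#' @return A [skeleton_stream()] at the series' rate.
#' @export
forward_kinematics <- function(template, angles, movement_code,
                               root_position = c(0, 0, 2.5)) {
  stopifnot(inherits(angles, "angle_series"))
  if (any(!angles$valid)) kv_stop("kv_bad_script", "scripted angles may not contain gaps")
  prof <- movement_profile(movement_code)
  pose0 <- skeleton_pose(template, root_position)
  basis <- build_body_basis(pose0, prof$limb_group)
  plane <- anatomical_plane(prof$plane)

  theta <- angles$angle_deg * pi / 180
  # in-plane unit vector at angle theta from the reference axis, rotated
  # towards the third (in-plane, non-reference) direction
  third <- cross3(plane$normal, plane$reference_axis)
  v_bc <- outer(cos(theta), plane$reference_axis) + outer(sin(theta), third)
  v_sc <- v_bc %*% t(basis$B)  # rows: sensor-frame unit vectors

  L <- template_segment_length(template, prof$distal)
  prox <- pose0[prof$proximal, ]
  distal_xyz <- sweep(L * v_sc, 2, prox, `+`)
  delta <- sweep(distal_xyz, 2, pose0[prof$distal, ], `-`)

  moving <- c(prof$distal, template_descendants(template, prof$distal))
  n <- nrow(angles)
  joints <- template$joint
  per_joint <- lapply(joints, function(j) {
    if (j == prof$distal) {
      distal_xyz
    } else if (j %in% moving) {
      sweep(delta, 2, pose0[j, ], `+`)
    } else {
      matrix(pose0[j, ], nrow = n, ncol = 3, byrow = TRUE)
    }
  })
  df <- data.frame(
    frame = rep(angles$frame, times = length(joints)),
    time_s = rep(angles$time_s, times = length(joints)),
    joint = rep(joints, each = n),
    x_m = unlist(lapply(per_joint, function(m) m[, 1])),
    y_m = unlist(lapply(per_joint, function(m) m[, 2])),
    z_m = unlist(lapply(per_joint, function(m) m[, 3]))
  )
  skeleton_stream(df, rate = attr(angles, "rate"),
                  movement_code = attr(angles, "movement_code"),
                  source = "forward_kinematics")
}

#' Render a skeleton stream through a virtual camera
#'
#' Emulates what a depth sensor plus landmark tracker would deliver for a
#' ground-truth skeleton stream: the subject is rotated about the vertical
#' axis by the configured camera orientation, isotropic Gaussian noise is
#' added to the 3D joint positions, and the noisy joints are projected
#' through the pinhole model to 2D landmarks with per-landmark depth
#' records. Frames containing a joint at or behind the camera plane are
#' rejected and logged, not silently dropped. With zero noise and zero
#' orientation the noisy stream equals the input exactly, and
#' back-projecting the rendered 2D + depth recovers the noisy 3D joints.
#'
#' @param stream A ground-truth [skeleton_stream()].
#' @param config A [simulation_config()]; `position_noise_sd`,
#'   `camera_orientation` and `seed` are used here.
#' @param intrinsics A [camera_intrinsics()] object.
#' @param source Label attached to the rendered stream.
#' @return A list with elements `stream` (noisy [skeleton_stream()]),
#'   `landmarks` (frame, time_s, joint, xp, yp), `depth` (frame, joint, u,
#'   v, z_m) and `rejected` (frame, reason).
#' @export
render_sensor_stream <- function(stream, config, intrinsics = default_intrinsics(),
                                 source = "sensor") {
  stopifnot(inherits(stream, "skeleton_stream"),
            inherits(config, "simulation_config"))
  df <- as.data.frame(stream)

  phi <- config$camera_orientation * pi / 180
  if (phi != 0) {
    # rotate the subject about the vertical (sensor y) axis through the
    # centroid of the first frame, so the subject stays in the field of view
    f0 <- df$frame == df$frame[1]
    cx <- mean(df$x_m[f0]); cz <- mean(df$z_m[f0])
    x0 <- df$x_m - cx; z0 <- df$z_m - cz
    df$x_m <- cos(phi) * x0 + sin(phi) * z0 + cx
    df$z_m <- -sin(phi) * x0 + cos(phi) * z0 + cz
  }

  if (config$position_noise_sd > 0) {
    df[, c("x_m", "y_m", "z_m")] <- with_preserved_rng(config$seed, {
      df[, c("x_m", "y_m", "z_m")] +
        matrix(rnorm(3 * nrow(df), sd = config$position_noise_sd), ncol = 3)
    })
  }

  bad_frames <- unique(df$frame[df$z_m <= 0])
  rejected <- data.frame(frame = bad_frames,
                         reason = rep("joint at or behind camera plane",
                                      length(bad_frames)))
  df <- df[!(df$frame %in% bad_frames), , drop = FALSE]
  if (nrow(df) == 0) kv_stop("kv_empty_series", "every frame was rejected")

  px <- project_points(df$x_m, df$y_m, df$z_m, intrinsics)
  landmarks <- data.frame(frame = df$frame, time_s = df$time_s,
                          joint = df$joint, xp = px$xp, yp = px$yp)
  depth <- data.frame(frame = df$frame, joint = df$joint,
                      u = round(px$xp), v = round(px$yp), z_m = df$z_m)
  list(stream = skeleton_stream(df, rate = attr(stream, "rate"),
                                movement_code = attr(stream, "movement_code"),
                                source = source),
       landmarks = landmarks, depth = depth, rejected = rejected)
}
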