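#' Pinhole camera intrinsics
#'
#' Minimal intrinsic model used to relate pixel coordinates plus depth to 3D
#' sensor-frame coordinates: a single focal length `f` (pixels) and a
#' principal point `(xo, yo)`. Pixel origin is the top-left image corner with
#' x rightwards and y downwards; consequently the sensor frame has y pointing
#' down as well (the flip to anatomical "up" happens once, in the body-basis
#' construction, not here). Lens distortion and RGB-to-depth registration are
#' out of scope: frames are assumed registered.
#'
#' @param f Focal length in pixels (> 0).
#' @param xo,yo Principal point in pixels, inside the image.
#' @param width,height Image size in pixels.
#' @return An object of class `camera_intrinsics`.
#' @examples
#' k <- camera_intrinsics(f = 500, xo = 320, yo = 240, width = 640, height = 480)
#' backproject(420, 240, z = 1, k)
#' @export
camera_intrinsics <- function(f, xo, yo, width = 2 * xo, height = 2 * yo) {
  stopifnot(is.numeric(f), length(f) == 1, is.finite(f))
  if (f <= 0) kv_stop("kv_bad_intrinsics", "focal length must be positive, got %g", f)
  if (xo < 0 || xo >= width || yo < 0 || yo >= height) {
    kv_stop("kv_bad_intrinsics", "principal point (%g, %g) outside %g x %g image",
            xo, yo, width, height)
  }
  structure(list(f = f, xo = xo, yo = yo, width = width, height = height),
            class = "camera_intrinsics")
}

#' Default virtual-camera intrinsics
#'
#' A 512 x 424 depth camera with a 365-pixel focal length, typical of
#' consumer time-of-flight depth sensors.
#'
#' @return A [camera_intrinsics()] object.
#' @export
default_intrinsics <- function() {
  camera_intrinsics(f = 365, xo = 256, yo = 212, width = 512, height = 424)
}

#' Back-project pixel coordinates plus depth to 3D
#'
#' Inverts the pinhole projection: a landmark at pixel `(xp, yp)` observed at
#' depth `z` metres maps to sensor-frame coordinates
#' `((xp - xo) z / f, (yp - yo) z / f, z)`.
#'
#' @param xp,yp Pixel coordinates (numeric vectors, recycled together).
#' @param z Depth in metres (> 0).
#' @param intrinsics A [camera_intrinsics()] object.
#' @return A data frame with columns `xw`, `yw`, `zw` (metres).
#' @seealso [project_points()] for the forward direction.
#' @examples
#' k <- camera_intrinsics(f = 500, xo = 320, yo = 240, width = 640, height = 480)
#' backproject(420, 240, 1, k)  # 0.2 m to the right of the optical axis
#' @export
backproject <- function(xp, yp, z, intrinsics) {
  stopifnot(inherits(intrinsics, "camera_intrinsics"))
  n <- max(length(xp), length(yp), length(z))
  xp <- rep_len(xp, n); yp <- rep_len(yp, n); z <- rep_len(z, n)
  if (any(!is.finite(z)) || any(z <= 0)) {
    kv_stop("kv_invalid_depth", "depth must be finite and positive")
  }
  data.frame(
    xw = (xp - intrinsics$xo) * z / intrinsics$f,
    yw = (yp - intrinsics$yo) * z / intrinsics$f,
    zw = z
  )
}

#' Project 3D sensor-frame points to pixel coordinates
#'
#' Forward pinhole projection, the exact inverse of [backproject()]:
#' `xp = xo + f * xw / zw`, `yp = yo + f * yw / zw`.
#'
#' @param xw,yw,zw Sensor-frame coordinates in metres; `zw` must be > 0
#'   (in front of the camera).
#' @param intrinsics A [camera_intrinsics()] object.
#' @return A data frame with columns `xp`, `yp` (pixels, sub-pixel floats).
#' @export
project_points <- function(xw, yw, zw, intrinsics) {
  stopifnot(inherits(intrinsics, "camera_intrinsics"))
  n <- max(length(xw), length(yw), length(zw))
  xw <- rep_len(xw, n); yw <- rep_len(yw, n); zw <- rep_len(zw, n)
  if (any(!is.finite(zw)) || any(zw <= 0)) {
    kv_stop("kv_behind_camera", "cannot project points at or behind the camera plane")
  }
  data.frame(
    xp = intrinsics$xo + intrinsics$f * xw / zw,
    yp = intrinsics$yo + intrinsics$f * yw / zw
  )
}

#' Overlay 2D landmarks onto a depth frame and lift them to 3D
#'
#' For each landmark, depth is sampled at the nearest integer pixel; if that
#' pixel holds no valid depth (missing, zero or negative), the median of the
#' valid depths in its 3x3 neighbourhood is used instead. Landmarks without
#' any valid depth are flagged (`valid = FALSE`) rather than dropped, so the
#' caller can account for the loss. When both streams carry timestamps, the
#' pair must agree to within half a frame period, mirroring the way
#' asynchronous depth/colour recordings invalidate a recording.
#'
#' @param landmarks Data frame with columns `joint`, `xp`, `yp` (sub-pixel
#'   floats are fine) and optionally `confidence`.
#' @param depth Data frame with columns `u`, `v` (integer pixels) and `z_m`
#'   (metres; values <= 0 are treated as invalid).
#' @param intrinsics A [camera_intrinsics()] object.
#' @param landmark_time,depth_time Optional timestamps (seconds) of the two
#'   frames.
#' @param frame_period Frame period in seconds used for the synchrony check
#'   (default `1/30`).
#' @return A data frame with columns `joint`, `xw`, `yw`, `zw`, `valid`.
#' @export
overlay_depth <- function(landmarks, depth, intrinsics,
                          landmark_time = NULL, depth_time = NULL,
                          frame_period = 1 / 30) {
  stopifnot(all(c("joint", "xp", "yp") %in% names(landmarks)),
            all(c("u", "v", "z_m") %in% names(depth)))
  if (!is.null(landmark_time) && !is.null(depth_time) &&
      abs(landmark_time - depth_time) > frame_period / 2) {
    kv_stop("kv_async_frames",
            "depth frame (t=%.4f) and landmark frame (t=%.4f) differ by more than half a frame period",
            depth_time, landmark_time)
  }
  ok <- is.finite(depth$z_m) & depth$z_m > 0
  depth <- depth[ok, , drop = FALSE]
  key <- function(u, v) paste(u, v, sep = ",")
  lut <- setNames(as.list(depth$z_m), key(depth$u, depth$v))

  lookup <- function(xp, yp) {
    u <- round(xp); v <- round(yp)
    z <- lut[[key(u, v)]]
    if (!is.null(z)) return(z)
    # nearest pixel invalid: median of valid 3x3 neighbours
    nb <- expand.grid(du = -1:1, dv = -1:1)
    zs <- unlist(lapply(seq_len(nrow(nb)), function(i) {
      lut[[key(u + nb$du[i], v + nb$dv[i])]]
    }))
    if (length(zs) > 0) median(zs) else NA_real_
  }

  z <- vapply(seq_len(nrow(landmarks)),
              function(i) lookup(landmarks$xp[i], landmarks$yp[i]) %||% NA_real_,
              numeric(1))
  valid <- is.finite(z) & z > 0
  out <- data.frame(joint = landmarks$joint, xw = NA_real_, yw = NA_real_,
                    zw = NA_real_, valid = valid)
  if (any(valid)) {
    w <- backproject(landmarks$xp[valid], landmarks$yp[valid], z[valid], intrinsics)
    out$xw[valid] <- w$xw
    out$yw[valid] <- w$yw
    out$zw[valid] <- w$zw
  }
  out
}
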