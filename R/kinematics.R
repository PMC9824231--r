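## Small 3-vector helpers kept internal: the package works frame by frame on
## length-3 vectors, where dedicated linear-algebra machinery would only add
## overhead.
vnorm <- function(v) sqrt(sum(v^2))
normalize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) kv_stop("kv_degenerate_basis", "cannot normalize a (near-)zero vector")
  v / n
}
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
angle_between_deg <- function(a, b) {
  ct <- sum(a * b) / (vnorm(a) * vnorm(b))
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

#' Build a body coordinate system from trunk landmarks
#'
#' Constructs a right-handed orthonormal basis anchored to the trunk, in the
#' ISB spirit: the longitudinal axis `y` runs from the middle of the spine to
#' its top; the mediolateral axis `x` is the left-hip-to-right-hip direction
#' orthogonalized against `y`; `z = x x y` completes the right-handed system.
#' Because the sensor frame has y pointing down (image convention), an
#' upright subject yields `y` close to `(0, -1, 0)` in sensor coordinates —
#' this is where the single image-axis flip of the pipeline lives.
#'
#' The same trunk/pelvis landmarks serve the upper- and lower-limb cases;
#' only the basis origin differs (mid-spine for upper limbs, the hip
#' midpoint for lower limbs).
#'
#' @param frame A joints-by-3 coordinate matrix with row names, or a data
#'   frame with columns `joint`, `x_m`, `y_m`, `z_m` (one frame).
#' @param limb_group `"upper"` or `"lower"`; selects the basis origin.
#' @return An object of class `body_basis`: unit vectors `x`, `y`, `z`, the
#'   `origin`, and the 3x3 basis matrix `B` whose columns are x, y, z in
#'   sensor coordinates.
#' @export
build_body_basis <- function(frame, limb_group = c("upper", "lower")) {
  limb_group <- match.arg(limb_group)
  m <- as_frame_matrix(frame)
  need <- c("hip_left", "hip_right", "spine_mid", "spine_top")
  missing <- setdiff(need, rownames(m))
  if (length(missing) > 0) {
    kv_stop("kv_missing_joint", "basis construction requires joints: %s",
            paste(missing, collapse = ", "))
  }
  y_raw <- unname(m["spine_top", ] - m["spine_mid", ])
  if (vnorm(y_raw) < 1e-9) {
    kv_stop("kv_degenerate_basis", "spine landmarks are coincident")
  }
  y <- normalize(y_raw)
  hips <- unname(m["hip_right", ] - m["hip_left", ])
  x_raw <- hips - sum(hips * y) * y
  if (vnorm(x_raw) < 1e-9) {
    kv_stop("kv_degenerate_basis",
            "hip axis is collinear with the spine axis; basis is degenerate")
  }
  x <- normalize(x_raw)
  z <- cross3(x, y)
  origin <- unname(if (limb_group == "upper") m["spine_mid", ] else {
    (m["hip_left", ] + m["hip_right", ]) / 2
  })
  structure(list(x = x, y = y, z = z, origin = origin,
                 B = cbind(x = x, y = y, z = z), limb_group = limb_group),
            class = "body_basis")
}

as_frame_matrix <- function(frame) {
  if (is.matrix(frame)) {
    if (!all(is.finite(frame))) kv_stop("kv_bad_frame", "non-finite joint coordinates")
    return(frame)
  }
  stopifnot(all(c("joint", "x_m", "y_m", "z_m") %in% names(frame)))
  m <- as.matrix(frame[, c("x_m", "y_m", "z_m")])
  rownames(m) <- frame$joint
  if (!all(is.finite(m))) kv_stop("kv_bad_frame", "non-finite joint coordinates")
  m
}

#' Change of basis from sensor to body coordinates
#'
#' Applies the inverse of the basis matrix `B` (columns = body axes expressed
#' in sensor coordinates) to a sensor-frame vector: `v_bc = B^-1 v_sc`. For a
#' valid orthonormal basis the inverse equals the transpose and the vector
#' norm is preserved; the explicit inverse is guarded against a degenerate
#' matrix anyway.
#'
#' @param v A length-3 vector, or an n-by-3 matrix of row vectors.
#' @param basis A [build_body_basis()] result.
#' @return Same shape as `v`, in body coordinates.
#' @export
to_body_coords <- function(v, basis) {
  stopifnot(inherits(basis, "body_basis"))
  B <- basis$B
  if (abs(det(B)) < 1e-9) kv_stop("kv_degenerate_basis", "basis matrix is not invertible")
  Binv <- solve(B)
  if (is.matrix(v)) t(Binv %*% t(v)) else as.numeric(Binv %*% v)
}

#' Anatomical plane definitions
#'
#' The three anatomical planes expressed in body coordinates, each with its
#' unit normal and the in-plane reference axis that angles are measured from:
#' frontal (normal `z`, reference `-y`, so the anatomical neutral "limb
#' hanging down" reads 0 deg and full elevation 180 deg), sagittal (normal
#' `x`, reference `-y`) and horizontal (normal `y`, reference `x`).
#'
#' @param name `"frontal"`, `"sagittal"` or `"horizontal"`.
#' @return An object of class `anatomical_plane` with fields `name`,
#'   `normal`, `reference_axis`.
#' @export
anatomical_plane <- function(name = c("frontal", "sagittal", "horizontal")) {
  name <- match.arg(name)
  def <- switch(name,
    frontal    = list(normal = c(0, 0, 1), reference_axis = c(0, -1, 0)),
    sagittal   = list(normal = c(1, 0, 0), reference_axis = c(0, -1, 0)),
    horizontal = list(normal = c(0, 1, 0), reference_axis = c(1, 0, 0))
  )
  structure(c(list(name = name), def), class = "anatomical_plane")
}

#' Specify which joint angle to compute
#'
#' Pairs a proximal and a distal joint (their difference is the moving
#' segment vector), the anatomical plane the movement is expected to stay
#' in, and the out-of-plane tolerance in degrees: the maximum deviation of
#' the moving vector from the plane before the frame is rejected. The
#' default tolerance of 90 degrees disables the check, since real tracked
#' data wander out of plane unpredictably; tighten it to enforce monoplanar
#' execution.
#'
#' @param proximal,distal Joint names.
#' @param plane An [anatomical_plane()] or a plane name.
#' @param tolerance Out-of-plane tolerance in degrees (>= 0).
#' @return An object of class `angle_request`.
#' @export
angle_request <- function(proximal, distal, plane, tolerance = 90) {
  if (is.character(plane)) plane <- anatomical_plane(plane)
  stopifnot(inherits(plane, "anatomical_plane"), tolerance >= 0)
  structure(list(proximal = proximal, distal = distal, plane = plane,
                 tolerance = tolerance),
            class = "angle_request")
}

#' Joint angle within an anatomical plane
#'
#' Computes the moving vector (distal minus proximal joint) in body
#' coordinates, verifies it lies in the requested plane — its angle to the
#' plane normal must be within `tolerance` of 90 degrees — and returns the
#' angle between the moving vector and the plane's reference axis, in
#' `[0, 180]` degrees.
#'
#' @param request An [angle_request()].
#' @param frame One skeleton frame (matrix or data frame, see
#'   [build_body_basis()]).
#' @param basis A [build_body_basis()] result for that frame.
#' @return Angle in degrees.
#' @export
angle_in_plane <- function(request, frame, basis) {
  stopifnot(inherits(request, "angle_request"))
  m <- as_frame_matrix(frame)
  need <- c(request$proximal, request$distal)
  missing <- setdiff(need, rownames(m))
  if (length(missing) > 0) {
    kv_stop("kv_missing_joint", "frame lacks joints: %s", paste(missing, collapse = ", "))
  }
  v_sc <- m[request$distal, ] - m[request$proximal, ]
  if (vnorm(v_sc) < 1e-12) {
    kv_stop("kv_degenerate_vector", "moving vector has zero length")
  }
  v_bc <- to_body_coords(v_sc, basis)
  off_plane <- abs(angle_between_deg(v_bc, request$plane$normal) - 90)
  if (off_plane > request$tolerance) {
    kv_stop("kv_out_of_plane",
            "moving vector is %.2f deg out of the %s plane (tolerance %.2f)",
            off_plane, request$plane$name, request$tolerance)
  }
  angle_between_deg(v_bc, request$plane$reference_axis)
}

#' Per-frame joint angles for a whole stream
#'
#' Applies [build_body_basis()] and [angle_in_plane()] to every frame of a
#' skeleton stream. Frames that fail (missing joints, degenerate basis,
#' out-of-plane beyond tolerance) become masked samples — gaps — rather than
#' aborting the series; gap filling is deliberately left to the signal
#' conditioning stage.
#'
#' @param stream A [skeleton_stream()].
#' @param request An [angle_request()].
#' @param limb_group `"upper"` or `"lower"`, passed to [build_body_basis()].
#' @return An [angle_series()] with `valid = FALSE` at failed frames.
#' @export
compute_angle_series <- function(stream, request, limb_group = "upper") {
  stopifnot(inherits(stream, "skeleton_stream"))
  frames <- stream_frames(stream)
  if (length(frames) == 0) kv_stop("kv_empty_series", "stream has no frames")
  times <- vapply(frames, function(f) stream$time_s[stream$frame == f][1], numeric(1))
  ang <- vapply(frames, function(f) {
    m <- frame_matrix(stream, f)
    tryCatch({
      basis <- build_body_basis(m, limb_group)
      angle_in_plane(request, m, basis)
    }, kv_error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(ang))) {
    kv_stop("kv_empty_series", "no frame of the stream yielded a valid angle")
  }
  angle_series(ang, rate = attr(stream, "rate"), time_s = times,
               movement_code = attr(stream, "movement_code"),
               source = attr(stream, "source"))
}
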