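#' Skeleton stream container
#'
#' A long-format per-frame record of named 3D joint positions with a sampling
#' rate: one row per (frame, joint) with sensor-frame coordinates in metres.
#' This is the common currency between the synthetic generator, the
#' back-projection path and the angle computation.
#'
#' @param df Data frame with columns `frame`, `time_s`, `joint`, `x_m`,
#'   `y_m`, `z_m`.
#' @param rate Sampling rate in Hz.
#' @param movement_code Optional movement code label (see
#'   [parse_movement_code()]).
#' @param source Optional label of the stream origin (e.g. a sensor name).
#' @return An object of classes `skeleton_stream` and `data.frame`.
#' @export
skeleton_stream <- function(df, rate, movement_code = NA_character_,
                            source = NA_character_) {
  req <- c("frame", "time_s", "joint", "x_m", "y_m", "z_m")
  stopifnot(all(req %in% names(df)))
  if (!all(is.finite(df$x_m) & is.finite(df$y_m) & is.finite(df$z_m))) {
    kv_stop("kv_bad_stream", "skeleton stream contains non-finite coordinates")
  }
  structure(df,
            rate = rate, movement_code = movement_code, source = source,
            class = c("skeleton_stream", "data.frame"))
}

#' @export
print.skeleton_stream <- function(x, ...) {
  cat(sprintf("<skeleton_stream> %d frames x %d joints @ %g Hz  [%s | %s]\n",
              length(unique(x$frame)), length(unique(x$joint)),
              attr(x, "rate"), attr(x, "movement_code"), attr(x, "source")))
  invisible(x)
}

## One frame of a stream as a joints x 3 coordinate matrix.
frame_matrix <- function(stream, frame_index) {
  rows <- stream$frame == frame_index
  m <- as.matrix(stream[rows, c("x_m", "y_m", "z_m")])
  rownames(m) <- stream$joint[rows]
  m
}

stream_frames <- function(stream) sort(unique(stream$frame))

#' Angle-versus-time series
#'
#' A 1-D joint-angle signal with its sampling rate, movement code and
#' provenance. Frames for which no angle could be computed (missing joints,
#' out-of-plane beyond tolerance) are kept as masked samples
#' (`valid = FALSE`, `angle_deg = NA`) so downstream gap handling stays
#' explicit.
#'
#' @param angle_deg Numeric vector of angles in degrees (NA for gaps).
#' @param rate Sampling rate in Hz.
#' @param time_s Optional sample times; defaults to `(0:(n-1)) / rate`.
#' @param valid Optional logical mask; defaults to `!is.na(angle_deg)`.
#' @param movement_code,source Optional provenance labels.
#' @return An object of classes `angle_series` and `data.frame` with columns
#'   `frame`, `time_s`, `angle_deg`, `valid`.
#' @export
angle_series <- function(angle_deg, rate, time_s = NULL, valid = NULL,
                         movement_code = NA_character_, source = NA_character_) {
  n <- length(angle_deg)
  if (n == 0) kv_stop("kv_empty_series", "angle series has no samples")
  time_s <- time_s %||% ((seq_len(n) - 1) / rate)
  valid <- valid %||% !is.na(angle_deg)
  structure(
    data.frame(frame = seq_len(n) - 1L, time_s = time_s,
               angle_deg = angle_deg, valid = valid),
    rate = rate, movement_code = movement_code, source = source,
    class = c("angle_series", "data.frame"))
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("<angle_series> %d samples @ %g Hz, %d gaps  [%s | %s]\n",
              nrow(x), attr(x, "rate"), sum(!x$valid),
              attr(x, "movement_code"), attr(x, "source")))
  invisible(x)
}

series_values <- function(x) {
  if (inherits(x, "angle_series")) x$angle_deg else as.numeric(x)
}

series_rate <- function(x, rate = NULL) {
  rate %||% attr(x, "rate") %||%
    kv_stop("kv_bad_series", "sampling rate neither supplied nor attached to the series")
}

## Rebuild an angle_series carrying provenance from a parent object.
rewrap_series <- function(values, template, rate = NULL, time_s = NULL) {
  angle_series(values,
               rate = series_rate(template, rate),
               time_s = time_s,
               movement_code = attr(template, "movement_code") %||% NA_character_,
               source = attr(template, "source") %||% NA_character_)
}
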