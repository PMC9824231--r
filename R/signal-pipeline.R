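#' Filter specification for angle-series conditioning
#'
#' The conditioning chain is a 7th-order Butterworth low-pass followed by a
#' 7-sample moving average. The Butterworth cutoff depends on the stream: 5
#' Hz for the 30 Hz sensor streams, 30 Hz for the 180 Hz reference stream
#' (see [default_filter_spec()]). The Butterworth stage is applied
#' forward-backward (zero phase), because the peak-based synchronization
#' downstream depends on filtering not shifting the peaks; this doubles the
#' effective attenuation order.
#'
#' @param butterworth_order Filter order (>= 1).
#' @param cutoff Low-pass cutoff in Hz; must be below the Nyquist rate of
#'   the series it is applied to.
#' @param moving_average_kernel Odd moving-average kernel length in samples.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(butterworth_order = 7, cutoff = 5,
                        moving_average_kernel = 7) {
  stopifnot(butterworth_order >= 1, cutoff > 0)
  if (moving_average_kernel %% 2 != 1) {
    kv_stop("kv_bad_filter", "moving-average kernel must be odd, got %d",
            moving_average_kernel)
  }
  structure(list(butterworth_order = butterworth_order, cutoff = cutoff,
                 moving_average_kernel = moving_average_kernel),
            class = "filter_spec")
}

#' @rdname filter_spec
#' @param rate Sampling rate of the stream to be filtered.
#' @export
default_filter_spec <- function(rate) {
  filter_spec(cutoff = if (rate >= 100) 30 else 5)
}

#' Fill short gaps in an angle series
#'
#' Masked samples (invalid frames from the angle computation) are linearly
#' interpolated across, provided no gap run exceeds `max_gap` consecutive
#' samples; leading/trailing gaps take the nearest valid value. A longer
#' gap means the recording cannot be conditioned reliably and is flagged
#' lost (`kv_recording_lost`), mirroring how noisy recordings are discarded
#' rather than patched.
#'
#' @param series An [angle_series()].
#' @param max_gap Longest fillable gap run, in samples.
#' @return An [angle_series()] with all samples valid.
#' @export
fill_gaps <- function(series, max_gap = 5) {
  stopifnot(inherits(series, "angle_series"))
  v <- series$valid & !is.na(series$angle_deg)
  if (all(v)) return(series)
  runs <- rle(!v)
  if (any(runs$lengths[runs$values] > max_gap)) {
    kv_stop("kv_recording_lost",
            "gap of %d consecutive invalid samples exceeds the fillable maximum of %d",
            max(runs$lengths[runs$values]), max_gap)
  }
  if (sum(v) < 2) kv_stop("kv_recording_lost", "too few valid samples to fill gaps")
  filled <- approx(x = which(v), y = series$angle_deg[v],
                   xout = seq_along(v), rule = 2)$y
  rewrap_series(filled, series, time_s = series$time_s)
}

## forward-backward filtering with mean removal and odd-reflection edge
## padding, so that transients from the filter's zero initial conditions
## cannot leak into the series (a constant passes through bit-exactly)
zero_phase_filter <- function(bf, x, order) {
  n <- length(x)
  mu <- mean(x)
  xc <- x - mu
  p <- min(n - 1, 12 * order)
  left <- 2 * xc[1] - xc[(p + 1):2]
  right <- 2 * xc[n] - xc[(n - 1):(n - p)]
  y <- signal::filtfilt(bf, c(left, xc, right))
  y[(p + 1):(p + n)] + mu
}

## moving average with edge-reflection padding; preserves length
moving_average <- function(x, kernel) {
  h <- (kernel - 1) / 2
  n <- length(x)
  if (h == 0) return(x)
  xp <- c(x[(h + 1):2], x, x[(n - 1):(n - h)])
  as.numeric(stats::filter(xp, rep(1 / kernel, kernel), sides = 2))[(h + 1):(h + n)]
}

#' Smooth an angle series
#'
#' Applies the zero-phase Butterworth low-pass, then the moving average of
#' [filter_spec()]. Gaps must have been filled first ([fill_gaps()]); the
#' series must be longer than three filter orders for the forward-backward
#' pass to be stable.
#'
#' @param series An [angle_series()] (or numeric vector with `rate`).
#' @param spec A [filter_spec()]; defaults to [default_filter_spec()] for
#'   the series' rate.
#' @param rate Sampling rate, taken from the series if attached.
#' @return A smoothed [angle_series()] of identical length.
#' @export
smooth_series <- function(series, spec = NULL, rate = NULL) {
  rate <- series_rate(series, rate)
  spec <- spec %||% default_filter_spec(rate)
  x <- series_values(series)
  if (anyNA(x)) kv_stop("kv_bad_series", "fill gaps before smoothing")
  if (length(x) <= 3 * spec$butterworth_order) {
    kv_stop("kv_series_too_short",
            "series of %d samples is too short for order-%d zero-phase filtering",
            length(x), spec$butterworth_order)
  }
  if (spec$cutoff >= rate / 2) {
    kv_stop("kv_bad_filter", "cutoff %g Hz is not below the Nyquist rate %g Hz",
            spec$cutoff, rate / 2)
  }
  bf <- signal::butter(spec$butterworth_order, spec$cutoff / (rate / 2), type = "low")
  y <- zero_phase_filter(bf, x, spec$butterworth_order)
  y <- moving_average(y, spec$moving_average_kernel)
  if (inherits(series, "angle_series")) {
    rewrap_series(y, series, rate = rate, time_s = series$time_s)
  } else {
    angle_series(y, rate = rate)
  }
}

## peak prominence: height above the higher of the two minima separating the
## peak from higher terrain (or the series ends)
peak_prominences <- function(x, peaks) {
  vapply(peaks, function(p) {
    left <- x[1:p]
    higher_l <- which(left > x[p])
    lmin <- min(left[(if (length(higher_l)) max(higher_l) else 1):p])
    right <- x[p:length(x)]
    higher_r <- which(right > x[p])
    rmin <- min(right[1:(if (length(higher_r)) min(higher_r) else length(right))])
    x[p] - max(lmin, rmin)
  }, numeric(1))
}

## dominant non-DC frequency, used to derive the minimum peak spacing
dominant_frequency <- function(x, rate) {
  x <- x - mean(x)
  if (sd(x) < 1e-12) return(NA_real_)
  n <- length(x)
  mag <- Mod(fft(x))[2:floor(n / 2)]
  freq <- (seq_along(mag)) * rate / n
  freq[which.max(mag)]
}

#' Detect repetition peaks and segment the series
#'
#' Finds the repetition maxima of a smoothed angle series and splits it into
#' the three sections used for dual-rate alignment: start to first peak,
#' first to last peak, and last peak to end. Candidate local maxima must
#' have a prominence of at least `min_prominence_frac` of the signal range
#' and be separated by at least half a repetition period (estimated from
#' the dominant spectral component unless `min_spacing_s` is given).
#'
#' @param series A smoothed [angle_series()] or numeric vector.
#' @param min_prominence_frac Minimum prominence as a fraction of the
#'   signal range.
#' @param min_spacing_s Minimum peak spacing in seconds (optional).
#' @param rate Sampling rate, taken from the series if attached.
#' @return An object of class `segmented_series`: the series values, `rate`,
#'   integer `peaks`, and `segments` — a list of three `(from, to)` index
#'   pairs that are contiguous and cover the series.
#' @export
detect_peaks <- function(series, min_prominence_frac = 0.2,
                         min_spacing_s = NULL, rate = NULL) {
  rate <- series_rate(series, rate)
  x <- series_values(series)
  n <- length(x)
  rng <- diff(range(x))
  if (rng < 1e-9) kv_stop("kv_no_peak", "signal is flat; no repetition peaks found")

  d <- diff(x)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L  # interior local maxima
  if (length(cand) == 0) kv_stop("kv_no_peak", "no local maximum found")
  prom <- peak_prominences(x, cand)
  cand <- cand[prom >= min_prominence_frac * rng]
  if (length(cand) == 0) kv_stop("kv_no_peak", "no sufficiently prominent peak found")

  spacing_s <- min_spacing_s %||% {
    f0 <- dominant_frequency(x, rate)
    if (is.na(f0) || f0 <= 0) 0 else 0.5 / f0
  }
  min_gap <- spacing_s * rate
  keep <- integer(0)
  for (p in cand[order(x[cand], decreasing = TRUE)]) {
    if (all(abs(p - keep) >= min_gap)) keep <- c(keep, p)
  }
  peaks <- sort(keep)
  segments <- list(c(1L, peaks[1]),
                   c(peaks[1], peaks[length(peaks)]),
                   c(peaks[length(peaks)], n))
  structure(list(values = x, rate = rate, peaks = peaks, segments = segments,
                 series = if (inherits(series, "angle_series")) series else NULL),
            class = "segmented_series")
}

#' @export
print.segmented_series <- function(x, ...) {
  cat(sprintf("<segmented_series> %d samples @ %g Hz, peaks at [%s]\n",
              length(x$values), x$rate, paste(x$peaks, collapse = ", ")))
  invisible(x)
}

## local 3-point (second-order) Lagrange interpolation on a sorted grid;
## exact on quadratics, identity when xi coincides with x
quadratic_interp <- function(x, y, xi) {
  n <- length(x)
  if (n < 3) kv_stop("kv_segment_too_short", "quadratic interpolation needs >= 3 points")
  idx <- findInterval(xi, x, all.inside = TRUE)
  ctr <- pmin(pmax(idx, 2L), n - 1L)
  x0 <- x[ctr - 1L]; x1 <- x[ctr]; x2 <- x[ctr + 1L]
  y0 <- y[ctr - 1L]; y1 <- y[ctr]; y2 <- y[ctr + 1L]
  l0 <- (xi - x1) * (xi - x2) / ((x0 - x1) * (x0 - x2))
  l1 <- (xi - x0) * (xi - x2) / ((x1 - x0) * (x1 - x2))
  l2 <- (xi - x0) * (xi - x1) / ((x2 - x0) * (x2 - x1))
  y0 * l0 + y1 * l1 + y2 * l2
}

## resample one segment (inclusive index range) to m samples
resample_segment <- function(values, range, m) {
  seg <- values[range[1]:range[2]]
  k <- length(seg)
  if (m == k) return(seg)
  if (k == 1) return(rep(seg, m))
  xs <- seq(0, 1, length.out = k)
  xt <- seq(0, 1, length.out = m)
  if (k < 3) {
    kv_warn("kv_linear_fallback",
            "segment of %d samples: falling back to linear interpolation", k)
    return(approx(xs, seg, xout = xt)$y)
  }
  quadratic_interp(xs, seg, xt)
}

#' Resample a segmented series onto a target segmentation
#'
#' Each of the three sections (start to first peak, first to last peak, last
#' peak to end) is resampled to the length of the corresponding target
#' section with second-order (local quadratic) polynomial interpolation —
#' exact on quadratic signals. The output has exactly the target's length,
#' and the first and last peak samples land on the target's peak positions.
#' Sections with fewer than three samples fall back to linear interpolation
#' with a warning.
#'
#' @param source,target [detect_peaks()] results; `target` is the
#'   higher-rate reference segmentation.
#' @return Numeric vector of length `length(target$values)`.
#' @export
interpolate_segments <- function(source, target) {
  stopifnot(inherits(source, "segmented_series"), inherits(target, "segmented_series"))
  pieces <- lapply(1:3, function(i) {
    m <- target$segments[[i]][2] - target$segments[[i]][1] + 1L
    resample_segment(source$values, source$segments[[i]], m)
  })
  # segments share their boundary samples; drop the duplicated joints
  c(pieces[[1]], pieces[[2]][-1], pieces[[3]][-1])
}

#' Synchronize sensor streams to the gold-standard series
#'
#' Aligns every (smoothed) sensor angle series to the reference series by
#' the movement peaks: both are segmented with [detect_peaks()], the peak
#' counts must agree, and each sensor section is resampled onto the
#' reference section with [interpolate_segments()]. Afterwards every series
#' has the reference's length and phase, with all peak samples coinciding
#' with the reference peaks. A peak-count mismatch raises
#' `kv_sync_mismatch`, which callers treat as a lost recording.
#'
#' @param sensor_series Named list of smoothed [angle_series()] (or numeric
#'   vectors, in which case `sensor_rate` must be given).
#' @param gold The smoothed reference [angle_series()].
#' @param sensor_rate,gold_rate Optional explicit rates.
#' @param ... Passed to [detect_peaks()].
#' @return An object of classes `aligned_set` and `data.frame`: columns
#'   `time_s`, `gold`, then one column per sensor; attribute `peaks` holds
#'   the reference peak indices.
#' @export
synchronize <- function(sensor_series, gold, sensor_rate = NULL,
                        gold_rate = NULL, ...) {
  if (inherits(sensor_series, "angle_series")) {
    sensor_series <- list(sensor = sensor_series)
  }
  g_seg <- detect_peaks(gold, rate = gold_rate, ...)
  aligned <- lapply(names(sensor_series), function(nm) {
    s_seg <- detect_peaks(sensor_series[[nm]], rate = sensor_rate, ...)
    if (length(s_seg$peaks) != length(g_seg$peaks)) {
      kv_stop("kv_sync_mismatch",
              "stream '%s' has %d peaks but the reference has %d",
              nm, length(s_seg$peaks), length(g_seg$peaks))
    }
    interpolate_segments(s_seg, g_seg)
  })
  names(aligned) <- names(sensor_series)
  time_s <- if (inherits(gold, "angle_series")) gold$time_s else {
    (seq_along(g_seg$values) - 1) / g_seg$rate
  }
  out <- data.frame(time_s = time_s, gold = g_seg$values)
  for (nm in names(aligned)) out[[nm]] <- aligned[[nm]]
  structure(out, peaks = g_seg$peaks, class = c("aligned_set", "data.frame"))
}
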