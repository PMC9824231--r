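test_that("smoothing has unit DC gain and strongly attenuates out-of-band tones", {
  # constant series pass through unchanged
  const <- angle_series(rep(42, 400), rate = 30)
  out <- smooth_series(const)
  expect_lt(max(abs(out$angle_deg - 42)), 1e-9)

  # a 12 Hz tone at 30 Hz sampling is attenuated at least 100-fold by the
  # 5 Hz chain (evaluated away from the edges)
  t <- seq(0, 10, by = 1 / 30)
  tone <- sin(2 * pi * 12 * t)
  sm <- smooth_series(angle_series(tone, rate = 30))
  core <- 60:240
  expect_gt(max(abs(tone[core])) / max(abs(sm$angle_deg[core])), 100)

  # a unit impulse through the moving average alone spreads to 7 samples of 1/7
  imp <- c(rep(0, 20), 1, rep(0, 20))
  ma <- kinovalid:::moving_average(imp, 7)
  expect_equal(ma[18:24], rep(1 / 7, 7), tolerance = 1e-12)
  expect_equal(sum(ma), 1, tolerance = 1e-12)

  expect_error(smooth_series(angle_series(rnorm(10), rate = 30)),
               class = "kv_series_too_short")
  expect_error(smooth_series(angle_series(rnorm(100), rate = 30),
                             filter_spec(cutoff = 20)),
               class = "kv_bad_filter")
  expect_error(filter_spec(moving_average_kernel = 6), class = "kv_bad_filter")
})

test_that("short gaps are filled linearly and long gaps lose the recording", {
  x <- as.numeric(1:50)
  x[10:12] <- NA
  filled <- fill_gaps(angle_series(x, rate = 30))
  expect_equal(filled$angle_deg, as.numeric(1:50))  # linear data: exact fill
  expect_true(all(filled$valid))

  x[20:26] <- NA  # 7 consecutive: beyond the fillable maximum of 5
  expect_error(fill_gaps(angle_series(x, rate = 30)), class = "kv_recording_lost")

  lead <- c(NA, NA, 3:30)
  expect_equal(fill_gaps(angle_series(lead, rate = 30))$angle_deg[1:2], c(3, 3))
})

test_that("peak detection finds one maximum per repetition and segments the series", {
  tr <- generate_angle_trajectory(motion_script("K-FLEX-FR-1"), 30)
  sm <- smooth_series(tr)
  seg <- detect_peaks(sm)
  expect_length(seg$peaks, 5)
  # the three sections are contiguous, ordered, and cover the series
  expect_equal(seg$segments[[1]][1], 1)
  expect_equal(seg$segments[[1]][2], seg$segments[[2]][1])
  expect_equal(seg$segments[[2]][2], seg$segments[[3]][1])
  expect_equal(seg$segments[[3]][2], length(seg$values))

  # flat signals and monotone ramps have no repetition peak
  expect_error(detect_peaks(angle_series(rep(5, 100), rate = 30)),
               class = "kv_no_peak")
  expect_error(detect_peaks(angle_series(seq(0, 10, length.out = 100), rate = 30)),
               class = "kv_no_peak")

  # the same trajectory at 30 and 180 Hz peaks at the same instants, within
  # one 30 Hz sample period
  hi <- smooth_series(generate_angle_trajectory(motion_script("K-FLEX-FR-1"), 180))
  sg_hi <- detect_peaks(hi)
  expect_length(sg_hi$peaks, 5)
  t_lo <- sm$time_s[seg$peaks]
  t_hi <- hi$time_s[sg_hi$peaks]
  expect_lt(max(abs(t_lo - t_hi)), 1 / 30 + 1e-9)
})

test_that("segment interpolation is the identity at equal lengths and exact on quadratics", {
  tr <- generate_angle_trajectory(motion_script("H-ABD-FR-1"), 30)
  sm <- smooth_series(tr)
  seg <- detect_peaks(sm)
  same <- interpolate_segments(seg, seg)
  expect_identical(same, seg$values)

  # order-2 interpolation reproduces any quadratic exactly at any length
  x <- seq(0, 1, length.out = 40)
  quad <- function(u) 3 - 2 * u + 5 * u^2
  y <- quad(x)
  xi <- seq(0, 1, length.out = 173)
  yi <- kinovalid:::quadratic_interp(x, y, xi)
  expect_lt(max(abs(yi - quad(xi))), 1e-9)

  # dual-rate ground truth: a 30 Hz series resampled onto its own 180 Hz
  # rendering differs by less than half a degree RMS
  rec <- clean_dual_rate_recording()
  g_seg <- detect_peaks(rec$gold)
  s_seg <- detect_peaks(rec$sensor)
  up <- interpolate_segments(s_seg, g_seg)
  expect_length(up, length(g_seg$values))
  expect_lt(sqrt(mean((up - g_seg$values)^2)), 0.5)
})

test_that("synchronization aligns offset streams onto the reference peaks", {
  script <- motion_script("S-ABD-FR-1")
  tpl <- default_skeleton_template()
  req <- angle_request("shoulder_right", "elbow_right", "frontal")
  mk <- function(rate, offset) {
    smooth_series(compute_angle_series(
      forward_kinematics(tpl, generate_angle_trajectory(script, rate, offset),
                         "S-ABD-FR"),
      req, "upper"))
  }
  gold <- mk(180, 0)
  sens <- mk(30, 0.5)  # injected half-second start offset
  aligned <- synchronize(list(sensor = sens), gold)
  expect_equal(nrow(aligned), nrow(gold))  # length conservation
  # after alignment the sensor peaks sit on the gold peaks: the maxima of
  # both columns coincide within one gold sample
  pk <- attr(aligned, "peaks")
  for (p in pk) {
    win <- max(1, p - 2):min(nrow(aligned), p + 2)
    expect_equal(which.max(aligned$sensor[win]), which.max(aligned$gold[win]),
                 tolerance = 1)
  }
  expect_lt(median(abs(aligned$sensor - aligned$gold)), 0.5)

  # an equal-rate, already aligned series passes through unchanged
  self <- synchronize(list(s = gold), gold)
  expect_equal(self$s, self$gold, tolerance = 1e-12)

  # a 4-peak stream cannot synchronize to a 5-peak reference
  short <- motion_script("S-ABD-FR-1", n_repetitions = 4)
  sens4 <- mk_short <- smooth_series(compute_angle_series(
    forward_kinematics(tpl, generate_angle_trajectory(short, 30), "S-ABD-FR"),
    req, "upper"))
  expect_error(synchronize(list(sensor = sens4), gold), class = "kv_sync_mismatch")
})
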